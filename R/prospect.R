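# Staged bioprospecting workflow: profile-HMM homology pre-filter over a
# sequence database, ensemble prediction of promiscuity, and ranking of the
# surviving candidates by binding-cavity descriptors.

#' Parse HMMER3 tabular search output
#'
#' Reads \code{--tblout} or \code{--domtblout} files; one hit per target is
#' retained (the best, i.e. lowest, full-sequence E-value when a target
#' appears on several lines).
#'
#' @param path path to the HMMER3 tabular file.
#' @param dialect \code{"tblout"} (E-value in field 5, score in field 6) or
#'   \code{"domtblout"} (fields 7 and 8).
#' @return data.frame with columns \code{id}, \code{evalue}, \code{score},
#'   one row per distinct target.
#' @export
parse_hmm_hits <- function(path, dialect = c("tblout", "domtblout")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("HMMER table not found: %s", path))
  e_field <- if (dialect == "tblout") 5L else 7L
  s_field <- e_field + 1L
  lines <- readLines(path, warn = FALSE)
  ids <- character(0); ev <- numeric(0); sc <- numeric(0)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln)) || startsWith(trimws(ln), "#")) next
    toks <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(toks) < s_field)
      stop(sprintf("%s:%d: malformed %s line (%d fields, need >= %d)",
                   path, i, dialect, length(toks), s_field))
    e <- suppressWarnings(as.numeric(toks[e_field]))
    s <- suppressWarnings(as.numeric(toks[s_field]))
    if (is.na(e) || is.na(s) || e <= 0 || !is.finite(e))
      stop(sprintf("%s:%d: malformed %s line (bad E-value/score field)",
                   path, i, dialect))
    ids <- c(ids, toks[1]); ev <- c(ev, e); sc <- c(sc, s)
  }
  if (length(ids) == 0L)
    return(data.frame(id = character(0), evalue = numeric(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  # best E-value per target
  ord <- order(ev, -sc)
  keep <- !duplicated(ids[ord])
  out <- data.frame(id = ids[ord][keep], evalue = ev[ord][keep],
                    score = sc[ord][keep], stringsAsFactors = FALSE)
  out[order(out$evalue, out$id), , drop = FALSE]
}

#' E-value homology pre-filter
#'
#' @param hits data.frame as from \code{\link{parse_hmm_hits}}.
#' @param cutoff E-value cutoff (default \code{1e-10}); hits with
#'   \code{evalue <= cutoff} are retained.
#' @return character vector of retained ids, sorted by ascending E-value.
#' @export
hmm_prefilter <- function(hits, cutoff = 1e-10) {
  kept <- hits[hits$evalue <= cutoff, , drop = FALSE]
  kept$id[order(kept$evalue, kept$id)]
}

#' Build a profile HMM from an alignment and search a database
#'
#' Thin wrapper over the external HMMER binaries (\code{hmmbuild} +
#' \code{hmmsearch}). When the binaries are not on the PATH the operation
#' fails with an explicit error advising the precomputed-hits-table path
#' (\code{\link{parse_hmm_hits}}), so the pipeline can continue in degraded
#' mode from a supplied table.
#'
#' @param msa path to an aligned FASTA or Stockholm multiple alignment
#'   (e.g. of the most promiscuous training esterases).
#' @param db path to the FASTA sequence database to search.
#' @param evalue reporting E-value threshold passed to \code{hmmsearch}.
#' @return data.frame of hits, as from \code{\link{parse_hmm_hits}}.
#' @export
build_profile_and_search <- function(msa, db, evalue = 10) {
  hmmbuild <- Sys.which("hmmbuild")
  hmmsearch <- Sys.which("hmmsearch")
  if (!nzchar(hmmbuild) || !nzchar(hmmsearch))
    stop(paste("external tool unavailable: hmmbuild/hmmsearch not found on PATH;",
               "supply a precomputed hits table via parse_hmm_hits() instead"),
         call. = FALSE)
  if (!file.exists(msa)) stop(sprintf("MSA file not found: %s", msa))
  if (!file.exists(db)) stop(sprintf("database FASTA not found: %s", db))
  if (length(read_fasta(db)) == 0L)   # hmmsearch rejects empty databases
    return(data.frame(id = character(0), evalue = numeric(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  tmp <- tempfile("hmm")
  hmm_file <- paste0(tmp, ".hmm")
  tbl_file <- paste0(tmp, ".tbl")
  status <- system2(hmmbuild, c("--amino", shQuote(hmm_file), shQuote(msa)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("hmmbuild failed on the supplied alignment")
  status <- system2(hmmsearch, c("--tblout", shQuote(tbl_file),
                                 "-E", format(evalue, scientific = TRUE),
                                 shQuote(hmm_file), shQuote(db)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("hmmsearch failed")
  on.exit(unlink(c(hmm_file, tbl_file)), add = TRUE)
  parse_hmm_hits(tbl_file, "tblout")
}

#' Rank positive candidates by binding-cavity descriptors
#'
#' Implements the final triage stage: (1) shortlist the \code{n_shortlist}
#' predicted-positive ids with the best homology E-values; (2) drop
#' candidates whose catalytic triad is not in an active conformation
#' (\code{triad_ok = FALSE}); (3) rank the survivors by cavity
#' hydrophobicity and by the enclosure/exposure ratio (higher = better for
#' both); (4) expand m from \code{n_final} upward until the intersection of
#' the two top-m lists holds at least \code{n_final} ids; (5) order the final
#' ids by the sum of their two ranks (ties by id).
#'
#' @param positive_ids ids predicted positive (after consensus and AD).
#' @param hits data.frame from \code{\link{parse_hmm_hits}}.
#' @param cavity data.frame with columns \code{id}, \code{hydrophobicity},
#'   \code{enclosure}, \code{exposure} (> 0), \code{triad_ok}.
#' @param n_shortlist homology shortlist size (default 100).
#' @param n_final target size of the final candidate set (default 10).
#' @return data.frame of the final candidates in rank order with columns
#'   \code{id}, \code{evalue}, \code{hydrophobicity}, \code{ratio},
#'   \code{hydro_rank}, \code{ratio_rank}, \code{rank_sum}; the attribute
#'   \code{short} is \code{TRUE} (with a warning) when fewer than
#'   \code{n_final} candidates survive the triad filter.
#' @export
rank_candidates <- function(positive_ids, hits, cavity, n_shortlist = 100L,
                            n_final = 10L) {
  req <- c("id", "hydrophobicity", "enclosure", "exposure", "triad_ok")
  missing_cols <- setdiff(req, names(cavity))
  if (length(missing_cols) > 0L)
    stop(sprintf("cavity table is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  pos_hits <- hits[hits$id %in% positive_ids, , drop = FALSE]
  pos_hits <- pos_hits[order(pos_hits$evalue, pos_hits$id), , drop = FALSE]
  shortlist <- utils::head(pos_hits, n_shortlist)
  no_cavity <- setdiff(shortlist$id, cavity$id)
  if (length(no_cavity) > 0L)
    stop(sprintf("cavity descriptors missing for shortlisted id(s): %s",
                 paste(utils::head(no_cavity, 5L), collapse = ", ")))
  tab <- merge(shortlist, cavity, by = "id")
  tab <- tab[tab$triad_ok, , drop = FALSE]
  empty <- data.frame(id = character(0), evalue = numeric(0),
                      hydrophobicity = numeric(0), ratio = numeric(0),
                      hydro_rank = numeric(0), ratio_rank = numeric(0),
                      rank_sum = numeric(0), stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) {
    warning("no candidates survive the catalytic-triad filter")
    attr(empty, "short") <- TRUE
    return(empty)
  }
  if (any(tab$exposure <= 0))
    stop("cavity exposure must be positive to form the enclosure/exposure ratio")
  tab$ratio <- tab$enclosure / tab$exposure
  # ties share the best (min) rank, so a metric constant across candidates
  # contributes nothing and the other metric decides
  tab$hydro_rank <- rank(-tab$hydrophobicity, ties.method = "min")
  tab$ratio_rank <- rank(-tab$ratio, ties.method = "min")
  short <- nrow(tab) < n_final
  if (short) {
    warning(sprintf("only %d candidate(s) survive the triad filter; returning all",
                    nrow(tab)))
    final_ids <- tab$id
  } else {
    final_ids <- character(0)
    for (m in seq.int(n_final, nrow(tab))) {
      inter <- tab$id[tab$hydro_rank <= m & tab$ratio_rank <= m]
      if (length(inter) >= n_final) { final_ids <- inter; break }
    }
  }
  out <- tab[match(final_ids, tab$id),
             c("id", "evalue", "hydrophobicity", "ratio",
               "hydro_rank", "ratio_rank"), drop = FALSE]
  out$rank_sum <- out$hydro_rank + out$ratio_rank
  out <- out[order(out$rank_sum, out$id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "short") <- short
  out
}
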