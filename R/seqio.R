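# Readers and writers for the on-disk formats the pipeline touches:
# multi-record FASTA, PSI-BLAST ASCII PSSM profiles, and delimited tables
# (labels, cavity descriptors, feature matrices).

#' Create a protein record
#'
#' A protein record is the unit of all featurization: a unique id plus an
#' uppercase amino-acid sequence over the 20 canonical letters. Non-canonical
#' residues (B, Z, J, U, O, gaps, stops) are mapped to \code{X};
#' \code{X} is excluded from composition counts downstream so descriptor
#' denominators stay well-defined.
#'
#' @param id unique identifier (non-empty string).
#' @param sequence amino-acid sequence; canonicalized on construction.
#' @return An object of class \code{protein_record} with fields \code{id} and
#'   \code{sequence}.
#' @export
protein_record <- function(id, sequence) {
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id))
    stop("protein record id must be a non-empty string")
  seq <- canonicalize_sequence(sequence)
  if (!nzchar(seq))
    stop(sprintf("record '%s' has an empty sequence", id))
  structure(list(id = id, sequence = seq), class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%d aa)\n", x$id, nchar(x$sequence)))
  invisible(x)
}

#' Canonicalize an amino-acid sequence
#'
#' Uppercases and maps every non-canonical symbol (B, Z, J, U, O, X, \code{*},
#' gap characters) to \code{X}. Errors on symbols that are not plausible
#' sequence characters at all.
#'
#' @param sequence character scalar.
#' @return canonicalized sequence string.
#' @export
canonicalize_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("sequence must be a character scalar")
  s <- toupper(gsub("[[:space:]]", "", sequence))
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- !(ch %in% c(AA20, NONCANONICAL))
  if (any(bad))
    stop(sprintf("sequence contains invalid character(s): %s",
                 paste(unique(ch[bad]), collapse = ", ")))
  ch[ch %in% NONCANONICAL] <- "X"
  paste(ch, collapse = "")
}

#' Read a multi-record FASTA file
#'
#' Sequences wrapped over multiple lines are concatenated; each record is
#' canonicalized (see \code{\link{canonicalize_sequence}}). The record id is
#' the first whitespace-delimited token of the header.
#'
#' @param path path to a FASTA file.
#' @return list of \code{\link{protein_record}} objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  if (file.size(path) == 0L) return(list())
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop(sprintf("malformed FASTA '%s': %s", path,
                                 conditionMessage(e))))
  if (length(set) == 0L) return(list())
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), function(x) {
    if (length(x) == 0L || !nzchar(x[1]))
      stop(sprintf("malformed header in '%s': record with empty id", path))
    x[1]
  }, character(1))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate record id(s) in '%s': %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  seqs <- as.character(set)
  empty <- !nzchar(seqs)
  if (any(empty))
    stop(sprintf("empty sequence for record '%s' in '%s'",
                 ids[which(empty)[1]], path))
  mapply(protein_record, ids, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write protein records to FASTA
#'
#' @param records list of \code{\link{protein_record}}.
#' @param path output path.
#' @param width line width for sequence wrapping.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  seqs <- vapply(records, function(r) r$sequence, character(1))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- vapply(records, function(r) r$id, character(1))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Create a PSSM profile object
#'
#' An L x 20 integer log-odds matrix tied to a record id, with the per-position
#' query residues and the residue column order as read from disk. Internally
#' the score columns are kept in the order they appeared in the file; accessors
#' reorder by name, so transforms are order-independent.
#'
#' @param id record id the profile belongs to.
#' @param scores L x 20 numeric matrix of log-odds; column names must be a
#'   permutation of the 20 canonical letters.
#' @param residues character vector of per-position query residues (length L).
#' @return object of class \code{pssm_profile}.
#' @export
pssm_profile <- function(id, scores, residues = NULL) {
  if (!is.matrix(scores) || ncol(scores) != 20L)
    stop("PSSM scores must be a matrix with exactly 20 columns")
  if (is.null(colnames(scores)) || !setequal(colnames(scores), AA20))
    stop("PSSM score columns must be named with the 20 canonical letters")
  if (nrow(scores) < 1L) stop("PSSM profile must have at least one position")
  if (is.null(residues)) residues <- rep(NA_character_, nrow(scores))
  if (length(residues) != nrow(scores))
    stop("residues must have one entry per PSSM position")
  residues <- toupper(residues)
  residues[!is.na(residues) & !(residues %in% AA20)] <- "X"
  structure(list(id = id, scores = scores, residues = residues,
                 column_order = colnames(scores)),
            class = "pssm_profile")
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat(sprintf("<pssm_profile> %s (%d positions x 20)\n", x$id, nrow(x$scores)))
  invisible(x)
}

#' Score matrix of a PSSM profile in canonical column order
#'
#' Positions whose query residue is the non-canonical placeholder \code{X}
#' have their row zeroed, so downstream transforms are unaffected by unknown
#' residues. Profiles constructed without residue annotations are returned
#' unchanged.
#'
#' @param profile a \code{\link{pssm_profile}}.
#' @return L x 20 numeric matrix with columns in alphabetical residue order.
#' @export
pssm_scores <- function(profile) {
  stopifnot(inherits(profile, "pssm_profile"))
  s <- profile$scores[, AA20, drop = FALSE]
  unk <- !is.na(profile$residues) & profile$residues == "X"
  if (any(unk)) s[unk, ] <- 0
  s
}

#' Read a PSI-BLAST ASCII PSSM file
#'
#' Consumes the \code{-out_ascii_pssm} dialect: header lines, then one row per
#' position carrying the position index, the query residue, 20 integer
#' log-odds, 20 weighted percentages and trailing per-position statistics.
#' Only the 20 log-odds columns are retained.
#'
#' @param path path to the ASCII PSSM file.
#' @param id profile id; defaults to the file name without extension.
#' @return a \code{\link{pssm_profile}}.
#' @export
read_pssm <- function(path, id = NULL) {
  if (!file.exists(path)) stop(sprintf("PSSM file not found: %s", path))
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, warn = FALSE)

  # The column-header line lists 40 residue letters (log-odds block then
  # percentage block); the first 20 give the column order.
  header_idx <- NA_integer_
  col_order <- NULL
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(toks) >= 20L && all(toks %in% AA20)) {
      header_idx <- i
      col_order <- toks[1:20]
      break
    }
  }
  if (is.na(header_idx))
    stop(sprintf("'%s' does not look like an ASCII PSSM: no residue header line",
                 path))

  rows <- list(); residues <- character(0)
  for (i in seq.int(header_idx + 1L, length(lines))) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) break          # blank line ends the matrix block
    toks <- strsplit(ln, "[[:space:]]+")[[1]]
    if (!grepl("^[0-9]+$", toks[1])) break   # trailing statistics block
    if (length(toks) < 2L || !(toupper(toks[2]) %in% c(AA20, NONCANONICAL)))
      stop(sprintf("%s:%d: malformed PSSM row (no residue field)", path, i))
    num <- suppressWarnings(as.numeric(toks[-(1:2)]))
    if (anyNA(num) || length(num) < 40L)
      stop(sprintf("%s:%d: malformed PSSM row: expected 40 numeric fields, got %d",
                   path, i, sum(!is.na(num))))
    rows[[length(rows) + 1L]] <- num[1:20]
    residues <- c(residues, toupper(toks[2]))
  }
  if (length(rows) == 0L)
    stop(sprintf("'%s' contains no PSSM rows", path))
  scores <- do.call(rbind, rows)
  if (all(scores == round(scores))) storage.mode(scores) <- "integer"
  colnames(scores) <- col_order
  pssm_profile(id, scores, residues)
}

#' Read a delimited table with a schema
#'
#' Reads comma- or tab-delimited text with a header row; the delimiter is
#' sniffed from the first line. Required columns are coerced to the declared
#' types; unknown columns are preserved as read.
#'
#' @param path path to the file.
#' @param schema named character vector mapping required column names to types
#'   (\code{"character"}, \code{"integer"}, \code{"numeric"}, \code{"logical"}).
#' @return a \code{data.frame}.
#' @export
read_table_schema <- function(path, schema = NULL) {
  if (!file.exists(path)) stop(sprintf("table not found: %s", path))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop(sprintf("'%s' is empty (no header line)", path))
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "", quote = "\"")
  if (!is.null(schema)) {
    missing_cols <- setdiff(names(schema), names(df))
    if (length(missing_cols) > 0L)
      stop(sprintf("'%s' is missing required column(s): %s", path,
                   paste(missing_cols, collapse = ", ")))
    for (col in names(schema)) {
      df[[col]] <- switch(schema[[col]],
        character = as.character(df[[col]]),
        integer   = as.integer(df[[col]]),
        numeric   = as.numeric(df[[col]]),
        logical   = as.logical(df[[col]]),
        stop(sprintf("unknown schema type '%s' for column '%s'",
                     schema[[col]], col)))
    }
  }
  df
}

#' Write a delimited table
#'
#' @param df data frame.
#' @param path output path; tab-delimited if it ends in \code{.tsv}, else CSV.
#' @return \code{path}, invisibly.
#' @export
write_table_delim <- function(df, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a feature matrix as delimited text
#'
#' The id column comes first, then one column per feature; the family tag of
#' each feature column is stored in a comment-free sidecar header produced by
#' \code{\link{read_feature_table}} from the column name prefix
#' (\code{physchem.} / \code{pssm.}).
#'
#' @param X feature matrix as returned by the featurization functions
#'   (numeric matrix with row ids and family-tagged column names).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_feature_table <- function(X, path) {
  df <- data.frame(id = rownames(X), as.data.frame(X, check.names = FALSE),
                   check.names = FALSE)
  write_table_delim(df, path)
}

#' Read a feature matrix written by \code{\link{write_feature_table}}
#'
#' @param path path to the table.
#' @return numeric matrix with row ids and a \code{family} attribute recovered
#'   from the column-name prefixes.
#' @export
read_feature_table <- function(path) {
  df <- read_table_schema(path, schema = c(id = "character"))
  X <- as.matrix(df[, setdiff(names(df), "id"), drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- df$id
  feature_matrix(X)
}
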