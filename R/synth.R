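# Synthetic data generation: random proteins, synthetic PSI-BLAST PSSM
# fixtures, planted-signal labelled datasets, and mock HMMER hit / cavity
# descriptor tables. Every generator is a pure function of its parameters and
# seed, so fixtures are reproducible byte for byte.

#' Generate a random protein record
#'
#' Uniform-random sequence over the 20 canonical residues.
#'
#' @param length sequence length (>= 1).
#' @param seed integer seed.
#' @param id record id.
#' @return a \code{\link{protein_record}}.
#' @export
gen_protein <- function(length, seed = 1L, id = "synthetic") {
  if (length < 1L) stop("length must be >= 1")
  set.seed(seed)
  protein_record(id, paste(sample(AA20, length, replace = TRUE),
                           collapse = ""))
}

#' Generate a synthetic PSSM profile (and optionally its ASCII fixture file)
#'
#' Log-odds favour the record's own residue: the matching column gets +5 at
#' each position, all other columns integer noise in [-3, 3]. When \code{path}
#' is given, a syntactically valid PSI-BLAST ASCII PSSM file is written whose
#' round trip through \code{\link{read_pssm}} reproduces the matrix exactly.
#'
#' @param record a \code{\link{protein_record}}.
#' @param seed integer seed.
#' @param path optional output path for the ASCII fixture.
#' @return the in-memory \code{\link{pssm_profile}}.
#' @export
gen_pssm_fixture <- function(record, seed = 1L, path = NULL) {
  set.seed(seed)
  ch <- strsplit(record$sequence, "", fixed = TRUE)[[1]]
  L <- length(ch)
  scores <- matrix(sample(-3:3, L * 20L, replace = TRUE), nrow = L)
  colnames(scores) <- AA20_PSSM
  for (i in seq_len(L))
    if (ch[i] %in% AA20_PSSM) scores[i, ch[i]] <- 5L
  profile <- pssm_profile(record$id, scores, ch)
  if (!is.null(path)) .write_ascii_pssm(profile, path)
  profile
}

# write the PSI-BLAST -out_ascii_pssm dialect: banner, 40-letter column
# header, per-position rows (index, residue, 20 log-odds, 20 percentages,
# two per-position statistics), blank line, trailing K/Lambda block
.write_ascii_pssm <- function(profile, path) {
  S <- profile$scores[, AA20_PSSM, drop = FALSE]
  pct <- round(100 / (1 + exp(-S)))
  lines <- c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("           ",
           paste(sprintf("%3s", c(AA20_PSSM, AA20_PSSM)), collapse = ""))
  )
  for (i in seq_len(nrow(S))) {
    lines <- c(lines, paste0(
      sprintf("%5d %s ", i, profile$residues[i]),
      paste(sprintf("%3d", S[i, ]), collapse = ""),
      paste(sprintf("%4d", pct[i, ]), collapse = ""),
      sprintf("  %4.2f %8.2f", 0.36, 0.08)))
  }
  lines <- c(lines, "",
             "                      K         Lambda",
             "Standard Ungapped    0.1347     0.3176",
             "Standard Gapped      0.0410     0.2670")
  writeLines(lines, path)
  invisible(path)
}

#' Specification of a planted-signal synthetic dataset
#'
#' Defines the study conditions of a synthetic promiscuity dataset: class
#' sizes, the descriptor columns carrying the planted signal, the requested
#' between-class separation in pooled-sd units, and the label-flip noise.
#' The signal is planted by biased residue sampling (the positive class draws
#' the signal residues at elevated frequency), so featurization is genuinely
#' exercised rather than feature values being edited.
#'
#' @param n_pos,n_neg class sizes; defaults 58/87 (145 samples, 40\% positive).
#' @param length sequence length (default 150).
#' @param signal_residues residues whose composition carries the signal
#'   (default I and L, mimicking elevated aliphatic content in promiscuous
#'   esterases); the corresponding descriptor targets are the
#'   \code{physchem.aac.<residue>} columns.
#' @param effect requested separation of each signal column in pooled-sd
#'   units (default 3).
#' @param noise label-flip probability in [0, 0.5).
#' @param seed integer seed.
#' @return object of class \code{planted_spec}.
#' @export
planted_spec <- function(n_pos = 58L, n_neg = 87L, length = 150L,
                         signal_residues = c("I", "L"), effect = 3,
                         noise = 0, seed = 1L) {
  if (effect < 0) stop("effect size must be >= 0")
  if (noise < 0 || noise >= 0.5) stop("label noise must lie in [0, 0.5)")
  bad <- setdiff(signal_residues, AA20)
  if (length(bad) > 0L)
    stop(sprintf("unachievable signal column(s): no descriptor for residue(s) %s",
                 paste(bad, collapse = ", ")))
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length = as.integer(length),
                 signal_residues = signal_residues,
                 signal_columns = paste0("physchem.aac.", signal_residues),
                 effect = effect, noise = noise, seed = as.integer(seed)),
            class = "planted_spec")
}

#' Generate a planted-signal dataset
#'
#' Positive-class sequences draw the signal residues with a frequency shift
#' calibrated (by a fixed-point step on the pooled binomial sd) so that the
#' realized separation of the \code{physchem.aac.*} signal columns matches
#' the requested effect size. Each record gets a synthetic PSSM profile, so
#' the signal propagates into the evolutionary feature block as well. Labels
#' are flipped with the given noise probability; substrate counts consistent
#' with the labels (>= 20 for positives) are also generated.
#'
#' @param spec a \code{\link{planted_spec}}.
#' @return list with \code{records}, \code{profiles}, \code{labels} (named
#'   0/1), \code{counts} (named substrate counts), \code{signal_columns} and
#'   the \code{spec}.
#' @export
gen_planted_dataset <- function(spec = planted_spec()) {
  stopifnot(inherits(spec, "planted_spec"))
  set.seed(spec$seed)
  n <- spec$n_pos + spec$n_neg
  L <- spec$length
  p0 <- rep(1 / 20, 20L)
  names(p0) <- AA20
  sig <- spec$signal_residues

  # fixed point: shift delta such that delta = effect * pooled sd of the
  # per-residue frequency at the realized probabilities
  delta <- spec$effect * sqrt(p0[1] * (1 - p0[1]) / L)
  for (it in 1:5) {
    p1s <- p0[1] + delta
    pooled <- sqrt((p0[1] * (1 - p0[1]) + p1s * (1 - p1s)) / (2 * L))
    delta <- spec$effect * pooled
  }
  p_pos <- p0
  p_pos[sig] <- p0[sig] + delta
  if (sum(p_pos[sig]) >= 1)
    stop("requested effect size is infeasible at this sequence length")
  other <- setdiff(AA20, sig)
  p_pos[other] <- p_pos[other] * (1 - sum(p_pos[sig])) / sum(p0[other])

  true_class <- sample(c(rep(1L, spec$n_pos), rep(0L, spec$n_neg)))
  ids <- sprintf("s%03d", seq_len(n))
  records <- vector("list", n)
  profiles <- vector("list", n)
  labels <- integer(n)
  counts <- integer(n)
  for (i in seq_len(n)) {
    probs <- if (true_class[i] == 1L) p_pos else p0
    seq_i <- paste(sample(AA20, L, replace = TRUE, prob = probs),
                   collapse = "")
    records[[i]] <- protein_record(ids[i], seq_i)
    lab <- true_class[i]
    if (spec$noise > 0 && stats::runif(1) < spec$noise) lab <- 1L - lab
    labels[i] <- lab
    counts[i] <- if (lab == 1L) sample(20:96, 1L) else sample(0:19, 1L)
  }
  # profile seeds derived from the spec seed, one per record
  prof_seeds <- sample.int(.Machine$integer.max %/% 2L, n)
  for (i in seq_len(n))
    profiles[[i]] <- gen_pssm_fixture(records[[i]], seed = prof_seeds[i])
  names(labels) <- ids
  names(counts) <- ids
  list(records = records, profiles = profiles, labels = labels,
       counts = counts, signal_columns = spec$signal_columns, spec = spec)
}

#' Realized between-class separation of feature columns
#'
#' Difference of class means divided by the pooled standard deviation, per
#' column; used to verify that the generator delivers the requested effect.
#'
#' @param X a \code{\link{feature_matrix}}.
#' @param labels named 0/1 labels covering the rows.
#' @param columns feature columns to measure.
#' @return named numeric vector of separations (positive-class mean minus
#'   negative-class mean, in pooled-sd units).
#' @export
realized_separation <- function(X, labels, columns) {
  labels <- labels[rownames(X)]
  vapply(columns, function(cl) {
    x1 <- X[labels == 1L, cl]; x0 <- X[labels == 0L, cl]
    pooled <- sqrt((stats::var(x1) + stats::var(x0)) / 2)
    if (pooled == 0) 0 else (mean(x1) - mean(x0)) / pooled
  }, numeric(1))
}

#' Generate a mock HMMER tblout hits table
#'
#' Ids in \code{significant_ids} receive E-values well below \code{1e-10};
#' the rest lie above it. Written in HMMER3 \code{--tblout} shape so the
#' fixture exercises the real parser.
#'
#' @param ids target ids.
#' @param significant_ids subset of \code{ids} to place below the cutoff.
#' @param seed integer seed.
#' @param path optional output path; when \code{NULL} only the data.frame is
#'   returned.
#' @return data.frame with \code{id}, \code{evalue}, \code{score}.
#' @export
gen_hmm_hits_fixture <- function(ids, significant_ids = ids, seed = 1L,
                                 path = NULL) {
  set.seed(seed)
  expo <- ifelse(ids %in% significant_ids,
                 stats::runif(length(ids), -30, -11),
                 stats::runif(length(ids), -9, -3))
  ev <- signif(10^expo, 3)   # written precision == returned precision
  sc <- round(-expo * 2 + stats::runif(length(ids), 0, 5), 1)
  if (!is.null(path)) {
    lines <- c(
      "#                                                               --- full sequence ---- --- best 1 domain ---- --- domain number estimation ----",
      "# target name        accession  query name           accession    E-value  score  bias   E-value  score  bias   exp reg clu  ov env dom rep inc description of target",
      "#------------------- ---------- -------------------- ---------- --------- ------ ----- --------- ------ ----- ---- --- --- -- -- --- --- --- ---------------------",
      sprintf("%-20s -          esterase_profile     -          %9.3g %6.1f   0.1 %9.3g %6.1f   0.1  1.0   1   0  0  1   1   1   1 -",
              ids, ev, sc, ev, sc))
    writeLines(lines, path)
  }
  data.frame(id = ids, evalue = ev, score = sc, stringsAsFactors = FALSE)
}

#' Generate a mock binding-cavity descriptor table
#'
#' Hydrophobicity, enclosure and exposure drawn from plausible ranges; a
#' fraction of candidates get an inactive catalytic triad
#' (\code{triad_ok = FALSE}). When labels are supplied, positives receive a
#' mild upward shift in hydrophobicity and enclosure so that cavity ranking
#' has signal to find.
#'
#' @param ids candidate ids.
#' @param seed integer seed.
#' @param triad_frac fraction of candidates with an intact triad.
#' @param labels optional named 0/1 labels used to bias the descriptors.
#' @param path optional output path (CSV).
#' @return data.frame with \code{id}, \code{hydrophobicity},
#'   \code{enclosure}, \code{exposure}, \code{triad_ok}.
#' @export
gen_cavity_fixture <- function(ids, seed = 1L, triad_frac = 0.8,
                               labels = NULL, path = NULL) {
  set.seed(seed)
  n <- length(ids)
  bump <- if (is.null(labels)) rep(0, n) else 0.3 * as.numeric(labels[ids])
  bump[is.na(bump)] <- 0
  tab <- data.frame(
    id = ids,
    hydrophobicity = round(stats::runif(n, 0.2, 1.0) + bump, 4),
    enclosure = round(stats::runif(n, 0.55, 0.85) + 0.05 * bump, 4),
    exposure = round(stats::runif(n, 0.3, 0.7), 4),
    triad_ok = stats::runif(n) < triad_frac,
    stringsAsFactors = FALSE)
  if (!is.null(path)) write_table_delim(tab, path)
  tab
}

#' Write a planted dataset to a directory as on-disk fixtures
#'
#' Emits the full set of pipeline inputs: a FASTA file, one ASCII PSSM per
#' record under \code{pssm/}, a label table (\code{id,count}), a mock cavity
#' table and a mock HMMER hits table.
#'
#' @param ds dataset from \code{\link{gen_planted_dataset}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_synth_dataset <- function(ds, dir) {
  dir.create(file.path(dir, "pssm"), recursive = TRUE, showWarnings = FALSE)
  write_fasta(ds$records, file.path(dir, "sequences.fasta"))
  for (i in seq_along(ds$records))
    .write_ascii_pssm(ds$profiles[[i]],
                      file.path(dir, "pssm",
                                paste0(ds$records[[i]]$id, ".pssm")))
  write_table_delim(data.frame(id = names(ds$counts), count = ds$counts),
                    file.path(dir, "labels.csv"))
  ids <- names(ds$labels)
  gen_hmm_hits_fixture(ids, significant_ids = ids[seq_len(length(ids) %/% 2)],
                       seed = ds$spec$seed + 1L,
                       path = file.path(dir, "hits.tbl"))
  gen_cavity_fixture(ids, seed = ds$spec$seed + 2L, labels = ds$labels,
                     path = file.path(dir, "cavity.csv"))
  invisible(dir)
}
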