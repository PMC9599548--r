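# Single entry point chaining the stages: data loading (real files or the
# synthetic generator) -> featurization -> cleaning -> ensemble fit ->
# homology pre-filter -> prediction with applicability domain -> cavity
# ranking. Every stage logs input/output cardinalities; the effective config
# (with all seeds explicit) is written next to the outputs, and re-running
# from that file reproduces the outputs bit for bit.

.default_config <- function() {
  list(
    seed = 1L,
    out = NULL,
    data = list(synth = list(n_pos = 58L, n_neg = 87L, length = 150L,
                             effect = 3, noise = 0, n_query = 40L)),
    registries = list(physchem = "default", pssm = "default"),
    clean = list(max_identical_frac = 0.9),
    model = list(methods = c(svc = "chi-square", ridge = "chi-square",
                             knn = "random-forest-importance"),
                 dims = c(svc = 20L, ridge = 20L, knn = 30L),
                 quota = c(svc = 2L, ridge = 3L, knn = 2L),
                 n_repeats = 5L, test_fraction = 0.2,
                 ad_k = 5L, ad_z = 0.5, pssm_frac = 0.75),
    prospect = list(hits = "synthetic", cavity = "synthetic",
                    evalue = 1e-10, shortlist = 100L, final = 10L)
  )
}

.merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]]))
      base[[k]] <- .merge_config(base[[k]], user[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}

#' Load a run configuration
#'
#' Merges a user configuration (a YAML file or a list) over the package
#' defaults. All randomness is controlled by explicit seeds in the config;
#' there is no hidden global randomness.
#'
#' @param config path to a YAML file, or a list.
#' @return the effective configuration list.
#' @export
load_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  cfg <- .merge_config(.default_config(), config)
  # a user data block without a synth entry means file inputs: the default
  # synthetic block must not resurface through the merge
  if (!is.null(config$data) && is.null(config$data$synth))
    cfg$data$synth <- NULL
  for (k in c("methods", "dims", "quota"))
    cfg$model[[k]] <- unlist(cfg$model[[k]])
  cfg
}

.resolve_registry <- function(spec, default) {
  if (identical(spec, "default") || is.null(spec)) return(default)
  registry_subset(default, unlist(spec))
}

.validate_config <- function(cfg) {
  if (is.null(cfg$out)) stop("config error: 'out' directory is required")
  d <- cfg$data
  if (is.null(d$synth)) {
    for (k in c("fasta", "pssm_dir", "labels"))
      if (is.null(d[[k]]))
        stop(sprintf("config error: data input '%s' is required when no synthetic block is given", k))
    for (k in c("fasta", "labels"))
      if (!file.exists(d[[k]]))
        stop(sprintf("config error: data input '%s' not found: %s", k, d[[k]]))
    if (!dir.exists(d$pssm_dir))
      stop(sprintf("config error: pssm_dir not found: %s", d$pssm_dir))
    for (k in c("hits", "cavity")) {
      v <- cfg$prospect[[k]]
      if (is.null(v) || identical(v, "synthetic"))
        stop(sprintf("config error: prospect input '%s' must be a file when data is not synthetic", k))
      if (!file.exists(v))
        stop(sprintf("config error: prospect input '%s' not found: %s", k, v))
    }
  }
  invisible(cfg)
}

#' Run the full bioprospecting pipeline
#'
#' Executes featurize -> clean -> select/train/ensemble/AD -> homology
#' pre-filter -> prediction -> cavity ranking, writing per-stage outputs, the
#' effective configuration, and a log with per-stage input/output counts to
#' the configured output directory.
#'
#' @param config YAML path or list; see \code{\link{load_config}}.
#' @return (invisibly) a list with the fitted \code{\link{eppred}} model, the
#'   prediction table, the final ranking, the funnel counts, and the output
#'   directory.
#' @export
run_pipeline <- function(config) {
  cfg <- .validate_config(load_config(config))
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log_stage <- function(stage, n_in, n_out) {
    line <- sprintf("stage %-12s in=%d out=%d", stage, n_in, n_out)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  phys_reg <- .resolve_registry(cfg$registries$physchem,
                                default_physchem_registry())
  pssm_reg <- .resolve_registry(cfg$registries$pssm, default_pssm_registry())

  # ---- stage: load training data -----------------------------------------
  if (!is.null(cfg$data$synth)) {
    s <- cfg$data$synth
    ds <- gen_planted_dataset(planted_spec(
      n_pos = s$n_pos, n_neg = s$n_neg, length = s$length,
      effect = s$effect, noise = s$noise, seed = cfg$seed))
    records <- ds$records; profiles <- ds$profiles
    labels <- ds$labels
  } else {
    records <- read_fasta(cfg$data$fasta)
    profiles <- lapply(records, function(r) {
      p <- file.path(cfg$data$pssm_dir, paste0(r$id, ".pssm"))
      if (!file.exists(p))
        stop(sprintf("no PSSM profile for record '%s' (%s)", r$id, p))
      read_pssm(p, id = r$id)
    })
    lab_tab <- read_table_schema(cfg$data$labels,
                                 schema = c(id = "character",
                                            count = "integer"))
    labels <- label_from_counts(stats::setNames(lab_tab$count, lab_tab$id))
    labels <- labels[vapply(records, function(r) r$id, character(1))]
  }
  log_stage("load", length(records), length(records))

  # ---- stage: featurize + clean ------------------------------------------
  X <- featurize(records, profiles, physchem_registry = phys_reg,
                 pssm_registry = pssm_reg)
  log_stage("featurize", nrow(X), ncol(X))
  Xc <- clean_features(X, cfg$clean$max_identical_frac)
  log_stage("clean", ncol(X), ncol(Xc))

  # ---- stage: fit the ensemble -------------------------------------------
  m <- cfg$model
  fit <- eppred(Xc, labels, methods = m$methods, dims = m$dims,
                quota = m$quota, n_repeats = m$n_repeats,
                test_fraction = m$test_fraction, ad_k = m$ad_k,
                ad_z = m$ad_z, pssm_frac = m$pssm_frac, seed = cfg$seed)
  log_stage("train", nrow(Xc), length(fit$ensemble$members))

  # ---- stage: prospecting inputs -----------------------------------------
  if (!is.null(cfg$data$synth)) {
    s <- cfg$data$synth
    qn <- s$n_query
    qds <- gen_planted_dataset(planted_spec(
      n_pos = ceiling(qn / 2), n_neg = floor(qn / 2), length = s$length,
      effect = s$effect, noise = 0, seed = cfg$seed + 1000L))
    q_records <- qds$records; q_profiles <- qds$profiles
    q_ids <- names(qds$labels)
    hits <- gen_hmm_hits_fixture(
      q_ids, significant_ids = q_ids[seq_len(ceiling(length(q_ids) * 0.75))],
      seed = cfg$seed + 2000L)
    cavity <- gen_cavity_fixture(q_ids, seed = cfg$seed + 3000L,
                                 labels = qds$labels)
  } else {
    q_records <- read_fasta(cfg$data$fasta)   # default: rescreen the input
    if (!is.null(cfg$prospect$db)) q_records <- read_fasta(cfg$prospect$db)
    q_profiles <- lapply(q_records, function(r)
      read_pssm(file.path(cfg$data$pssm_dir, paste0(r$id, ".pssm")),
                id = r$id))
    hits <- parse_hmm_hits(cfg$prospect$hits)
    cavity <- read_table_schema(cfg$prospect$cavity,
                                schema = c(id = "character",
                                           hydrophobicity = "numeric",
                                           enclosure = "numeric",
                                           exposure = "numeric",
                                           triad_ok = "logical"))
  }

  # ---- stage: homology pre-filter ----------------------------------------
  retained <- hmm_prefilter(hits, cutoff = cfg$prospect$evalue)
  retained <- intersect(retained,
                        vapply(q_records, function(r) r$id, character(1)))
  log_stage("hmm_filter", nrow(hits), length(retained))

  # ---- stage: ensemble prediction + AD -----------------------------------
  keep <- vapply(q_records, function(r) r$id %in% retained, logical(1))
  Xq <- featurize(q_records[keep], q_profiles[keep],
                  physchem_registry = phys_reg, pssm_registry = pssm_reg)
  Xq <- feature_matrix(Xq[retained, , drop = FALSE])  # E-value order
  pred <- predict(fit, Xq, ad = TRUE)
  positive_ids <- pred$id[pred$label == "positive"]
  log_stage("predict", length(retained), length(positive_ids))
  reliable_ids <- pred$id[pred$label == "positive" & pred$ad_reliable]
  log_stage("ad_filter", length(positive_ids), length(reliable_ids))

  # ---- stage: cavity ranking ---------------------------------------------
  ranking <- rank_candidates(reliable_ids, hits, cavity,
                             n_shortlist = cfg$prospect$shortlist,
                             n_final = cfg$prospect$final)
  log_stage("rank", length(reliable_ids), nrow(ranking))

  # ---- outputs ------------------------------------------------------------
  writeLines(log_lines, file.path(cfg$out, "log.txt"))
  yaml::write_yaml(.config_serializable(cfg),
                   file.path(cfg$out, "config_effective.yaml"))
  write_table_delim(pred, file.path(cfg$out, "predictions.csv"))
  write_table_delim(ranking, file.path(cfg$out, "final_ranking.csv"))
  perf <- eppred_performance(fit)
  write_table_delim(
    data.frame(repeat_id = seq_along(perf$ensemble_mcc),
               ensemble_mcc = perf$ensemble_mcc,
               abstention_rate = perf$abstention_rate),
    file.path(cfg$out, "ensemble_performance.csv"))
  for (a in names(fit$feature_sets))
    write_feature_set(fit$feature_sets[[a]],
                      file.path(cfg$out, sprintf("feature_set_%s.txt", a)))

  invisible(list(fit = fit, predictions = pred, ranking = ranking,
                 log = log_lines, out = cfg$out))
}

# yaml::write_yaml needs plain lists
.config_serializable <- function(cfg) {
  rapply(cfg, function(x) if (is.null(names(x))) x else as.list(x),
         how = "replace")
}
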