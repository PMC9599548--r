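# The core model: an abstaining agreement ensemble of shallow classifiers
# trained under the repeated stratified-split protocol, with a KNN-style
# applicability domain. eppred() is the one fitting entry point; the pieces
# (make_splits, build_feature_sets, tune_and_train, select_members, fit_ad)
# are exported individually for custom protocols.

#' Fit the promiscuity ensemble classifier
#'
#' End-to-end model fit from a cleaned feature matrix and binary labels:
#' \enumerate{
#'   \item build the repeated stratified 80/20 split plan;
#'   \item on the first repeat's training slice, select one compact weighted
#'     feature set per algorithm (PSSM-heavy, size-capped at half the
#'     training-sample count);
#'   \item for each algorithm, tune (inner stratified 5-fold CV over the
#'     grid, best mean MCC) and train one model per repeat;
#'   \item keep the per-algorithm quota of members with the best test MCC
#'     (default 2 SVM + 3 ridge + 2 KNN) as the unanimous-agreement ensemble;
#'   \item fit the applicability domain in the standardized space of the
#'     ensemble's most-used feature set.
#' }
#'
#' @param X a \code{\link{feature_matrix}} (typically
#'   \code{\link{clean_features}} of \code{\link{featurize}} output).
#' @param y binary 0/1 labels named by row id (see
#'   \code{\link{label_from_counts}}).
#' @param methods named character: feature-ranking method per algorithm.
#' @param dims named integer: feature-set size per algorithm.
#' @param quota named integer: ensemble member count per algorithm.
#' @param n_repeats,test_fraction split-plan parameters (default 5 x 80/20).
#' @param grids hyperparameter grids, as \code{\link{default_grids}}.
#' @param rule agreement rule, \code{"unanimous"} or \code{"majority"}.
#' @param ad_k,ad_z applicability-domain neighbour count and spread
#'   multiplier.
#' @param pssm_frac evolutionary-feature fraction of each feature set.
#' @param seed integer seed for splits, selection and tuning.
#' @return an object of class \code{eppred}; see
#'   \code{\link{predict.eppred}}, \code{\link{summary.eppred}}.
#' @examples
#' ds <- gen_planted_dataset(planted_spec(n_pos = 20, n_neg = 30,
#'                                        length = 60, seed = 4))
#' X <- clean_features(featurize(
#'   ds$records, ds$profiles,
#'   physchem_registry = registry_subset(default_physchem_registry(),
#'                                       c("aac", "dpc")),
#'   pssm_registry = registry_subset(default_pssm_registry(), "aac_pssm")))
#' fit <- eppred(X, ds$labels, dims = c(svc = 5, ridge = 5, knn = 5),
#'               seed = 4)
#' summary(fit)
#' @export
eppred <- function(X, y,
                   methods = c(svc = "chi-square", ridge = "chi-square",
                               knn = "random-forest-importance"),
                   dims = c(svc = 20L, ridge = 20L, knn = 30L),
                   quota = c(svc = 2L, ridge = 3L, knn = 2L),
                   n_repeats = 5L, test_fraction = 0.2,
                   grids = default_grids(),
                   rule = c("unanimous", "majority"),
                   ad_k = 5L, ad_z = 0.5, pssm_frac = 0.75, seed = 1L) {
  rule <- match.arg(rule)
  cl <- match.call()
  if (is.null(names(y)) || !setequal(names(y), rownames(X)))
    stop("y must be a named 0/1 vector covering the rows of X")
  y <- as.integer(y[rownames(X)] > 0)
  names(y) <- rownames(X)
  algorithms <- names(quota)
  stopifnot(all(algorithms %in% names(methods)),
            all(algorithms %in% names(dims)))

  plan <- make_splits(y, n_repeats = n_repeats,
                      test_fraction = test_fraction, seed = seed)
  sel_ids <- plan$repeats[[1]]$train
  cap <- floor(length(sel_ids) / 2)

  # one feature set per algorithm, selected on the designated training slice
  feature_sets <- list()
  cache <- list()
  for (a in algorithms) {
    key <- sprintf("%s_%d", methods[[a]], dims[[a]])
    if (is.null(cache[[key]])) {
      fs <- build_feature_sets(X[sel_ids, , drop = FALSE], y[sel_ids],
                               methods = methods[[a]],
                               variants = data.frame(dims = dims[[a]],
                                                     pssm_frac = pssm_frac),
                               cap = cap, seed = seed)
      cache[[key]] <- fs[[1]]
    }
    feature_sets[[a]] <- cache[[key]]
  }

  evaluations <- list()
  candidates <- list()
  for (a in algorithms) {
    ev <- evaluate_over_splits(a, X, y, feature_sets[[a]], plan,
                               grid = grids[[a]])
    evaluations[[a]] <- ev
    candidates <- c(candidates, ev$models)
  }

  ensemble <- select_members(candidates, quota = quota, rule = rule)

  # per-repeat consensus performance on the held-out test ids
  ens_reports <- vector("list", plan$n_repeats)
  for (r in seq_len(plan$n_repeats)) {
    te <- plan$repeats[[r]]$test
    cons <- consensus_predict(ensemble, X[te, , drop = FALSE])
    ens_reports[[r]] <- score_consensus(cons, y)
  }

  # applicability domain in the ensemble's most-used feature space
  used <- vapply(ensemble$members, function(m)
    if (is.null(m$feature_set)) "custom" else m$feature_set$label,
    character(1))
  ref_label <- names(sort(table(used), decreasing = TRUE))[1]
  ref_member <- ensemble$members[[which(used == ref_label)[1]]]
  ref_cols <- ref_member$columns
  Xr <- X[, ref_cols, drop = FALSE]
  ctr <- colMeans(Xr)
  scl <- apply(Xr, 2L, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(Xr, 2L, ctr), 2L, scl, "/")
  ad <- fit_ad(Xs, k = ad_k, Z = ad_z, center = ctr, scale = scl)

  structure(list(call = cl,
                 ensemble = ensemble,
                 ad = ad,
                 plan = plan,
                 feature_sets = feature_sets,
                 evaluations = evaluations,
                 ensemble_reports = ens_reports,
                 labels = y,
                 seed = seed),
            class = "eppred")
}

#' Mean ensemble test MCC of a fitted model
#'
#' @param object an \code{eppred} fit.
#' @return list with per-repeat ensemble MCCs, their mean, the per-repeat
#'   abstention rates, and per-algorithm mean member MCCs.
#' @export
eppred_performance <- function(object) {
  stopifnot(inherits(object, "eppred"))
  ens_mcc <- vapply(object$ensemble_reports, function(s) s$report$MCC,
                    numeric(1))
  abst <- vapply(object$ensemble_reports, function(s) s$abstention_rate,
                 numeric(1))
  member_mcc <- sapply(object$ensemble$members, function(m) m$test_mcc)
  alg_mean <- vapply(object$evaluations, function(e) e$mean_test_mcc,
                     numeric(1))
  list(ensemble_mcc = ens_mcc, mean_ensemble_mcc = mean(ens_mcc),
       abstention_rate = abst, member_test_mcc = member_mcc,
       algorithm_mean_test_mcc = alg_mean)
}

#' @export
print.eppred <- function(x, ...) {
  perf <- eppred_performance(x)
  cat("Abstaining agreement ensemble for substrate-promiscuity prediction\n")
  cat(sprintf("  %d members, rule=%s; %d-repeat stratified %d/%d split plan\n",
              length(x$ensemble$members), x$ensemble$rule,
              x$plan$n_repeats,
              round(100 * (1 - x$plan$test_fraction)),
              round(100 * x$plan$test_fraction)))
  cat(sprintf("  mean ensemble test MCC: %.3f (abstention %.1f%%)\n",
              perf$mean_ensemble_mcc, 100 * mean(perf$abstention_rate)))
  invisible(x)
}

#' @export
summary.eppred <- function(object, ...) {
  perf <- eppred_performance(object)
  algs <- vapply(object$ensemble$members, function(m) m$algorithm,
                 character(1))
  reps <- vapply(object$ensemble$members, function(m) m$repeat_id, numeric(1))
  members <- data.frame(algorithm = algs, repeat_id = reps,
                        feature_set = vapply(object$ensemble$members,
                                             function(m) m$feature_set$label,
                                             character(1)),
                        test_mcc = perf$member_test_mcc)
  out <- list(members = members,
              per_repeat = data.frame(
                repeat_id = seq_along(perf$ensemble_mcc),
                ensemble_mcc = perf$ensemble_mcc,
                abstention_rate = perf$abstention_rate),
              mean_ensemble_mcc = perf$mean_ensemble_mcc,
              algorithm_mean_test_mcc = perf$algorithm_mean_test_mcc)
  class(out) <- "summary.eppred"
  out
}

#' @export
print.summary.eppred <- function(x, ...) {
  cat("Ensemble members (chosen by test MCC):\n")
  print(x$members, row.names = FALSE)
  cat("\nPer-repeat consensus on held-out test sets (abstentions excluded):\n")
  print(x$per_repeat, row.names = FALSE)
  cat(sprintf("\nMean ensemble test MCC: %.3f\n", x$mean_ensemble_mcc))
  invisible(x)
}

#' Predict promiscuity with a fitted ensemble
#'
#' Member votes, the agreement label (\code{positive} / \code{negative} /
#' \code{abstain}) and the applicability-domain reliability flag for each
#' query row.
#'
#' @param object an \code{eppred} fit.
#' @param newdata a \code{\link{feature_matrix}} with the required columns
#'   (same featurization as the training matrix).
#' @param ad apply the applicability-domain filter (default TRUE).
#' @param ... unused.
#' @return data.frame with \code{id}, \code{votes}, \code{label},
#'   \code{ad_reliable}.
#' @export
predict.eppred <- function(object, newdata, ad = TRUE, ...) {
  cons <- consensus_predict(object$ensemble, newdata)
  out <- data.frame(id = cons$id, votes = cons$votes, label = cons$label,
                    stringsAsFactors = FALSE)
  out$ad_reliable <- if (ad)
    as.logical(ad_filter(object$ad, newdata)) else NA
  out
}

#' Plot per-repeat MCCs of members and ensemble
#'
#' @param x an \code{eppred} fit.
#' @param ... passed to \code{matplot}.
#' @export
plot.eppred <- function(x, ...) {
  perf <- eppred_performance(x)
  alg_mcc <- sapply(x$evaluations, function(e)
    vapply(e$test_reports, function(s) s$MCC, numeric(1)))
  mat <- cbind(alg_mcc, ensemble = perf$ensemble_mcc)
  graphics::matplot(mat, type = "b", pch = 19, lty = 1,
                    xlab = "split repeat", ylab = "test MCC",
                    ylim = range(c(0, 1, mat)), ...)
  graphics::legend("bottomright", legend = colnames(mat),
                   col = seq_len(ncol(mat)), pch = 19, lty = 1, bty = "n")
  invisible(x)
}
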