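# Repeated stratified-split training with inner 5-fold hyperparameter tuning,
# and the confusion-matrix metric suite (precision, recall, F1, Matthews
# correlation coefficient).

#' Stratified repeated train/test split plan
#'
#' Splits the ids into an 80/20 train/test partition, stratified by label,
#' \code{n_repeats} times with different draws; reproducible from the seed.
#'
#' @param y named binary 0/1 label vector (names are sample ids).
#' @param n_repeats number of repeats (default 5).
#' @param test_fraction test-set fraction (default 0.2).
#' @param seed integer seed.
#' @return object of class \code{split_plan}: per-repeat train/test id sets.
#' @export
make_splits <- function(y, n_repeats = 5L, test_fraction = 0.2, seed = 1L) {
  if (is.null(names(y))) names(y) <- as.character(seq_along(y))
  tab <- table(y)
  if (length(tab) < 2L || any(tab < 5L))
    stop("stratified splitting requires at least 5 samples per class")
  set.seed(seed)
  repeats <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    test_ids <- character(0)
    for (cls in names(tab)) {
      ids_c <- names(y)[y == cls]
      n_test <- max(1L, round(test_fraction * length(ids_c)))
      test_ids <- c(test_ids, sample(ids_c, n_test))
    }
    repeats[[r]] <- list(train = setdiff(names(y), test_ids),
                         test = test_ids)
  }
  structure(list(repeats = repeats, n_repeats = n_repeats,
                 test_fraction = test_fraction, seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d repeats, test fraction %.2f (seed %d)\n",
              x$n_repeats, x$test_fraction, x$seed))
  for (r in seq_len(x$n_repeats))
    cat(sprintf("  repeat %d: %d train / %d test\n", r,
                length(x$repeats[[r]]$train), length(x$repeats[[r]]$test)))
  invisible(x)
}

#' Confusion-matrix metric report
#'
#' Computes TP/TN/FP/FN counts and precision \eqn{Pr = TP/(FP+TP)}, recall
#' \eqn{Re = TP/(FN+TP)}, \eqn{F1 = 2 Pr Re/(Pr+Re)} and the Matthews
#' correlation coefficient
#' \eqn{MCC = (TP TN - FP FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.
#' Any metric with a zero denominator is 0 by convention, so constant
#' predictors score 0.
#'
#' @param pred predicted binary 0/1 labels.
#' @param truth true binary 0/1 labels of the same length.
#' @return object of class \code{metric_report} with fields \code{TP},
#'   \code{TN}, \code{FP}, \code{FN}, \code{Pr}, \code{Re}, \code{F1},
#'   \code{MCC}.
#' @export
score_predictions <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("pred and truth must have the same length")
  pred <- as.integer(pred); truth <- as.integer(truth)
  if (!all(pred %in% c(0L, 1L)) || !all(truth %in% c(0L, 1L)))
    stop("labels must be binary 0/1")
  TP <- sum(pred == 1L & truth == 1L)
  TN <- sum(pred == 0L & truth == 0L)
  FP <- sum(pred == 1L & truth == 0L)
  FN <- sum(pred == 0L & truth == 1L)
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  Pr <- safe_div(TP, FP + TP)
  Re <- safe_div(TP, FN + TP)
  F1 <- safe_div(2 * Pr * Re, Pr + Re)
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  MCC <- if (mcc_den == 0) 0 else (TP * TN - FP * FN) / mcc_den
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN,
                 Pr = Pr, Re = Re, F1 = F1, MCC = MCC),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("TP=%d TN=%d FP=%d FN=%d | Pr=%.3f Re=%.3f F1=%.3f MCC=%.3f\n",
              x$TP, x$TN, x$FP, x$FN, x$Pr, x$Re, x$F1, x$MCC))
  invisible(x)
}

# ---------------------------------------------------------------------------
# shallow classifiers behind a uniform fit/predict interface

# closed-form ridge classifier: ridge regression on +/-1 targets with an
# unpenalized intercept, thresholded at 0
.ridge_fit <- function(X, y, lambda) {
  ypm <- ifelse(as.integer(y) == 1L, 1, -1)
  xm <- colMeans(X)
  Xc <- sweep(X, 2L, xm)
  A <- crossprod(Xc) + diag(lambda, ncol(X))
  w <- solve(A, crossprod(Xc, ypm - mean(ypm)))
  b <- mean(ypm) - sum(xm * w)
  list(w = as.vector(w), b = b)
}

.ridge_predict <- function(fit, X) {
  as.integer(as.vector(X %*% fit$w + fit$b) > 0)
}

.knn_predict <- function(train_X, train_y, k, weights, X) {
  train_y <- as.integer(train_y)
  k <- min(k, nrow(train_X))   # degenerate small folds
  out <- integer(nrow(X))
  for (i in seq_len(nrow(X))) {
    d <- sqrt(colSums((t(train_X) - X[i, ])^2))
    nn <- order(d)[seq_len(k)]
    wts <- if (weights == "uniform") rep(1, k) else 1 / pmax(d[nn], 1e-12)
    pos <- sum(wts[train_y[nn] == 1L])
    neg <- sum(wts[train_y[nn] == 0L])
    out[i] <- as.integer(pos > neg)
  }
  out
}

.fit_algorithm <- function(algorithm, X, y, hyper) {
  switch(algorithm,
    svc = e1071::svm(X, factor(y, levels = c(0L, 1L)),
                     kernel = hyper$kernel, cost = hyper$cost, scale = FALSE),
    knn = list(train_X = X, train_y = y, k = hyper$k, weights = hyper$weights),
    ridge = .ridge_fit(X, y, hyper$lambda),
    stop(sprintf("unknown algorithm '%s'", algorithm)))
}

.predict_algorithm <- function(algorithm, fit, X) {
  switch(algorithm,
    svc = as.integer(as.character(stats::predict(fit, X))),
    knn = .knn_predict(fit$train_X, fit$train_y, fit$k, fit$weights, X),
    ridge = .ridge_predict(fit, X))
}

#' Default hyperparameter grids
#'
#' @return named list of data.frames, one grid per algorithm (\code{svc},
#'   \code{knn}, \code{ridge}).
#' @export
default_grids <- function() {
  list(svc = expand.grid(kernel = c("radial", "linear"),
                         cost = c(0.1, 1, 10), stringsAsFactors = FALSE),
       knn = expand.grid(k = c(3L, 5L, 7L, 9L),
                         weights = c("uniform", "distance"),
                         stringsAsFactors = FALSE),
       ridge = data.frame(lambda = c(0.01, 0.1, 1, 10)))
}

# stratified fold assignment, deterministic from the current RNG state
.stratified_folds <- function(y, nfold) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(nfold), length(idx))
  }
  fold
}

#' Tune hyperparameters by inner cross-validation and fit
#'
#' Standardizes the selected feature columns on the training split (center
#' and scale fitted on train only), runs stratified 5-fold cross-validation
#' over the grid, picks the grid point with the best mean inner-CV MCC (ties:
#' first grid row), and refits on the full training split. Deterministic
#' given \code{seed}.
#'
#' @param algorithm \code{"svc"}, \code{"knn"} or \code{"ridge"}.
#' @param X training \code{\link{feature_matrix}}.
#' @param y binary 0/1 labels for the rows of \code{X}.
#' @param feature_set a \code{feature_set} (or character vector of column
#'   names) restricting the columns used.
#' @param grid data.frame of hyperparameter combinations; defaults to the
#'   packaged grid for the algorithm.
#' @param seed integer seed controlling fold assignment.
#' @param inner_folds number of inner CV folds (default 5).
#' @return object of class \code{promisc_classifier} carrying the fitted
#'   state, chosen hyperparameters, scaler, feature set and provenance.
#' @export
tune_and_train <- function(algorithm, X, y, feature_set, grid = NULL,
                           seed = 1L, inner_folds = 5L) {
  cols <- if (inherits(feature_set, "feature_set")) feature_set$columns
          else as.character(feature_set)
  missing_cols <- setdiff(cols, colnames(X))
  if (length(missing_cols) > 0L)
    stop(sprintf("feature matrix lacks column(s): %s",
                 paste(utils::head(missing_cols, 5L), collapse = ", ")))
  if (is.null(grid)) grid <- default_grids()[[algorithm]]
  if (is.null(grid) || nrow(grid) == 0L) stop("hyperparameter grid is empty")
  y <- as.integer(y)
  Xs_raw <- X[, cols, drop = FALSE]
  center <- colMeans(Xs_raw)
  scl <- apply(Xs_raw, 2L, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(Xs_raw, 2L, center), 2L, scl, "/")

  set.seed(seed)
  fold <- .stratified_folds(y, inner_folds)
  mean_mcc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    hyper <- as.list(grid[g, , drop = FALSE])
    mccs <- numeric(inner_folds)
    for (f in seq_len(inner_folds)) {
      tr <- fold != f; te <- fold == f
      if (length(unique(y[tr])) < 2L)
        stop("degenerate inner fold with a single class; use more samples")
      fit <- .fit_algorithm(algorithm, Xs[tr, , drop = FALSE], y[tr], hyper)
      pred <- .predict_algorithm(algorithm, fit, Xs[te, , drop = FALSE])
      mccs[f] <- score_predictions(pred, y[te])$MCC
    }
    mean_mcc[g] <- mean(mccs)
  }
  best <- which.max(mean_mcc)   # first maximum: deterministic tie-break
  hyper <- as.list(grid[best, , drop = FALSE])
  fit <- .fit_algorithm(algorithm, Xs, y, hyper)
  structure(list(algorithm = algorithm,
                 hyper = hyper,
                 cv_mcc = mean_mcc[best],
                 feature_set = if (inherits(feature_set, "feature_set"))
                   feature_set else NULL,
                 columns = cols,
                 center = center, scale = scl,
                 fit = fit, seed = seed,
                 train_ids = rownames(X)),
            class = "promisc_classifier")
}

#' @export
print.promisc_classifier <- function(x, ...) {
  hy <- paste(names(x$hyper), unlist(lapply(x$hyper, as.character)),
              sep = "=", collapse = ", ")
  cat(sprintf("<promisc_classifier> %s (%s), %d features, inner-CV MCC %.3f\n",
              x$algorithm, hy, length(x$columns), x$cv_mcc))
  invisible(x)
}

#' Predict with a fitted classifier
#'
#' Applies the classifier's own scaler to its own feature columns.
#'
#' @param object a \code{promisc_classifier}.
#' @param newdata \code{\link{feature_matrix}} containing the classifier's
#'   columns.
#' @param ... unused.
#' @return named integer 0/1 predictions.
#' @export
predict.promisc_classifier <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$columns, colnames(newdata))
  if (length(missing_cols) > 0L)
    stop(sprintf("newdata lacks column(s): %s",
                 paste(utils::head(missing_cols, 5L), collapse = ", ")))
  Xs <- sweep(sweep(newdata[, object$columns, drop = FALSE], 2L,
                    object$center), 2L, object$scale, "/")
  stats::setNames(.predict_algorithm(object$algorithm, object$fit, Xs),
                  rownames(newdata))
}

#' Evaluate an algorithm/feature-set pair over a split plan
#'
#' For each repeat of the plan, tunes and trains on the training ids and
#' scores on the held-out test ids; returns the per-repeat fitted models,
#' the per-repeat train/test metric reports, and mean/sd aggregates.
#'
#' @param algorithm \code{"svc"}, \code{"knn"} or \code{"ridge"}.
#' @param X full \code{\link{feature_matrix}} (rows = all ids of the plan).
#' @param y binary labels named by id.
#' @param feature_set \code{feature_set} or column-name vector.
#' @param plan a \code{\link{make_splits}} plan.
#' @param grid optional hyperparameter grid.
#' @return object of class \code{split_evaluation}.
#' @export
evaluate_over_splits <- function(algorithm, X, y, feature_set, plan,
                                 grid = NULL) {
  stopifnot(inherits(plan, "split_plan"))
  models <- vector("list", plan$n_repeats)
  train_reports <- vector("list", plan$n_repeats)
  test_reports <- vector("list", plan$n_repeats)
  for (r in seq_len(plan$n_repeats)) {
    tr_ids <- plan$repeats[[r]]$train
    te_ids <- plan$repeats[[r]]$test
    m <- tune_and_train(algorithm, X[tr_ids, , drop = FALSE], y[tr_ids],
                        feature_set, grid = grid,
                        seed = plan$seed + r)
    m$repeat_id <- r
    pred_tr <- predict(m, X[tr_ids, , drop = FALSE])
    pred_te <- predict(m, X[te_ids, , drop = FALSE])
    train_reports[[r]] <- score_predictions(pred_tr, y[tr_ids])
    test_reports[[r]] <- score_predictions(pred_te, y[te_ids])
    m$test_mcc <- test_reports[[r]]$MCC
    models[[r]] <- m
  }
  test_mcc <- vapply(test_reports, function(s) s$MCC, numeric(1))
  train_mcc <- vapply(train_reports, function(s) s$MCC, numeric(1))
  structure(list(algorithm = algorithm,
                 models = models,
                 train_reports = train_reports,
                 test_reports = test_reports,
                 mean_test_mcc = mean(test_mcc), sd_test_mcc = stats::sd(test_mcc),
                 mean_train_mcc = mean(train_mcc),
                 sd_train_mcc = stats::sd(train_mcc)),
            class = "split_evaluation")
}

#' @export
print.split_evaluation <- function(x, ...) {
  cat(sprintf("<split_evaluation> %s over %d repeats: test MCC %.3f +/- %.3f (train %.3f +/- %.3f)\n",
              x$algorithm, length(x$models), x$mean_test_mcc, x$sd_test_mcc,
              x$mean_train_mcc, x$sd_train_mcc))
  invisible(x)
}
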