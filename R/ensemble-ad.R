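# Agreement-based abstaining ensemble and the k-nearest-neighbour
# applicability domain that gates prediction reliability.

#' Select ensemble members by test MCC quota
#'
#' From a pool of fitted classifiers carrying test MCCs, keeps the per-
#' algorithm quota of top candidates (default two SVM, three ridge, two KNN).
#' Ties in MCC are broken deterministically by lower repeat id.
#'
#' @param candidates list of \code{promisc_classifier} objects, each with
#'   \code{test_mcc} and \code{repeat_id} set (as returned inside
#'   \code{\link{evaluate_over_splits}}).
#' @param quota named integer vector of per-algorithm member counts.
#' @param rule agreement rule: \code{"unanimous"} (default) or
#'   \code{"majority"}.
#' @param majority_q minimum agreeing votes for the majority rule.
#' @return object of class \code{ensemble_model}.
#' @export
select_members <- function(candidates,
                           quota = c(svc = 2L, ridge = 3L, knn = 2L),
                           rule = c("unanimous", "majority"),
                           majority_q = NULL) {
  rule <- match.arg(rule)
  algs <- vapply(candidates, function(m) m$algorithm, character(1))
  members <- list()
  for (a in names(quota)) {
    pool <- candidates[algs == a]
    if (length(pool) < quota[[a]])
      stop(sprintf("quota unsatisfiable: need %d '%s' candidates, have %d",
                   quota[[a]], a, length(pool)))
    mcc <- vapply(pool, function(m) m$test_mcc, numeric(1))
    rep_id <- vapply(pool, function(m) m$repeat_id, numeric(1))
    keep <- order(-mcc, rep_id)[seq_len(quota[[a]])]
    members <- c(members, pool[keep])
  }
  if (rule == "majority" && is.null(majority_q))
    majority_q <- floor(length(members) / 2) + 1L
  structure(list(members = members, rule = rule, majority_q = majority_q,
                 quota = quota),
            class = "ensemble_model")
}

#' Build an ensemble directly from a member list
#'
#' Degenerate or custom compositions (including a single-member ensemble used
#' in tests) without the quota machinery.
#'
#' @param members list of \code{promisc_classifier}.
#' @param rule,majority_q agreement rule, as in \code{\link{select_members}}.
#' @return an \code{ensemble_model}.
#' @export
ensemble_model <- function(members, rule = c("unanimous", "majority"),
                           majority_q = NULL) {
  rule <- match.arg(rule)
  if (rule == "majority" && is.null(majority_q))
    majority_q <- floor(length(members) / 2) + 1L
  structure(list(members = members, rule = rule, majority_q = majority_q,
                 quota = NULL),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  algs <- table(vapply(x$members, function(m) m$algorithm, character(1)))
  cat(sprintf("<ensemble_model> %d members (%s), rule=%s\n",
              length(x$members),
              paste(names(algs), algs, sep = ":", collapse = ", "), x$rule))
  invisible(x)
}

#' Consensus prediction with abstention
#'
#' Each member votes with its own feature set and scaler. Under the unanimous
#' rule a sample is labelled only when all members agree, otherwise the
#' ensemble abstains; under the majority rule at least \code{majority_q}
#' agreeing votes are required.
#'
#' @param ensemble an \code{ensemble_model}.
#' @param X \code{\link{feature_matrix}} containing the union of the member
#'   feature columns.
#' @return object of class \code{consensus_prediction}: a data.frame with
#'   \code{id}, \code{votes} (comma-separated member votes) and \code{label}
#'   (\code{"positive"}, \code{"negative"} or \code{"abstain"}), plus the raw
#'   vote matrix as attribute \code{vote_matrix}.
#' @export
consensus_predict <- function(ensemble, X) {
  stopifnot(inherits(ensemble, "ensemble_model"))
  need <- unique(unlist(lapply(ensemble$members, function(m) m$columns)))
  missing_cols <- setdiff(need, colnames(X))
  if (length(missing_cols) > 0L)
    stop(sprintf("feature matrix lacks required column(s): %s",
                 paste(utils::head(missing_cols, 5L), collapse = ", ")))
  votes <- vapply(ensemble$members, function(m) predict(m, X),
                  integer(nrow(X)))
  if (nrow(X) == 1L) votes <- matrix(votes, nrow = 1L)
  n_pos <- rowSums(votes == 1L)
  n_members <- length(ensemble$members)
  label <- rep("abstain", nrow(X))
  if (ensemble$rule == "unanimous") {
    label[n_pos == n_members] <- "positive"
    label[n_pos == 0L] <- "negative"
  } else {
    q <- ensemble$majority_q
    label[n_pos >= q] <- "positive"
    label[(n_members - n_pos) >= q] <- "negative"
  }
  out <- data.frame(id = rownames(X),
                    votes = apply(votes, 1L, paste, collapse = ","),
                    label = label, stringsAsFactors = FALSE)
  attr(out, "vote_matrix") <- votes
  class(out) <- c("consensus_prediction", "data.frame")
  out
}

#' Score a consensus prediction against truth, excluding abstentions
#'
#' @param consensus a \code{consensus_prediction}.
#' @param truth named 0/1 labels.
#' @return list with the \code{\link{score_predictions}} report on the
#'   non-abstained samples, the abstention rate, and the scored ids.
#' @export
score_consensus <- function(consensus, truth) {
  kept <- consensus$label != "abstain"
  ids <- consensus$id[kept]
  report <- if (length(ids) == 0L) score_predictions(integer(0), integer(0))
            else score_predictions(as.integer(consensus$label[kept] == "positive"),
                                   truth[ids])
  list(report = report,
       abstention_rate = mean(!kept),
       scored_ids = ids)
}

#' Fit a k-nearest-neighbour applicability domain
#'
#' For each training sample i, the reliability threshold is
#' \eqn{t_i = \bar d_i + Z s_i}, where \eqn{\bar d_i} and \eqn{s_i} are the
#' mean and standard deviation of the Euclidean distances from sample i to
#' its k nearest training neighbours (Z = 0 gives the plain mean). Distances
#' are computed in the coordinates of \code{X} as given; pass standardized
#' features (and their scaler) for scale-sensitive spaces.
#'
#' @param X numeric training matrix (rows = training samples), already in the
#'   reference feature space.
#' @param k neighbour count (default 5); must be < \code{nrow(X)}.
#' @param Z spread multiplier (default 0.5).
#' @param center,scale optional scaler parameters recorded so that
#'   \code{\link{ad_filter}} can project queries into the same space.
#' @return object of class \code{ad_model}.
#' @export
fit_ad <- function(X, k = 5L, Z = 0.5, center = NULL, scale = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k >= n) stop(sprintf("k = %d must be smaller than the number of training samples (%d)", k, n))
  D <- as.matrix(stats::dist(X))
  thresholds <- numeric(n)
  for (i in seq_len(n)) {
    dn <- sort(D[i, -i])[seq_len(k)]
    s <- if (k > 1L) stats::sd(dn) else 0
    thresholds[i] <- mean(dn) + Z * s
  }
  structure(list(train = X, thresholds = thresholds, k = k, Z = Z,
                 center = center, scale = scale,
                 columns = colnames(X)),
            class = "ad_model")
}

#' @export
print.ad_model <- function(x, ...) {
  cat(sprintf("<ad_model> %d training samples, k=%d, Z=%.2f, thresholds [%.3g, %.3g]\n",
              nrow(x$train), x$k, x$Z, min(x$thresholds), max(x$thresholds)))
  invisible(x)
}

#' Applicability-domain reliability filter
#'
#' A query is reliable iff its Euclidean distance to at least one training
#' sample i is less than or equal to that sample's threshold \eqn{t_i}.
#' If the model carries scaler parameters, queries are projected with them
#' first.
#'
#' @param ad an \code{ad_model}.
#' @param X query matrix (rows = queries) in the same feature space (or raw
#'   features if the model carries a scaler).
#' @return named logical vector, \code{TRUE} = reliable.
#' @export
ad_filter <- function(ad, X) {
  stopifnot(inherits(ad, "ad_model"))
  X <- as.matrix(X)
  if (!is.null(ad$columns) && !is.null(colnames(X))) {
    missing_cols <- setdiff(ad$columns, colnames(X))
    if (length(missing_cols) > 0L)
      stop(sprintf("query matrix lacks column(s): %s",
                   paste(utils::head(missing_cols, 5L), collapse = ", ")))
    X <- X[, ad$columns, drop = FALSE]
  }
  if (ncol(X) != ncol(ad$train))
    stop(sprintf("query has %d feature(s), applicability domain expects %d",
                 ncol(X), ncol(ad$train)))
  if (!is.null(ad$center)) X <- sweep(X, 2L, ad$center)
  if (!is.null(ad$scale)) X <- sweep(X, 2L, ad$scale, "/")
  out <- logical(nrow(X))
  for (i in seq_len(nrow(X))) {
    d <- sqrt(colSums((t(ad$train) - X[i, ])^2))
    out[i] <- any(d <= ad$thresholds)
  }
  names(out) <- rownames(X)
  out
}
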