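# Length-independent matrix transforms of PSSM profiles. Transforms operate on
# the raw integer log-odds; transforms that need probabilities apply the
# logistic map 1/(1+exp(-s)) internally (flagged per registry entry as
# uses_logistic). The default registry concatenates to 18,730 dimensions.

.logistic <- function(s) 1 / (1 + exp(-s))

.pair_names <- function(prefix = "") {
  as.vector(t(outer(AA20, AA20, function(a, b) paste0(prefix, a, ".", b))))
}

#' Column-average transform of a PSSM
#'
#' Reduces the L x 20 profile to 20 dimensions by averaging each log-odds
#' column over positions.
#'
#' @param profile a \code{\link{pssm_profile}}.
#' @return named 20-vector.
#' @export
column_average_transform <- function(profile) {
  S <- pssm_scores(profile)
  stats::setNames(colMeans(S), AA20)
}

#' Dipeptide transform of a PSSM
#'
#' Entry (a, b) is the position-averaged product of the column-a score at
#' position i and the column-b score at position i+1:
#' \eqn{(1/(L-1)) \sum_i s_{i,a} s_{i+1,b}}.
#'
#' @param profile a \code{\link{pssm_profile}}.
#' @return named 400-vector.
#' @export
dipeptide_transform <- function(profile) {
  S <- pssm_scores(profile)
  L <- nrow(S)
  if (L < 2L) stop("dipeptide transform requires at least 2 positions")
  M <- crossprod(S[-L, , drop = FALSE], S[-1L, , drop = FALSE]) / (L - 1L)
  stats::setNames(as.vector(t(M)), .pair_names())
}

#' Per-column autocovariance transform of a PSSM
#'
#' For column j and lag d: \eqn{(1/(L-d)) \sum_i (s_{i,j}-m_j)(s_{i+d,j}-m_j)}
#' with \eqn{m_j} the column mean.
#'
#' @param profile a \code{\link{pssm_profile}}.
#' @param nlag maximum lag; must be smaller than the profile length.
#' @return named vector of length \code{20 * nlag}.
#' @export
autocovariance_transform <- function(profile, nlag = 20L) {
  S <- pssm_scores(profile)
  L <- nrow(S)
  if (L <= nlag)
    stop(sprintf("autocovariance requires profile length > nlag = %d", nlag))
  Sc <- sweep(S, 2L, colMeans(S))
  out <- numeric(20L * nlag)
  for (d in seq_len(nlag)) {
    v <- colSums(Sc[seq_len(L - d), , drop = FALSE] *
                 Sc[seq_len(L - d) + d, , drop = FALSE]) / (L - d)
    out[(d - 1L) * 20L + seq_len(20L)] <- v
  }
  names(out) <- paste0(rep(AA20, nlag), ".lag", rep(seq_len(nlag), each = 20L))
  out
}

# cross-covariance between distinct columns at lags 1..nlag (380 * nlag dims)
.pssm_cc <- function(profile, nlag = 17L) {
  S <- pssm_scores(profile)
  L <- nrow(S)
  if (L <= nlag)
    stop(sprintf("cross-covariance requires profile length > nlag = %d", nlag))
  Sc <- sweep(S, 2L, colMeans(S))
  off <- which(diag(20L) == 0)   # off-diagonal cells, column-major
  pair_nm <- outer(AA20, AA20, function(a, b) paste0(a, ".", b))
  out <- numeric(380L * nlag)
  nms <- character(380L * nlag)
  for (d in seq_len(nlag)) {
    M <- crossprod(Sc[seq_len(L - d), , drop = FALSE],
                   Sc[seq_len(L - d) + d, , drop = FALSE]) / (L - d)
    idx <- (d - 1L) * 380L + seq_len(380L)
    out[idx] <- M[off]
    nms[idx] <- paste0(pair_nm[off], ".lag", d)
  }
  names(out) <- nms
  out
}

# column sums of the positive-part matrix, per unit length
.d_fpssm <- function(profile) {
  S <- pssm_scores(profile)
  stats::setNames(colSums(pmax(S, 0)) / nrow(S), AA20)
}

# squared-difference dipeptide at gap 2 (400) and its column means (20)
.eedp_matrix <- function(profile) {
  S <- pssm_scores(profile)
  L <- nrow(S)
  if (L < 3L) stop("gap-2 squared-difference transform requires length >= 3")
  A <- S[seq_len(L - 2L), , drop = FALSE]
  C <- S[seq_len(L - 2L) + 2L, , drop = FALSE]
  ma2 <- colMeans(A^2)
  mc2 <- colMeans(C^2)
  Mac <- crossprod(A, C) / (L - 2L)
  outer(ma2, rep(1, 20L)) + outer(rep(1, 20L), mc2) - 2 * Mac
}

.eedp <- function(profile) {
  M <- .eedp_matrix(profile)
  stats::setNames(as.vector(t(M)), .pair_names())
}

.edp <- function(profile) {
  stats::setNames(colMeans(.eedp_matrix(profile)), AA20)
}

# moving-window smoothed profile, then column means
.smoothed_avg <- function(profile, window = 7L) {
  S <- pssm_scores(profile)
  L <- nrow(S)
  half <- window %/% 2L
  Sm <- matrix(0, L, 20L)
  for (i in seq_len(L)) {
    lo <- max(1L, i - half); hi <- min(L, i + half)
    Sm[i, ] <- colMeans(S[lo:hi, , drop = FALSE])
  }
  stats::setNames(colMeans(Sm), AA20)
}

# 20 consecutive row blocks, column means per block
.ab_pssm <- function(profile) {
  S <- pssm_scores(profile)
  L <- nrow(S)
  if (L < 20L) stop("block-average transform requires profile length >= 20")
  block <- ceiling(seq_len(L) / (L / 20))
  block[block > 20L] <- 20L
  out <- numeric(400L)
  for (b in seq_len(20L))
    out[(b - 1L) * 20L + seq_len(20L)] <-
      colMeans(S[block == b, , drop = FALSE])
  stats::setNames(out, as.vector(t(outer(paste0("b", 1:20), AA20, paste,
                                         sep = "."))))
  }

# residue-grouped row statistics (query residue a -> 20 column stats)
.grouped_rows <- function(profile, mode = c("sum_per_len", "pos_mean",
                                            "pos_sum_per_len")) {
  mode <- match.arg(mode)
  S <- pssm_scores(profile)
  L <- nrow(S)
  res <- profile$residues
  out <- numeric(400L)
  for (a in seq_len(20L)) {
    rows <- which(res == AA20[a])
    v <- if (length(rows) == 0L) rep(0, 20L) else switch(mode,
      sum_per_len = colSums(S[rows, , drop = FALSE]) / L,
      pos_mean = colMeans(pmax(S[rows, , drop = FALSE], 0)),
      pos_sum_per_len = colSums(pmax(S[rows, , drop = FALSE], 0)) / L)
    out[(a - 1L) * 20L + seq_len(20L)] <- v
  }
  stats::setNames(out, .pair_names())
}

# k-separated bigram: products of columns k+1 apart
.ksb_pssm <- function(profile, k = 2L) {
  S <- pssm_scores(profile)
  L <- nrow(S)
  if (L <= k) stop(sprintf("k-separated bigram requires length > %d", k))
  M <- crossprod(S[seq_len(L - k), , drop = FALSE],
                 S[seq_len(L - k) + k, , drop = FALSE]) / (L - k)
  stats::setNames(as.vector(t(M)), .pair_names(paste0("k", k, ".")))
}

# logistic-probability dipeptide transform
.tpc_pssm <- function(profile) {
  P <- .logistic(pssm_scores(profile))
  L <- nrow(P)
  if (L < 2L) stop("probability dipeptide transform requires length >= 2")
  M <- crossprod(P[-L, , drop = FALSE], P[-1L, , drop = FALSE]) / (L - 1L)
  stats::setNames(as.vector(t(M)), .pair_names())
}

# reduced 10-letter alphabet transform: squared-difference dipeptide (100)
# plus per-group column variances (10)
.rpssm <- function(profile) {
  S <- pssm_scores(profile)
  L <- nrow(S)
  if (L < 2L) stop("reduced-alphabet transform requires length >= 2")
  R <- sapply(RPSSM_GROUPS, function(g)
    rowMeans(S[, match(g, AA20), drop = FALSE]))
  A <- R[-L, , drop = FALSE]; B <- R[-1L, , drop = FALSE]
  ma2 <- colMeans(A^2); mb2 <- colMeans(B^2)
  D <- (outer(ma2, rep(1, 10L)) + outer(rep(1, 10L), mb2) -
        2 * crossprod(A, B) / (L - 1L)) / 2
  vars <- apply(R, 2L, function(x) mean((x - mean(x))^2))
  gn <- paste0("g", seq_len(10L))
  stats::setNames(c(as.vector(t(D)), vars),
                  c(as.vector(t(outer(gn, gn, paste, sep = "."))),
                    paste0(gn, ".var")))
}

# pseudo-PSSM: logistic column means plus lagged squared-difference terms
.pse_pssm <- function(profile, xi = 2L) {
  P <- .logistic(pssm_scores(profile))
  L <- nrow(P)
  if (L <= xi) stop(sprintf("pseudo-PSSM requires length > xi = %d", xi))
  out <- colMeans(P)
  names(out) <- paste0("mean.", AA20)
  for (g in seq_len(xi)) {
    v <- colMeans((P[seq_len(L - g), , drop = FALSE] -
                   P[seq_len(L - g) + g, , drop = FALSE])^2)
    names(v) <- paste0("lag", g, ".", AA20)
    out <- c(out, v)
  }
  out
}

# logistic trigram: (1/(L-2)) sum_i P[i,a] P[i+1,b] P[i+2,c]
.tri_gram <- function(profile) {
  P <- .logistic(pssm_scores(profile))
  L <- nrow(P)
  if (L < 3L) stop("trigram transform requires length >= 3")
  A <- P[seq_len(L - 2L), , drop = FALSE]
  B <- P[seq_len(L - 2L) + 1L, , drop = FALSE]
  C <- P[seq_len(L - 2L) + 2L, , drop = FALSE]
  out <- numeric(8000L)
  for (a in seq_len(20L)) {
    M <- crossprod(B * A[, a], C) / (L - 2L)   # 20 x 20, (b, c)
    out[(a - 1L) * 400L + seq_len(400L)] <- as.vector(t(M))
  }
  nms <- as.vector(t(outer(AA20, .pair_names(), paste, sep = ".")))
  stats::setNames(out, nms)
}

.PSSM_TRANSFORMS <- list(
  aac_pssm   = list(fn = function(p, pr) column_average_transform(p),
                    uses_logistic = FALSE),
  d_fpssm    = list(fn = function(p, pr) .d_fpssm(p), uses_logistic = FALSE),
  edp        = list(fn = function(p, pr) .edp(p), uses_logistic = FALSE),
  smoothed   = list(fn = function(p, pr) .smoothed_avg(p, pr$window),
                    uses_logistic = FALSE),
  ab_pssm    = list(fn = function(p, pr) .ab_pssm(p), uses_logistic = FALSE),
  composition = list(fn = function(p, pr) .grouped_rows(p, "sum_per_len"),
                     uses_logistic = FALSE),
  rpm_pssm   = list(fn = function(p, pr) .grouped_rows(p, "pos_mean"),
                    uses_logistic = FALSE),
  s_fpssm    = list(fn = function(p, pr) .grouped_rows(p, "pos_sum_per_len"),
                    uses_logistic = FALSE),
  dpc_pssm   = list(fn = function(p, pr) dipeptide_transform(p),
                    uses_logistic = FALSE),
  ksb_pssm   = list(fn = function(p, pr) .ksb_pssm(p, pr$k),
                    uses_logistic = FALSE),
  eedp       = list(fn = function(p, pr) .eedp(p), uses_logistic = FALSE),
  tpc_pssm   = list(fn = function(p, pr) .tpc_pssm(p), uses_logistic = TRUE),
  aadp_pssm  = list(fn = function(p, pr)
    c(stats::setNames(column_average_transform(p), paste0("aac.", AA20)),
      stats::setNames(dipeptide_transform(p),
                      paste0("dpc.", .pair_names()))),
    uses_logistic = FALSE),
  rpssm      = list(fn = function(p, pr) .rpssm(p), uses_logistic = FALSE),
  pse_pssm   = list(fn = function(p, pr) .pse_pssm(p, pr$xi),
                    uses_logistic = TRUE),
  tri_gram   = list(fn = function(p, pr) .tri_gram(p), uses_logistic = TRUE),
  pssm_ac    = list(fn = function(p, pr) autocovariance_transform(p, pr$nlag),
                    uses_logistic = FALSE),
  pssm_cc    = list(fn = function(p, pr) .pssm_cc(p, pr$nlag),
                    uses_logistic = FALSE)
)

#' Default PSSM-transform registry
#'
#' The ordered list of 18 length-independent PSSM transforms computed by
#' \code{\link{compute_all_pssm}}, parameterized (bigram separation k = 2,
#' smoothing window 7, pseudo-PSSM xi = 2, autocovariance nlag = 20,
#' cross-covariance nlag = 17) so the concatenated vector has exactly 18,730
#' dimensions. Each entry records whether the transform maps scores to
#' probabilities with the logistic function. Membership is a reconstruction
#' from the classical PSSM descriptor suites; the per-transform definitions
#' and the pinned total are the contract.
#'
#' @return object of class \code{descriptor_registry} (kind \code{"pssm"}).
#' @export
default_pssm_registry <- function() {
  e <- function(name, transform, dim, params = list(), min_len = 3L,
                uses_logistic = FALSE) {
    list(name = name, family = transform, dim = as.integer(dim),
         params = params, min_len = as.integer(min_len),
         uses_logistic = uses_logistic)
  }
  entries <- list(
    e("aac_pssm", "aac_pssm", 20L, min_len = 1L),
    e("d_fpssm", "d_fpssm", 20L, min_len = 1L),
    e("edp", "edp", 20L, min_len = 3L),
    e("smoothed", "smoothed", 20L, params = list(window = 7L), min_len = 1L),
    e("ab_pssm", "ab_pssm", 400L, min_len = 20L),
    e("composition", "composition", 400L, min_len = 1L),
    e("rpm_pssm", "rpm_pssm", 400L, min_len = 1L),
    e("s_fpssm", "s_fpssm", 400L, min_len = 1L),
    e("dpc_pssm", "dpc_pssm", 400L, min_len = 2L),
    e("ksb_pssm", "ksb_pssm", 400L, params = list(k = 2L), min_len = 3L),
    e("eedp", "eedp", 400L, min_len = 3L),
    e("tpc_pssm", "tpc_pssm", 400L, min_len = 2L, uses_logistic = TRUE),
    e("aadp_pssm", "aadp_pssm", 420L, min_len = 2L),
    e("rpssm", "rpssm", 110L, min_len = 2L),
    e("pse_pssm", "pse_pssm", 60L, params = list(xi = 2L), min_len = 3L,
      uses_logistic = TRUE),
    e("tri_gram", "tri_gram", 8000L, min_len = 3L, uses_logistic = TRUE),
    e("pssm_ac", "pssm_ac", 400L, params = list(nlag = 20L), min_len = 21L),
    e("pssm_cc", "pssm_cc", 6460L, params = list(nlag = 17L), min_len = 18L)
  )
  structure(entries, class = "descriptor_registry", kind = "pssm")
}

#' Compute all PSSM-derived descriptors of a profile
#'
#' Concatenates every transform in the registry, in registry order, with
#' family-tagged column names \code{pssm.<transform>.<element>}. Deterministic:
#' identical profiles give bit-identical vectors.
#'
#' @param profile a \code{\link{pssm_profile}}.
#' @param registry a \code{descriptor_registry};
#'   \code{\link{default_pssm_registry}()} by default (18,730 dims).
#' @return named numeric vector.
#' @export
compute_all_pssm <- function(profile, registry = default_pssm_registry()) {
  L <- nrow(profile$scores)
  out <- vector("list", length(registry))
  for (i in seq_along(registry)) {
    e <- registry[[i]]
    if (L < e$min_len)
      stop(sprintf("profile '%s' (length %d) is shorter than the minimum %d required by transform '%s'",
                   profile$id, L, e$min_len, e$name))
    tr <- .PSSM_TRANSFORMS[[e$family]]
    if (is.null(tr)) stop(sprintf("unknown PSSM transform '%s'", e$family))
    v <- tr$fn(profile, e$params)
    if (length(v) != e$dim)
      stop(sprintf("transform '%s' returned %d dims, registry declares %d",
                   e$name, length(v), e$dim))
    names(v) <- paste0("pssm.", e$name, ".", names(v))
    out[[i]] <- v
  }
  unlist(out)
}
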