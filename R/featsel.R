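# Feature cleaning, univariate and model-based feature ranking, and
# construction of the per-family weighted candidate feature sets.

#' Construct a feature matrix
#'
#' A feature matrix is a numeric matrix with unique row ids, unique column
#' names, no missing values, and a family tag per column derived from the
#' column-name prefix (\code{physchem.} or \code{pssm.}).
#'
#' @param X numeric matrix with rownames (ids) and colnames (features).
#' @return the validated matrix, with class \code{feature_matrix} and a
#'   \code{family} attribute.
#' @export
feature_matrix <- function(X) {
  if (!is.matrix(X) || !is.numeric(X)) stop("X must be a numeric matrix")
  if (nrow(X) < 1L) stop("feature matrix needs at least one row")
  if (is.null(rownames(X)) || anyDuplicated(rownames(X)))
    stop("feature matrix needs unique row ids")
  if (is.null(colnames(X)) || anyDuplicated(colnames(X)))
    stop("feature matrix needs unique column names")
  if (anyNA(X)) stop("feature matrix contains missing values")
  fam <- ifelse(startsWith(colnames(X), "pssm."), "pssm",
                ifelse(startsWith(colnames(X), "physchem."), "physchem",
                       "other"))
  structure(X, family = fam, class = c("feature_matrix", class(X)))
}

#' Family tag of each feature column
#'
#' @param X a \code{\link{feature_matrix}}.
#' @return character vector (\code{"physchem"}, \code{"pssm"} or
#'   \code{"other"}), one per column.
#' @export
feature_family <- function(X) {
  fam <- attr(X, "family")
  if (is.null(fam))
    fam <- ifelse(startsWith(colnames(X), "pssm."), "pssm",
                  ifelse(startsWith(colnames(X), "physchem."), "physchem",
                         "other"))
  fam
}

#' Featurize records and profiles into one concatenated matrix
#'
#' Rows are sequences; columns are the physicochemical block followed by the
#' PSSM block. Profiles are matched to records by id.
#'
#' @param records list of \code{\link{protein_record}}.
#' @param profiles optional named list of \code{\link{pssm_profile}} (names or
#'   \code{$id} matching record ids); if \code{NULL} only the physicochemical
#'   block is computed.
#' @param physchem_registry,pssm_registry descriptor registries.
#' @return a \code{\link{feature_matrix}}.
#' @export
featurize <- function(records, profiles = NULL,
                      physchem_registry = default_physchem_registry(),
                      pssm_registry = default_pssm_registry()) {
  ids <- vapply(records, function(r) r$id, character(1))
  phys <- t(vapply(records, function(r)
    compute_all_physchem(r, physchem_registry),
    numeric(registry_dims(physchem_registry))))
  rownames(phys) <- ids
  if (is.null(profiles)) return(feature_matrix(phys))
  prof_ids <- vapply(profiles, function(p) p$id, character(1))
  missing_prof <- setdiff(ids, prof_ids)
  if (length(missing_prof) > 0L)
    stop(sprintf("no PSSM profile for record(s): %s",
                 paste(utils::head(missing_prof, 5L), collapse = ", ")))
  profiles <- profiles[match(ids, prof_ids)]
  ev <- t(vapply(profiles, function(p) compute_all_pssm(p, pssm_registry),
                 numeric(registry_dims(pssm_registry))))
  rownames(ev) <- ids
  feature_matrix(cbind(phys, ev))
}

#' Binarize substrate counts into promiscuity labels
#'
#' An enzyme is labelled promiscuous (positive, 1) when it hydrolyzes at least
#' \code{threshold} of the 96 tested substrates.
#'
#' @param counts named integer vector of substrate counts in \code{[0, 96]}.
#' @param threshold promiscuity boundary (default 20; the boundary itself is
#'   positive).
#' @return named integer vector of 0/1 labels.
#' @export
label_from_counts <- function(counts, threshold = 20L) {
  if (any(is.na(counts)) || any(counts < 0L) || any(counts > 96L))
    stop("substrate counts must lie in [0, 96]")
  stats::setNames(as.integer(counts >= threshold), names(counts))
}

#' Drop near-constant feature columns
#'
#' Removes every column whose single most frequent value occupies more than
#' \code{max_identical_frac} of the rows. Column order is otherwise preserved;
#' the operation is idempotent.
#'
#' @param X a \code{\link{feature_matrix}} with at least two rows.
#' @param max_identical_frac drop threshold on the modal-value fraction.
#' @return the cleaned \code{\link{feature_matrix}}.
#' @export
clean_features <- function(X, max_identical_frac = 0.9) {
  if (nrow(X) < 2L) stop("cleaning requires at least two rows")
  modal_frac <- apply(X, 2L, function(col) max(tabulate(match(col, unique(col)))) / length(col))
  keep <- modal_frac <= max_identical_frac
  if (!any(keep))
    stop("all feature columns were dropped by cleaning; lower max_identical_frac")
  feature_matrix(X[, keep, drop = FALSE])
}

# ---------------------------------------------------------------------------
# discretization + information measures (filter methods)

# equal-frequency binning (default 5 bins); low-cardinality columns keep
# their own levels
.bin_equal_freq <- function(x, bins = 5L) {
  ux <- unique(x)
  if (length(ux) <= bins) return(match(x, sort(ux)))
  qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1L),
                               names = FALSE, type = 7))
  if (length(qs) < 3L) return(match(x, sort(ux))[seq_along(x)] * 0L + 1L)
  findInterval(x, qs[-c(1L, length(qs))]) + 1L
}

.bin_equal_width <- function(x, bins = 5L) {
  ux <- unique(x)
  if (length(ux) <= bins) return(match(x, sort(ux)))
  r <- range(x)
  if (r[1] == r[2]) return(rep(1L, length(x)))
  cut_points <- seq(r[1], r[2], length.out = bins + 1L)[-c(1L, bins + 1L)]
  findInterval(x, cut_points) + 1L
}

# joint counts of two small integer codes, via tabulate (fast path: these
# run tens of thousands of times inside the greedy selectors)
.joint_counts <- function(bx, by) {
  nx <- max(bx); ny <- max(by)
  matrix(tabulate((by - 1L) * nx + bx, nbins = nx * ny), nx, ny)
}

.mi_from_bins <- function(bx, y) {
  tab <- .joint_counts(bx, y + 1L)
  n <- sum(tab)
  px <- rowSums(tab) / n; py <- colSums(tab) / n
  p <- tab / n
  e <- outer(px, py)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / e[nz]))
}

.chi2_from_bins <- function(bx, y) {
  tab <- .joint_counts(bx, y + 1L)
  tab <- tab[rowSums(tab) > 0L, , drop = FALSE]
  if (nrow(tab) < 2L) return(0)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

.fisher_score <- function(x, y) {
  cls <- unique(y)
  mu <- mean(x)
  num <- 0; den <- 0
  for (c in cls) {
    xc <- x[y == c]
    num <- num + length(xc) * (mean(xc) - mu)^2
    den <- den + length(xc) * stats::var(xc) * (length(xc) - 1) / length(xc)
  }
  if (den == 0) return(0)
  num / den
}

# conditional mutual information I(X;S|Y) from binned vectors
.cmi_given_y <- function(bx, bs, y) {
  out <- 0
  for (c in unique(y)) {
    sel <- y == c
    out <- out + mean(sel) * .mi_from_bins(bx[sel], bs[sel])
  }
  out
}

#' Feature-selection method registry
#'
#' @return character vector of the supported ranking method identifiers.
#' @export
featsel_methods <- function() {
  c("chi-square", "information-gain", "mutual-information", "fisher-score",
    "mRMR", "CIFE", "RFE-linear", "RFE-svc", "random-forest-importance",
    "boosted-tree-importance")
}

#' Rank features by relevance to a binary label
#'
#' Filter methods (chi-square, information-gain, mutual-information,
#' fisher-score, mRMR, CIFE) use binned statistics; wrapper methods
#' (RFE-linear, RFE-svc) recursively eliminate by fitted coefficient
#' magnitude; embedded methods (random-forest-importance,
#' boosted-tree-importance) rank by fitted-model importances. Rankings are
#' deterministic given \code{seed}; importance ties are broken by column
#' order. The returned score is non-increasing along the ranking (for greedy
#' and recursive methods it is a rank-derived score).
#'
#' @param method one of \code{\link{featsel_methods}()}.
#' @param X a \code{\link{feature_matrix}} (the training slice only).
#' @param y binary 0/1 labels, one per row; both classes must be present.
#' @param seed integer seed for the stochastic methods.
#' @param greedy_depth number of greedy steps for mRMR/CIFE before falling
#'   back to relevance ordering for the tail.
#' @return data.frame with columns \code{name}, \code{score}, ordered best
#'   first.
#' @export
rank_features <- function(method, X, y, seed = 1L, greedy_depth = 60L) {
  if (!method %in% featsel_methods())
    stop(sprintf("unknown method '%s'; available: %s", method,
                 paste(featsel_methods(), collapse = ", ")))
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("both classes must be present for ranking")
  if (length(y) != nrow(X)) stop("labels must match rows of X")
  p <- ncol(X)
  nms <- colnames(X)

  order_by_score <- function(score) {
    ord <- order(-score, seq_len(p))
    data.frame(name = nms[ord], score = score[ord],
               stringsAsFactors = FALSE)
  }
  # greedy orders get a strictly decreasing surrogate score
  order_as_rank <- function(ord) {
    data.frame(name = nms[ord], score = seq(p, 1), stringsAsFactors = FALSE)
  }

  if (method %in% c("chi-square", "information-gain", "mutual-information",
                    "fisher-score")) {
    score <- switch(method,
      "chi-square" = apply(X, 2L, function(x)
        .chi2_from_bins(.bin_equal_freq(x), y)),
      "information-gain" = apply(X, 2L, function(x)
        .mi_from_bins(.bin_equal_width(x), y)),
      "mutual-information" = apply(X, 2L, function(x)
        .mi_from_bins(.bin_equal_freq(x), y)),
      "fisher-score" = apply(X, 2L, function(x) .fisher_score(x, y)))
    return(order_by_score(unname(score)))
  }

  if (method %in% c("mRMR", "CIFE")) {
    B <- apply(X, 2L, .bin_equal_freq)        # n x p binned matrix
    rel <- vapply(seq_len(p), function(j) .mi_from_bins(B[, j], y),
                  numeric(1))
    depth <- min(greedy_depth, p)
    selected <- integer(0)
    remaining <- seq_len(p)
    red_sum <- numeric(p)                     # sum of MI(f; s) over selected
    syn_sum <- numeric(p)                     # sum of CMI(f; s | y)
    for (step in seq_len(depth)) {
      crit <- if (length(selected) == 0L) rel[remaining] else {
        if (method == "mRMR")
          rel[remaining] - red_sum[remaining] / length(selected)
        else
          rel[remaining] - red_sum[remaining] + syn_sum[remaining]
      }
      pick <- remaining[order(-crit, remaining)[1]]
      selected <- c(selected, pick)
      remaining <- setdiff(remaining, pick)
      if (length(remaining) == 0L) break
      for (j in remaining) {
        red_sum[j] <- red_sum[j] + .mi_from_bins(B[, j], B[, pick])
        if (method == "CIFE")
          syn_sum[j] <- syn_sum[j] + .cmi_given_y(B[, j], B[, pick], y)
      }
    }
    tail_ord <- remaining[order(-rel[remaining], remaining)]
    return(order_as_rank(c(selected, tail_ord)))
  }

  if (method %in% c("RFE-linear", "RFE-svc")) {
    Xs <- scale(X)
    Xs[, apply(X, 2L, stats::sd) == 0] <- 0
    active <- seq_len(p)
    eliminated <- integer(0)
    yf <- factor(y)
    while (length(active) > 1L) {
      w <- if (method == "RFE-linear") {
        fit <- .ridge_fit(Xs[, active, drop = FALSE], y, lambda = 1)
        abs(fit$w)
      } else {
        fit <- e1071::svm(Xs[, active, drop = FALSE], yf, kernel = "linear",
                          cost = 1, scale = FALSE)
        abs(as.vector(crossprod(fit$coefs, fit$SV)))
      }
      drop_n <- max(1L, floor(length(active) * 0.2))
      drop_n <- min(drop_n, length(active) - 1L)
      ord <- order(w, active)                 # weakest first, ties by column
      dropped <- active[ord[seq_len(drop_n)]]
      # within a round the stronger of the dropped rank ahead
      eliminated <- c(rev(dropped), eliminated)
      active <- setdiff(active, dropped)
    }
    return(order_as_rank(c(active, eliminated)))
  }

  if (method == "random-forest-importance") {
    fit <- ranger::ranger(x = unclass(X), y = factor(y),
                          importance = "impurity", num.trees = 500L,
                          seed = seed, num.threads = 1L)
    imp <- fit$variable.importance[nms]
    imp[is.na(imp)] <- 0
    return(order_by_score(unname(imp)))
  }

  # boosted-tree-importance
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(unclass(X)[, , drop = FALSE], label = y)
  fit <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                          max_depth = 3L, eta = 0.3,
                                          nthread = 1L, seed = seed),
                            data = dtrain, nrounds = 50L, verbose = 0)
  imp_tab <- xgboost::xgb.importance(model = fit)
  score <- stats::setNames(rep(0, p), nms)
  score[imp_tab$Feature] <- imp_tab$Gain
  order_by_score(unname(score))
}

#' Build weighted per-family candidate feature sets
#'
#' For each ranking method and each (dimension, pssm-fraction) variant, ranks
#' the physicochemical and PSSM feature blocks independently on the training
#' slice, takes the per-family quotas (PSSM quota rounded up), and
#' concatenates. Every set must stay below the overfitting cap of half the
#' training-sample count.
#'
#' @param X training-slice \code{\link{feature_matrix}}.
#' @param y binary labels for the rows of \code{X}.
#' @param methods ranking methods; default all ten.
#' @param variants data.frame with columns \code{dims} and \code{pssm_frac};
#'   default six dimension variants \{20, 25, 30, 40, 50, 55\} at PSSM
#'   fraction 0.75.
#' @param cap maximum allowed set size (exclusive); default half of
#'   \code{nrow(X)}.
#' @param seed integer seed.
#' @return list of \code{feature_set} objects (one per method x variant), each
#'   with \code{method}, \code{dims}, \code{columns}, \code{family_counts}.
#' @export
build_feature_sets <- function(X, y, methods = featsel_methods(),
                               variants = default_variants(),
                               cap = floor(nrow(X) / 2), seed = 1L) {
  stopifnot(all(c("dims", "pssm_frac") %in% names(variants)))
  if (any(variants$dims >= cap))
    stop(sprintf("variant dimension(s) %s exceed the cap of %d (< half the training samples)",
                 paste(variants$dims[variants$dims >= cap], collapse = ", "),
                 cap))
  fam <- feature_family(X)
  phys_cols <- which(fam == "physchem")
  pssm_cols <- which(fam == "pssm")
  out <- list()
  for (m in methods) {
    rank_phys <- if (length(phys_cols) > 0L)
      rank_features(m, feature_matrix(X[, phys_cols, drop = FALSE]), y,
                    seed = seed)$name else character(0)
    rank_pssm <- if (length(pssm_cols) > 0L)
      rank_features(m, feature_matrix(X[, pssm_cols, drop = FALSE]), y,
                    seed = seed)$name else character(0)
    for (vi in seq_len(nrow(variants))) {
      dims <- variants$dims[vi]
      frac <- variants$pssm_frac[vi]
      n_pssm <- as.integer(min(ceiling(dims * frac), length(rank_pssm)))
      n_phys <- as.integer(min(dims - n_pssm, length(rank_phys)))
      cols <- c(utils::head(rank_pssm, n_pssm), utils::head(rank_phys, n_phys))
      fs <- structure(list(
        method = m,
        dims = length(cols),
        target_dims = as.integer(dims),
        columns = cols,
        family_counts = c(pssm = n_pssm, physchem = n_phys),
        label = sprintf("%s_%d", m, dims)),
        class = "feature_set")
      out[[fs$label]] <- fs
    }
  }
  out
}

#' Default feature-set dimension variants
#'
#' Six total-dimension variants at an evolutionary-feature (PSSM) fraction of
#' 0.75, reflecting the larger weight given to PSSM-derived descriptors.
#'
#' @return data.frame with columns \code{dims} and \code{pssm_frac}.
#' @export
default_variants <- function() {
  data.frame(dims = c(20L, 25L, 30L, 40L, 50L, 55L), pssm_frac = 0.75)
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %s: %d columns (pssm %d, physchem %d)\n",
              x$label, x$dims, x$family_counts["pssm"],
              x$family_counts["physchem"]))
  invisible(x)
}

#' Write a feature-set manifest
#'
#' Plain text: a header block (method, dims, family counts) as comment lines,
#' then one selected column name per line.
#'
#' @param fs a \code{feature_set}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_feature_set <- function(fs, path) {
  hdr <- c(sprintf("# method: %s", fs$method),
           sprintf("# dims: %d", fs$dims),
           sprintf("# pssm: %d", fs$family_counts["pssm"]),
           sprintf("# physchem: %d", fs$family_counts["physchem"]))
  writeLines(c(hdr, fs$columns), path)
  invisible(path)
}

#' Read a feature-set manifest written by \code{\link{write_feature_set}}
#'
#' @param path manifest path.
#' @return a \code{feature_set}.
#' @export
read_feature_set <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  cols <- lines[!startsWith(lines, "#") & nzchar(lines)]
  get <- function(key) sub(sprintf("^# %s: ", key), "",
                           grep(sprintf("^# %s:", key), hdr, value = TRUE)[1])
  structure(list(method = get("method"),
                 dims = length(cols),
                 target_dims = as.integer(get("dims")),
                 columns = cols,
                 family_counts = c(pssm = as.integer(get("pssm")),
                                   physchem = as.integer(get("physchem"))),
                 label = sprintf("%s_%s", get("method"), get("dims"))),
            class = "feature_set")
}
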