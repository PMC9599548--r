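# Length-independent physicochemical descriptor families computed from the
# amino-acid sequence alone. Every family maps a sequence of any length to a
# fixed-dimension named vector; the default registry concatenates to 2274
# dimensions. Positions holding the unknown residue X are excluded from all
# counts and windows, so denominators use the number of valid residues or
# windows rather than the raw length.

# residue indices (1..20 in alphabetical order, NA for X) for a record
.seq_idx <- function(record) {
  stopifnot(inherits(record, "protein_record"))
  ch <- strsplit(record$sequence, "", fixed = TRUE)[[1]]
  match(ch, AA20)
}

.freqs <- function(idx) {
  n <- tabulate(idx[!is.na(idx)], nbins = 20L)
  total <- sum(n)
  if (total == 0L) stop("sequence has no canonical residues")
  stats::setNames(n / total, AA20)
}

#' Amino-acid composition
#'
#' Frequency of each of the 20 canonical residues; entries sum to 1.
#'
#' @param record a \code{\link{protein_record}}.
#' @return named 20-vector of frequencies.
#' @export
aac <- function(record) {
  .freqs(.seq_idx(record))
}

# valid overlapping k-windows: start positions where all k residues canonical
.kmer_codes <- function(idx, k) {
  L <- length(idx)
  if (L < k) stop(sprintf("sequence shorter than k = %d", k))
  starts <- seq_len(L - k + 1L)
  code <- rep(0L, length(starts))
  ok <- rep(TRUE, length(starts))
  for (j in seq_len(k)) {
    v <- idx[starts + j - 1L]
    ok <- ok & !is.na(v)
    v[is.na(v)] <- 1L
    code <- code * 20L + (v - 1L)
  }
  code[ok] + 1L   # 1-based codes over 20^k cells
}

.kmer_names <- function(k) {
  g <- do.call(expand.grid,
               c(rev(replicate(k, AA20, simplify = FALSE)),
                 list(stringsAsFactors = FALSE)))
  apply(g[, rev(seq_len(k)), drop = FALSE], 1, paste, collapse = "")
}

#' Overlapping k-mer (di/tripeptide) composition
#'
#' Counts of overlapping k-mers normalized by the number of valid windows,
#' so the vector sums to 1.
#'
#' @param record a \code{\link{protein_record}}.
#' @param k word size, 2 (400 dims) or 3 (8000 dims).
#' @return named frequency vector of length \code{20^k}.
#' @export
kmer_composition <- function(record, k = 2L) {
  if (!k %in% c(2L, 3L)) stop("k must be 2 or 3")
  idx <- .seq_idx(record)
  codes <- .kmer_codes(idx, k)
  counts <- tabulate(codes, nbins = 20L^k)
  total <- sum(counts)
  v <- if (total > 0L) counts / total else rep(0, 20L^k)
  stats::setNames(v, .kmer_names(k))
}

# dipeptide deviation from expected mean, using codon multiplicities
.dde <- function(record) {
  idx <- .seq_idx(record)
  codes <- .kmer_codes(idx, 2L)
  N <- length(codes)
  if (N < 1L) stop("sequence too short for dipeptide statistics")
  Dc <- tabulate(codes, nbins = 400L) / N
  ca <- CODON_COUNTS[AA20] / 61
  # expected frequency of dipeptide (a, b); symmetric, so storage order-safe
  Tm <- as.vector(t(outer(ca, ca)))
  Tv <- Tm * (1 - Tm) / N
  v <- (Dc - Tm) / sqrt(Tv)
  stats::setNames(v, .kmer_names(2L))
}

# 5-group composition helpers
.group_idx <- function(idx, groups) {
  map <- integer(20L)
  for (g in seq_along(groups)) map[match(groups[[g]], AA20)] <- g
  out <- map[idx]
  out[is.na(idx)] <- NA_integer_
  out
}

.grouped_kmers <- function(idx, groups, k, gap = 0L) {
  gidx <- .group_idx(idx, groups)
  ng <- length(groups)
  L <- length(gidx)
  span <- (k - 1L) * (gap + 1L) + 1L
  if (L < span) stop(sprintf("sequence shorter than window span %d", span))
  starts <- seq_len(L - span + 1L)
  code <- rep(0L, length(starts)); ok <- rep(TRUE, length(starts))
  for (j in seq_len(k)) {
    v <- gidx[starts + (j - 1L) * (gap + 1L)]
    ok <- ok & !is.na(v)
    v[is.na(v)] <- 1L
    code <- code * ng + (v - 1L)
  }
  counts <- tabulate(code[ok] + 1L, nbins = ng^k)
  total <- sum(counts)
  if (total > 0L) counts / total else rep(0, ng^k)
}

.group_names <- function(groups, k) {
  nm <- names(groups)
  g <- do.call(expand.grid,
               c(rev(replicate(k, nm, simplify = FALSE)),
                 list(stringsAsFactors = FALSE)))
  apply(g[, rev(seq_len(k)), drop = FALSE], 1, paste, collapse = ".")
}

.gaac <- function(record) {
  idx <- .seq_idx(record)
  v <- .grouped_kmers(idx, AA_GROUPS5, 1L)
  stats::setNames(v, names(AA_GROUPS5))
}

.gdpc <- function(record) {
  idx <- .seq_idx(record)
  stats::setNames(.grouped_kmers(idx, AA_GROUPS5, 2L),
                  .group_names(AA_GROUPS5, 2L))
}

.gtpc <- function(record) {
  idx <- .seq_idx(record)
  stats::setNames(.grouped_kmers(idx, AA_GROUPS5, 3L),
                  .group_names(AA_GROUPS5, 3L))
}

.cksaagp <- function(record, gap) {
  idx <- .seq_idx(record)
  v <- .grouped_kmers(idx, AA_GROUPS5, 2L, gap = gap)
  stats::setNames(v, paste0("g", gap, ".", .group_names(AA_GROUPS5, 2L)))
}

# class index sequence (1/2/3, NA for X) under one CTD property partition
.ctd_classes <- function(idx, partition) {
  map <- integer(20L)
  for (ci in seq_along(partition)) map[match(partition[[ci]], AA20)] <- ci
  if (any(map == 0L)) stop("property partition does not cover all 20 letters")
  out <- map[idx]
  out[is.na(idx)] <- NA_integer_
  out
}

#' Composition/transition/distribution descriptors
#'
#' For each physicochemical property partition (three residue classes):
#' the three class compositions; the three unordered inter-class transition
#' frequencies among adjacent residue pairs; and, per class, five distribution
#' landmarks (position of the first, 25\%, 50\%, 75\% and last occurrence,
#' as a fraction of the sequence length). Absent classes yield zeros.
#'
#' @param record a \code{\link{protein_record}}.
#' @param property_partitions named list of partitions, each a named list of
#'   three character vectors covering the 20 letters. Defaults to the classical
#'   seven-property set.
#' @param parts which blocks to compute: any of \code{"C"}, \code{"T"},
#'   \code{"D"}.
#' @return named numeric vector.
#' @export
ctd_features <- function(record, property_partitions = CTD_PARTITIONS,
                         parts = c("C", "T", "D")) {
  idx <- .seq_idx(record)
  L <- length(idx)
  if (L < 2L) stop("CTD features require sequence length >= 2")
  out <- numeric(0)
  for (pname in names(property_partitions)) {
    cls <- .ctd_classes(idx, property_partitions[[pname]])
    valid <- !is.na(cls)
    nv <- sum(valid)
    cls_names <- names(property_partitions[[pname]])
    if ("C" %in% parts) {
      comp <- tabulate(cls[valid], nbins = 3L) / nv
      names(comp) <- paste0(pname, ".comp.", cls_names)
      out <- c(out, comp)
    }
    if ("T" %in% parts) {
      a <- cls[-L]; b <- cls[-1L]
      ok <- !is.na(a) & !is.na(b)
      npairs <- sum(ok)
      tr <- c(sum(ok & ((a == 1 & b == 2) | (a == 2 & b == 1))),
              sum(ok & ((a == 1 & b == 3) | (a == 3 & b == 1))),
              sum(ok & ((a == 2 & b == 3) | (a == 3 & b == 2))))
      tr <- if (npairs > 0L) tr / npairs else rep(0, 3L)
      names(tr) <- paste0(pname, ".trans.",
                          c(paste0(cls_names[1], "_", cls_names[2]),
                            paste0(cls_names[1], "_", cls_names[3]),
                            paste0(cls_names[2], "_", cls_names[3])))
      out <- c(out, tr)
    }
    if ("D" %in% parts) {
      for (ci in 1:3) {
        pos <- which(!is.na(cls) & cls == ci)
        n <- length(pos)
        d <- if (n == 0L) rep(0, 5L) else
          pos[c(1L, ceiling(0.25 * n), ceiling(0.5 * n),
                ceiling(0.75 * n), n)] / L
        names(d) <- paste0(pname, ".dist.", cls_names[ci], ".",
                           c("first", "p25", "p50", "p75", "last"))
        out <- c(out, d)
      }
    }
  }
  out
}

# conjoint triad over the Shen 7-class alphabet
.ctriad <- function(record) {
  idx <- .seq_idx(record)
  if (length(idx) < 3L) stop("conjoint triad requires sequence length >= 3")
  v <- .grouped_kmers(idx, stats::setNames(TRIAD_CLASSES, paste0("c", 1:7)),
                      3L)
  stats::setNames(v, .group_names(stats::setNames(TRIAD_CLASSES,
                                                  paste0("c", 1:7)), 3L))
}

#' Property autocorrelation descriptors
#'
#' Moran, Geary or normalized Moreau-Broto autocorrelation of per-residue
#' property scales (standardized to mean 0, sd 1 over the 20 letters) at lags
#' \code{1..nlag}. Zero-variance sequences (homopolymers) return 0 by
#' convention. Output length is \code{length(scales) * nlag}.
#'
#' @param record a \code{\link{protein_record}}.
#' @param scales named list of per-residue numeric scales (names = residues);
#'   defaults to the packaged eight-scale set.
#' @param nlag maximum lag; the number of valid residues must exceed it.
#' @param type one of \code{"moran"}, \code{"geary"}, \code{"moreau_broto"}.
#' @return named numeric vector of length \code{length(scales) * nlag}.
#' @export
autocorrelation_features <- function(record, scales = AA_SCALES, nlag = 18L,
                                     type = c("moran", "geary",
                                              "moreau_broto")) {
  type <- match.arg(type)
  idx <- .seq_idx(record)
  valid_n <- sum(!is.na(idx))
  if (valid_n <= nlag)
    stop(sprintf("autocorrelation requires more than nlag = %d valid residues",
                 nlag))
  out <- numeric(0)
  for (sname in names(scales)) {
    z20 <- standardize_scale(scales[[sname]][AA20])
    x <- z20[idx]                      # NA at X positions
    xv <- x[!is.na(x)]
    xbar <- mean(xv)
    devsq <- mean((xv - xbar)^2)
    vals <- numeric(nlag)
    for (d in seq_len(nlag)) {
      a <- x[seq_len(length(x) - d)]
      b <- x[seq_len(length(x) - d) + d]
      ok <- !is.na(a) & !is.na(b)
      if (!any(ok)) { vals[d] <- 0; next }
      vals[d] <- switch(type,
        moran = if (devsq > 0)
          mean((a[ok] - xbar) * (b[ok] - xbar)) / devsq else 0,
        geary = {
          ssd <- sum((xv - xbar)^2) / (length(xv) - 1L)
          if (ssd > 0) mean((a[ok] - b[ok])^2) / (2 * ssd) else 0
        },
        moreau_broto = mean(a[ok] * b[ok]))
    }
    names(vals) <- paste0(sname, ".lag", seq_len(nlag))
    out <- c(out, vals)
  }
  out
}

# mean squared scale-space distance between residues at lag d, per matrix
.soc_tau <- function(idx, dmat, nlag) {
  x <- idx
  vals <- numeric(nlag)
  for (d in seq_len(nlag)) {
    a <- x[seq_len(length(x) - d)]
    b <- x[seq_len(length(x) - d) + d]
    ok <- !is.na(a) & !is.na(b)
    vals[d] <- if (any(ok)) mean(dmat[cbind(a[ok], b[ok])]^2) else 0
  }
  vals
}

.socnumber <- function(record, nlag = 21L) {
  idx <- .seq_idx(record)
  if (sum(!is.na(idx)) <= nlag)
    stop("sequence-order coupling requires more valid residues than nlag")
  dm <- aa_distance_matrices()
  out <- numeric(0)
  for (mname in names(dm)) {
    tau <- .soc_tau(idx, dm[[mname]], nlag)
    names(tau) <- paste0(mname, ".tau", seq_len(nlag))
    out <- c(out, tau)
  }
  out
}

.qsorder <- function(record, nlag = 21L, w = 0.1) {
  idx <- .seq_idx(record)
  if (sum(!is.na(idx)) <= nlag)
    stop("quasi-sequence-order requires more valid residues than nlag")
  f <- .freqs(idx)
  dm <- aa_distance_matrices()
  out <- numeric(0)
  for (mname in names(dm)) {
    tau <- .soc_tau(idx, dm[[mname]], nlag)
    denom <- sum(f) + w * sum(tau)
    v <- c(f / denom, w * tau / denom)
    names(v) <- c(paste0(mname, ".", AA20),
                  paste0(mname, ".tau", seq_len(nlag)))
    out <- c(out, v)
  }
  out
}

# pseudo amino-acid composition (type I), three-property correlation
.paac <- function(record, lambda = 21L, w = 0.05) {
  idx <- .seq_idx(record)
  if (sum(!is.na(idx)) <= lambda)
    stop("pseudo amino-acid composition requires more valid residues than lambda")
  props <- lapply(AA_SCALES[c("hydropathy", "hydrophilicity", "mass")],
                  function(s) standardize_scale(s[AA20]))
  theta <- numeric(lambda)
  for (d in seq_len(lambda)) {
    a <- idx[seq_len(length(idx) - d)]
    b <- idx[seq_len(length(idx) - d) + d]
    ok <- !is.na(a) & !is.na(b)
    theta[d] <- if (any(ok))
      mean(Reduce(`+`, lapply(props, function(z)
        (z[a[ok]] - z[b[ok]])^2)) / length(props)) else 0
  }
  f <- .freqs(idx)
  denom <- 1 + w * sum(theta)
  v <- c(f / denom, w * theta / denom)
  names(v) <- c(AA20, paste0("theta", seq_len(lambda)))
  v
}

# amphiphilic pseudo amino-acid composition (type II)
.apaac <- function(record, lambda = 21L, w = 0.05) {
  idx <- .seq_idx(record)
  if (sum(!is.na(idx)) <= lambda)
    stop("amphiphilic pseudo composition requires more valid residues than lambda")
  h1 <- standardize_scale(AA_SCALES$hydropathy[AA20])
  h2 <- standardize_scale(AA_SCALES$hydrophilicity[AA20])
  tau <- numeric(2L * lambda)
  for (d in seq_len(lambda)) {
    a <- idx[seq_len(length(idx) - d)]
    b <- idx[seq_len(length(idx) - d) + d]
    ok <- !is.na(a) & !is.na(b)
    tau[2L * d - 1L] <- if (any(ok)) mean(h1[a[ok]] * h1[b[ok]]) else 0
    tau[2L * d]      <- if (any(ok)) mean(h2[a[ok]] * h2[b[ok]]) else 0
  }
  f <- .freqs(idx)
  denom <- 1 + w * sum(abs(tau))   # |tau|: keeps the denominator positive
  v <- c(f / denom, w * tau / denom)
  names(v) <- c(AA20,
                paste0(rep(c("h1", "h2"), lambda), ".tau",
                       rep(seq_len(lambda), each = 2L)))
  v
}

# ---------------------------------------------------------------------------
# registry

.PHYSCHEM_FAMILIES <- list(
  aac       = list(fn = function(r, p) aac(r), dim = 20L),
  dpc       = list(fn = function(r, p) kmer_composition(r, 2L), dim = 400L),
  dde       = list(fn = function(r, p) .dde(r), dim = 400L),
  gaac      = list(fn = function(r, p) .gaac(r), dim = 5L),
  gdpc      = list(fn = function(r, p) .gdpc(r), dim = 25L),
  gtpc      = list(fn = function(r, p) .gtpc(r), dim = 125L),
  cksaagp   = list(fn = function(r, p) .cksaagp(r, p$gap), dim = 25L),
  ctdc      = list(fn = function(r, p) ctd_features(r, parts = "C"), dim = 21L),
  ctdt      = list(fn = function(r, p) ctd_features(r, parts = "T"), dim = 21L),
  ctdd      = list(fn = function(r, p) ctd_features(r, parts = "D"), dim = 105L),
  ctriad    = list(fn = function(r, p) .ctriad(r), dim = 343L),
  moran     = list(fn = function(r, p)
    autocorrelation_features(r, nlag = p$nlag, type = "moran"), dim = NA),
  geary     = list(fn = function(r, p)
    autocorrelation_features(r, nlag = p$nlag, type = "geary"), dim = NA),
  nmbroto   = list(fn = function(r, p)
    autocorrelation_features(r, nlag = p$nlag, type = "moreau_broto"), dim = NA),
  socnumber = list(fn = function(r, p) .socnumber(r, p$nlag), dim = NA),
  qsorder   = list(fn = function(r, p) .qsorder(r, p$nlag), dim = NA),
  paac      = list(fn = function(r, p) .paac(r, p$lambda), dim = NA),
  apaac     = list(fn = function(r, p) .apaac(r, p$lambda), dim = NA)
)

.registry_entry <- function(name, family, dim, params = list(), min_len = 2L) {
  list(name = name, family = family, dim = as.integer(dim), params = params,
       min_len = as.integer(min_len))
}

#' Default sequence-descriptor registry
#'
#' The ordered list of length-independent physicochemical descriptor families
#' computed by \code{\link{compute_all_physchem}}. The default membership and
#' parameters (autocorrelation nlag = 18 over eight scales; sequence-order
#' nlag / lambda = 21) are pinned so the concatenated vector has exactly 2274
#' dimensions. The registry is data: pass a subset or a modified registry to
#' compute alternative descriptor sets.
#'
#' NOTE: the family membership is a reconstruction from the classical
#' descriptor suites; only the per-family definitions and the pinned total are
#' contractual.
#'
#' @return object of class \code{descriptor_registry}: a list of entries with
#'   \code{name}, \code{family}, \code{dim}, \code{params}, \code{min_len}.
#' @export
default_physchem_registry <- function() {
  entries <- list(
    .registry_entry("aac", "aac", 20L),
    .registry_entry("dpc", "dpc", 400L),
    .registry_entry("dde", "dde", 400L),
    .registry_entry("gaac", "gaac", 5L),
    .registry_entry("gdpc", "gdpc", 25L),
    .registry_entry("gtpc", "gtpc", 125L)
  )
  for (g in 0:5)
    entries[[length(entries) + 1L]] <-
      .registry_entry(paste0("cksaagp", g), "cksaagp", 25L,
                      params = list(gap = g), min_len = g + 2L)
  entries <- c(entries, list(
    .registry_entry("ctdc", "ctdc", 21L),
    .registry_entry("ctdt", "ctdt", 21L),
    .registry_entry("ctdd", "ctdd", 105L),
    .registry_entry("ctriad", "ctriad", 343L, min_len = 3L),
    .registry_entry("moran", "moran", 8L * 18L, params = list(nlag = 18L),
                    min_len = 19L),
    .registry_entry("geary", "geary", 8L * 18L, params = list(nlag = 18L),
                    min_len = 19L),
    .registry_entry("nmbroto", "nmbroto", 8L * 18L, params = list(nlag = 18L),
                    min_len = 19L),
    .registry_entry("socnumber", "socnumber", 2L * 21L,
                    params = list(nlag = 21L), min_len = 22L),
    .registry_entry("qsorder", "qsorder", 2L * (20L + 21L),
                    params = list(nlag = 21L), min_len = 22L),
    .registry_entry("paac", "paac", 20L + 21L, params = list(lambda = 21L),
                    min_len = 22L),
    .registry_entry("apaac", "apaac", 20L + 2L * 21L,
                    params = list(lambda = 21L), min_len = 22L)
  ))
  structure(entries, class = "descriptor_registry", kind = "physchem")
}

#' @export
print.descriptor_registry <- function(x, ...) {
  cat(sprintf("<descriptor_registry> kind=%s, %d entries, %d dimensions\n",
              attr(x, "kind"), length(x), registry_dims(x)))
  for (e in x)
    cat(sprintf("  %-12s dim=%5d min_len=%d\n", e$name, e$dim, e$min_len))
  invisible(x)
}

#' Total output dimension of a registry
#'
#' @param registry a \code{descriptor_registry}.
#' @return integer total of the per-entry dimensions.
#' @export
registry_dims <- function(registry) {
  sum(vapply(registry, function(e) e$dim, integer(1)))
}

#' Subset a registry by entry name
#'
#' @param registry a \code{descriptor_registry}.
#' @param names entry names to keep, in registry order.
#' @return the restricted registry.
#' @export
registry_subset <- function(registry, names) {
  keep <- Filter(function(e) e$name %in% names, registry)
  if (length(keep) == 0L) stop("no registry entries match the requested names")
  structure(keep, class = "descriptor_registry", kind = attr(registry, "kind"))
}

#' Compute all physicochemical descriptors of a sequence
#'
#' Concatenates every family in the registry, in registry order, with
#' family-tagged column names \code{physchem.<family>.<element>}.
#'
#' @param record a \code{\link{protein_record}}.
#' @param registry a \code{descriptor_registry};
#'   \code{\link{default_physchem_registry}()} by default (2274 dims).
#' @return named numeric vector.
#' @export
compute_all_physchem <- function(record, registry = default_physchem_registry()) {
  L <- nchar(record$sequence)
  out <- vector("list", length(registry))
  for (i in seq_along(registry)) {
    e <- registry[[i]]
    if (L < e$min_len)
      stop(sprintf("sequence '%s' (length %d) is shorter than the minimum %d required by family '%s'",
                   record$id, L, e$min_len, e$name))
    fam <- .PHYSCHEM_FAMILIES[[e$family]]
    if (is.null(fam)) stop(sprintf("unknown descriptor family '%s'", e$family))
    v <- fam$fn(record, e$params)
    if (length(v) != e$dim)
      stop(sprintf("family '%s' returned %d dims, registry declares %d",
                   e$name, length(v), e$dim))
    names(v) <- paste0("physchem.", e$name, ".", names(v))
    out[[i]] <- v
  }
  unlist(out)
}
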