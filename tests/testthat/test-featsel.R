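test_that("substrate counts binarize at the promiscuity threshold", {
  counts <- c(most = 72L, least = 1L, boundary = 20L, below = 19L)
  lab <- label_from_counts(counts)
  expect_identical(unname(lab), c(1L, 0L, 1L, 0L))
  expect_error(label_from_counts(c(a = -1L)), "\\[0, 96\\]")
  expect_error(label_from_counts(c(a = 97L)), "\\[0, 96\\]")
})

test_that("near-constant columns are dropped and cleaning is idempotent", {
  set.seed(1)
  X <- cbind(const = rep(1, 100),
             almost = c(rep(0, 95), rnorm(5)),
             balanced = rep(c(0, 1), 50),
             noisy = rnorm(100))
  rownames(X) <- sprintf("r%03d", 1:100)
  Xf <- feature_matrix(X)
  Xc <- clean_features(Xf, max_identical_frac = 0.9)
  expect_identical(colnames(Xc), c("balanced", "noisy"))
  expect_identical(colnames(clean_features(Xc, 0.9)), colnames(Xc))
  expect_error(clean_features(feature_matrix(
    matrix(1, 10, 2, dimnames = list(letters[1:10], c("a", "b"))))),
    "all feature columns")
})

test_that("chi-square ranking reproduces the 2x2 contingency statistic", {
  # 2-level feature perfectly matching balanced labels (3 vs 3)
  X <- feature_matrix(matrix(
    c(1, 1, 1, 0, 0, 0,
      0.3, -0.1, 0.25, 0.31, -0.05, 0.2),
    ncol = 2L, dimnames = list(paste0("s", 1:6), c("perfect", "noise"))))
  y <- c(1L, 1L, 1L, 0L, 0L, 0L)
  rk <- rank_features("chi-square", X, y)
  expect_identical(rk$name[1], "perfect")
  expect_equal(rk$score[1], 6)

  # feature independent of labels by construction: identical value pattern
  # in both classes
  X2 <- feature_matrix(matrix(c(0, 1, 0, 1, 0, 1),
                              ncol = 1L,
                              dimnames = list(paste0("s", 1:6), "indep")))
  y2 <- c(1L, 1L, 1L, 0L, 0L, 0L)
  # class 1 has (0,1,0), class 0 has (1,0,1): chi-square of the 2x2 table
  tab <- table(c(0, 1, 0, 1, 0, 1), y2)
  ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic
  rk2 <- rank_features("chi-square", X2, y2)
  expect_equal(rk2$score[1], unname(ref))
})

test_that("chi-square and fisher scores match brute force on small matrices", {
  set.seed(33)
  X <- feature_matrix(matrix(sample(0:2, 100, replace = TRUE), 10L, 10L,
                             dimnames = list(paste0("r", 1:10),
                                             paste0("f", 1:10))))
  y <- rep(c(0L, 1L), 5L)
  rk <- rank_features("chi-square", X, y)
  for (j in colnames(X)) {
    ref <- suppressWarnings(
      stats::chisq.test(table(X[, j], y), correct = FALSE))$statistic
    expect_equal(rk$score[rk$name == j], unname(ref))
  }

  rkf <- rank_features("fisher-score", X, y)
  for (j in colnames(X)) {
    x <- X[, j]
    mu <- mean(x)
    num <- sum(sapply(0:1, function(c) sum(y == c) * (mean(x[y == c]) - mu)^2))
    den <- sum(sapply(0:1, function(c) {
      xc <- x[y == c]; length(xc) * mean((xc - mean(xc))^2)
    }))
    expect_equal(rkf$score[rkf$name == j], num / den)
  }
})

test_that("information rankings recover a planted column", {
  set.seed(7)
  n <- 200L
  y <- rep(c(0L, 1L), each = 100L)
  X <- matrix(rnorm(n * 30L), n, 30L,
              dimnames = list(sprintf("s%03d", 1:n), paste0("f", 1:30)))
  X[, "f7"] <- X[, "f7"] + 2 * y          # planted signal
  X <- feature_matrix(X)
  for (m in c("mutual-information", "information-gain", "mRMR", "CIFE")) {
    rk <- rank_features(m, X, y, seed = 7L)
    expect_true("f7" %in% rk$name[1:3], label = m)
  }
  # scores are monotone non-increasing along the ranking
  rk <- rank_features("mutual-information", X, y)
  expect_true(all(diff(rk$score) <= 1e-12))
})

test_that("wrapper and embedded rankings find the planted column and are deterministic", {
  set.seed(9)
  n <- 80L
  y <- rep(c(0L, 1L), each = 40L)
  X <- matrix(rnorm(n * 15L), n, 15L,
              dimnames = list(sprintf("s%03d", 1:n), paste0("f", 1:15)))
  X[, "f3"] <- X[, "f3"] + 2.5 * y
  X <- feature_matrix(X)
  for (m in c("RFE-linear", "RFE-svc", "random-forest-importance",
              "boosted-tree-importance")) {
    rk1 <- rank_features(m, X, y, seed = 5L)
    rk2 <- rank_features(m, X, y, seed = 5L)
    expect_identical(rk1, rk2)
    expect_true("f3" %in% rk1$name[1:3], label = m)
  }
  expect_error(rank_features("pca", X, y), "unknown method")
})

test_that("the feature-set protocol yields |methods| x |variants| capped sets", {
  sm <- small_planted()
  tr_ids <- rownames(sm$X)[1:40]
  Xtr <- feature_matrix(sm$X[tr_ids, , drop = FALSE])
  ytr <- sm$y[tr_ids]
  cap <- 20L

  sets <- build_feature_sets(Xtr, ytr,
                             methods = c("chi-square", "fisher-score"),
                             variants = data.frame(dims = c(8L, 12L, 16L),
                                                   pssm_frac = 0.75),
                             cap = cap, seed = 3L)
  expect_length(sets, 6L)
  for (fs in sets) {
    expect_lt(fs$dims, cap)
    expect_identical(sum(fs$family_counts), fs$dims)
    # PSSM quota rounded up
    expect_identical(unname(fs$family_counts["pssm"]),
                     as.integer(ceiling(fs$target_dims * 0.75)))
    expect_true(all(fs$columns %in% colnames(Xtr)))
    fam <- ifelse(startsWith(fs$columns, "pssm."), "pssm", "physchem")
    expect_identical(unname(table(fam)["pssm"]),
                     as.integer(fs$family_counts["pssm"]))
  }
  expect_error(build_feature_sets(Xtr, ytr, methods = "chi-square",
                                  variants = data.frame(dims = 30L,
                                                        pssm_frac = 0.75),
                                  cap = cap),
               "cap")
})

test_that("feature-set manifests round trip through their plain-text format", {
  sm <- small_planted()
  tr_ids <- rownames(sm$X)[1:40]
  sets <- build_feature_sets(feature_matrix(sm$X[tr_ids, , drop = FALSE]),
                             sm$y[tr_ids], methods = "chi-square",
                             variants = data.frame(dims = 10L,
                                                   pssm_frac = 0.75),
                             cap = 20L)
  f <- withr::local_tempfile(fileext = ".txt")
  write_feature_set(sets[[1]], f)
  back <- read_feature_set(f)
  expect_identical(back$columns, sets[[1]]$columns)
  expect_identical(back$method, sets[[1]]$method)
  expect_identical(back$family_counts, sets[[1]]$family_counts)
})
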