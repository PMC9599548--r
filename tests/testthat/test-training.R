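# independent oracle: explicit confusion counting + literal metric formulas
oracle_metrics <- function(pred, truth) {
  TP <- 0; TN <- 0; FP <- 0; FN <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) TP <- TP + 1
    if (pred[i] == 0 && truth[i] == 0) TN <- TN + 1
    if (pred[i] == 1 && truth[i] == 0) FP <- FP + 1
    if (pred[i] == 0 && truth[i] == 1) FN <- FN + 1
  }
  Pr <- if (FP + TP == 0) 0 else TP / (FP + TP)
  Re <- if (FN + TP == 0) 0 else TP / (FN + TP)
  F1 <- if (Pr + Re == 0) 0 else 2 * Pr * Re / (Pr + Re)
  den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  MCC <- if (den == 0) 0 else (TP * TN - FP * FN) / sqrt(den)
  list(TP = TP, TN = TN, FP = FP, FN = FN, Pr = Pr, Re = Re, F1 = F1,
       MCC = MCC)
}

test_that("metrics equal exhaustive confusion-matrix enumeration (length <= 4)", {
  for (n in 1:4) {
    grid <- expand.grid(rep(list(0:1), 2L * n))
    for (g in seq_len(nrow(grid))) {
      v <- as.integer(grid[g, ])
      pred <- v[seq_len(n)]; truth <- v[n + seq_len(n)]
      got <- score_predictions(pred, truth)
      ref <- oracle_metrics(pred, truth)
      expect_equal(got[c("TP", "TN", "FP", "FN")],
                   ref[c("TP", "TN", "FP", "FN")],
                   ignore_attr = TRUE)
      expect_equal(unlist(got[c("Pr", "Re", "F1", "MCC")]),
                   unlist(ref[c("Pr", "Re", "F1", "MCC")]))
    }
  }
})

test_that("the worked confusion example gives MCC = 10/sqrt(600)", {
  pred <- c(rep(1, 4), rep(0, 6))
  truth <- c(rep(1, 3), 0, 1, 1, rep(0, 4))   # TP=3 FP=1 FN=2 TN=4
  s <- score_predictions(pred, truth)
  expect_identical(c(s$TP, s$FP, s$FN, s$TN), c(3L, 1L, 2L, 4L))
  expect_equal(s$Pr, 0.75)
  expect_equal(s$Re, 0.6)
  expect_equal(s$F1, 2 / 3)
  expect_equal(s$MCC, 10 / sqrt(600))
})

test_that("metric identities hold: perfection, inversion, symmetry, F1", {
  s <- score_predictions(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
                         c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0))
  expect_equal(c(s$Pr, s$Re, s$F1, s$MCC), rep(1, 4))

  s_inv <- score_predictions(c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1),
                             c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0))
  expect_equal(s_inv$MCC, -1)

  set.seed(2)
  for (i in 1:20) {
    pred <- sample(0:1, 12, replace = TRUE)
    truth <- sample(0:1, 12, replace = TRUE)
    a <- score_predictions(pred, truth)
    b <- score_predictions(1L - pred, 1L - truth)   # class-label swap
    expect_equal(a$MCC, b$MCC)
    if (a$Pr > 0 && a$Re > 0)
      expect_equal(a$F1, 2 / (1 / a$Pr + 1 / a$Re))
  }

  # constant predictor scores 0 under the zero-denominator convention
  expect_equal(score_predictions(rep(1, 6), c(1, 0, 1, 0, 1, 0))$MCC, 0)
  expect_error(score_predictions(c(1, 0), c(1, 0, 1)), "length")
})

test_that("split plans are stratified, reproducible and distinct per repeat", {
  set.seed(100)
  y <- stats::setNames(c(rep(1L, 58), rep(0L, 87)), sprintf("e%03d", 1:145))
  plan <- make_splits(y, seed = 42L)
  for (r in 1:5) {
    tr <- plan$repeats[[r]]$train; te <- plan$repeats[[r]]$test
    expect_length(tr, 116L)
    expect_length(te, 29L)
    expect_length(intersect(tr, te), 0L)
    expect_setequal(c(tr, te), names(y))
    expect_identical(sum(y[te]), 12L)   # round(0.2 * 58) positives
  }
  expect_identical(make_splits(y, seed = 42L), plan)
  test_sets <- lapply(plan$repeats, function(r) sort(r$test))
  expect_gt(length(unique(test_sets)), 1L)
  expect_error(make_splits(c(a = 1L, b = 1L, c = 0L)), "5 samples per class")
})

test_that("hyperparameter tuning is deterministic and honors single-point grids", {
  sm <- small_planted()
  cols <- colnames(sm$X)[1:10]
  tr <- rownames(sm$X)[1:40]
  grid1 <- data.frame(lambda = 0.5)
  m <- tune_and_train("ridge", feature_matrix(sm$X[tr, , drop = FALSE]),
                      sm$y[tr], cols, grid = grid1, seed = 2L)
  expect_equal(m$hyper$lambda, 0.5)

  m2 <- tune_and_train("ridge", feature_matrix(sm$X[tr, , drop = FALSE]),
                       sm$y[tr], cols, seed = 2L)
  m3 <- tune_and_train("ridge", feature_matrix(sm$X[tr, , drop = FALSE]),
                       sm$y[tr], cols, seed = 2L)
  expect_identical(m2$hyper, m3$hyper)
  expect_identical(m2$fit, m3$fit)
})

test_that("linearly separable data is fit perfectly by the tuned SVC", {
  set.seed(6)
  n <- 40L
  y <- rep(c(0L, 1L), each = n / 2L)
  X <- matrix(rnorm(n * 3L, sd = 0.3), n, 3L,
              dimnames = list(sprintf("p%02d", 1:n), c("a", "b", "c")))
  X[, "a"] <- X[, "a"] + 4 * y   # separable by construction
  Xf <- feature_matrix(X)
  m <- tune_and_train("svc", Xf, y, c("a", "b", "c"), seed = 1L)
  s <- score_predictions(predict(m, Xf), y)
  expect_equal(s$MCC, 1)
})

test_that("tuning and scaling never read held-out test rows", {
  sm <- small_planted()
  y <- sm$y
  plan <- make_splits(y, n_repeats = 1L, seed = 5L)
  te <- plan$repeats[[1]]$test
  y_perm <- y
  y_perm[te] <- rev(y[te])   # scramble only the held-out labels

  fs <- colnames(sm$X)[1:8]
  ev1 <- evaluate_over_splits("ridge", sm$X, y, fs, plan)
  ev2 <- evaluate_over_splits("ridge", sm$X, y_perm, fs, plan)
  expect_identical(ev1$models[[1]]$fit, ev2$models[[1]]$fit)
  expect_identical(ev1$models[[1]]$center, ev2$models[[1]]$center)
})

test_that("split evaluation aggregates five repeats and recovers planted signal", {
  sm <- small_planted()
  plan <- make_splits(sm$y, seed = 9L)
  sets <- build_feature_sets(
    feature_matrix(sm$X[plan$repeats[[1]]$train, , drop = FALSE]),
    sm$y[plan$repeats[[1]]$train], methods = "chi-square",
    variants = data.frame(dims = 10L, pssm_frac = 0.75),
    cap = floor(length(plan$repeats[[1]]$train) / 2), seed = 9L)
  ev <- evaluate_over_splits("ridge", sm$X, sm$y, sets[[1]], plan)
  expect_length(ev$test_reports, 5L)
  mccs <- vapply(ev$test_reports, function(s) s$MCC, numeric(1))
  expect_equal(ev$mean_test_mcc, mean(mccs))
  expect_gte(ev$mean_test_mcc, 0.8)   # strong planted signal, n = 50
  for (r in 1:5)
    expect_identical(ev$models[[r]]$repeat_id, r)
})

test_that("knn prediction supports uniform and distance weighting", {
  X <- matrix(c(0, 0.1, 0.2, 10, 10.1, 10.2), ncol = 1,
              dimnames = list(paste0("t", 1:6), "f"))
  y <- c(0L, 0L, 0L, 1L, 1L, 1L)
  Xf <- feature_matrix(X)
  for (w in c("uniform", "distance")) {
    m <- tune_and_train("knn", Xf, y, "f",
                        grid = data.frame(k = 3L, weights = w,
                                          stringsAsFactors = FALSE),
                        seed = 1L, inner_folds = 2L)
    q <- matrix(c(-1, 11), ncol = 1, dimnames = list(c("a", "b"), "f"))
    expect_identical(unname(predict(m, q)), c(0L, 1L))
  }
})
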