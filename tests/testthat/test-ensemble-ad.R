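test_that("member selection honors quotas, MCC order and the repeat tie-break", {
  pool <- list()
  for (a in c("svc", "ridge", "knn"))
    for (r in 1:5)
      pool[[paste(a, r)]] <- constant_direction_classifier(
        "f1", w = 1, algorithm = a,
        test_mcc = c(0.5, 0.9, 0.7, 0.9, 0.6)[r], repeat_id = r)
  ens <- select_members(pool, quota = c(svc = 2L, ridge = 3L, knn = 2L))
  expect_length(ens$members, 7L)
  svc_members <- Filter(function(m) m$algorithm == "svc", ens$members)
  # MCC 0.9 tie between repeats 2 and 4: lower repeat id wins first slot
  expect_identical(unname(vapply(svc_members, function(m) m$repeat_id,
                                 numeric(1))), c(2, 4))
  ridge_members <- Filter(function(m) m$algorithm == "ridge", ens$members)
  expect_identical(unname(vapply(ridge_members, function(m) m$test_mcc,
                                 numeric(1))), c(0.9, 0.9, 0.7))

  expect_error(select_members(pool[1:4], quota = c(svc = 2L, ridge = 3L,
                                                   knn = 2L)),
               "quota unsatisfiable")
  single <- select_members(pool["svc 1"], quota = c(svc = 1L))
  expect_length(single$members, 1L)
})

test_that("unanimous consensus labels only full agreement", {
  X <- feature_matrix(matrix(c(2, -2, 0.5), ncol = 1,
                             dimnames = list(c("q1", "q2", "q3"), "f1")))
  up <- constant_direction_classifier("f1", w = 1)     # positive iff f1 > 0
  down <- constant_direction_classifier("f1", w = -1)  # inverted

  agree <- ensemble_model(list(up, up, up))
  cons <- consensus_predict(agree, X)
  expect_identical(cons$label, c("positive", "negative", "positive"))

  mixed <- ensemble_model(list(up, up, down))
  cons <- consensus_predict(mixed, X)
  expect_identical(unique(cons$label), "abstain")

  solo <- ensemble_model(list(up))
  cons <- consensus_predict(solo, X)
  expect_identical(as.integer(cons$label == "positive"),
                   unname(predict(up, X)))

  expect_error(consensus_predict(agree, feature_matrix(
    matrix(1, 1, 1, dimnames = list("q", "other")))), "f1")
})

test_that("abstention is non-decreasing as members are added", {
  set.seed(8)
  X <- feature_matrix(matrix(rnorm(60), 30, 2,
                             dimnames = list(sprintf("q%02d", 1:30),
                                             c("f1", "f2"))))
  m1 <- constant_direction_classifier("f1", w = 1)
  m2 <- constant_direction_classifier("f2", w = 1)
  m3 <- constant_direction_classifier(c("f1", "f2"), w = c(1, -1))
  members <- list(m1, m2, m3)
  abst <- sapply(1:3, function(k) {
    cons <- consensus_predict(ensemble_model(members[seq_len(k)]), X)
    sum(cons$label == "abstain")
  })
  expect_true(all(diff(abst) >= 0))
  # consensus equals every member on non-abstained samples
  cons <- consensus_predict(ensemble_model(members), X)
  votes <- attr(cons, "vote_matrix")
  kept <- cons$label != "abstain"
  for (j in 1:3)
    expect_identical(as.integer(cons$label[kept] == "positive"),
                     unname(votes[kept, j]))
})

test_that("the 1-D applicability-domain worked example holds", {
  X <- matrix(c(0, 1, 3), ncol = 1)
  ad <- fit_ad(X, k = 1L, Z = 0)
  expect_equal(ad$thresholds, c(1, 1, 2))
  expect_true(unname(ad_filter(ad, matrix(2, ncol = 1))))
  expect_false(unname(ad_filter(ad, matrix(6, ncol = 1))))
  expect_error(fit_ad(X, k = 3L), "smaller")
  expect_error(ad_filter(ad, matrix(1, 1, 2)), "expects")
})

test_that("duplicated training rows give zero thresholds; permutation invariance", {
  X <- matrix(c(0, 0, 5), ncol = 1)
  ad <- fit_ad(X, k = 1L, Z = 0)
  expect_equal(ad$thresholds[1:2], c(0, 0))

  set.seed(3)
  M <- matrix(rnorm(40), 10, 4)
  perm <- sample(10)
  t1 <- fit_ad(M, k = 3L, Z = 0.5)$thresholds
  t2 <- fit_ad(M[perm, ], k = 3L, Z = 0.5)$thresholds
  expect_equal(sort(t1), sort(t2))
  expect_equal(t1[perm], t2)
})

test_that("training samples are self-reliable and far queries are rejected", {
  set.seed(14)
  M <- matrix(rnorm(100), 20, 5)
  ad <- fit_ad(M, k = 5L, Z = 0)
  expect_true(all(ad_filter(ad, M)))   # distinct rows, Z = 0

  far <- M + 10 * matrix(apply(M, 2, stats::sd), 20, 5, byrow = TRUE)
  expect_false(any(ad_filter(ad, far)))
})

test_that("scaler-carrying AD models project queries before distances", {
  set.seed(21)
  M <- matrix(rnorm(60, mean = 100, sd = 10), 20, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  ctr <- colMeans(M)
  scl <- apply(M, 2, stats::sd)
  Ms <- sweep(sweep(M, 2, ctr), 2, scl, "/")
  ad <- fit_ad(Ms, k = 3L, Z = 0.5, center = ctr, scale = scl)
  expect_true(all(ad_filter(ad, M)))   # raw queries, scaled internally
})

test_that("the ensemble is robust on planted data: consensus beats members", {
  sm <- small_planted()
  fit <- eppred(sm$X, sm$y,
                dims = c(svc = 8L, ridge = 8L, knn = 10L), seed = 11L)
  perf <- eppred_performance(fit)
  expect_lt(mean(perf$abstention_rate), 0.5)
  for (r in seq_along(perf$ensemble_mcc)) {
    te <- fit$plan$repeats[[r]]$test
    member_mcc <- vapply(fit$ensemble$members, function(m)
      score_predictions(predict(m, sm$X[te, , drop = FALSE]),
                        sm$y[te])$MCC, numeric(1))
    expect_gte(perf$ensemble_mcc[r], max(member_mcc) - 0.05)
  }
})
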