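test_that("HMMER tblout fixtures parse with their E-values", {
  f <- withr::local_tempfile(fileext = ".tbl")
  tab <- gen_hmm_hits_fixture(c("t1", "t2", "t3"),
                              significant_ids = c("t1", "t2"),
                              seed = 2L, path = f)
  hits <- parse_hmm_hits(f, "tblout")
  expect_setequal(hits$id, tab$id)
  expect_equal(hits$evalue[match(tab$id, hits$id)], tab$evalue,
               tolerance = 1e-6)
})

test_that("duplicate targets keep their best E-value; empty tables parse", {
  f <- withr::local_tempfile(fileext = ".tbl")
  writeLines(c(
    "# comment line",
    "dup - prof - 1e-04 12.0 0.0 1e-04 12.0 0.0 1 1 0 0 1 1 1 1 -",
    "dup - prof - 1e-12 40.0 0.0 1e-12 40.0 0.0 1 1 0 0 1 1 1 1 -",
    "oth - prof - 1e-06 20.0 0.0 1e-06 20.0 0.0 1 1 0 0 1 1 1 1 -"), f)
  hits <- parse_hmm_hits(f, "tblout")
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$evalue[hits$id == "dup"], 1e-12)

  writeLines("# only comments", f)
  expect_equal(nrow(parse_hmm_hits(f, "tblout")), 0L)
})

test_that("domtblout uses fields 7/8 and malformed lines name the line", {
  f <- withr::local_tempfile(fileext = ".domtbl")
  writeLines(
    "targ - 250 prof - 180 1e-15 50.2 0.0 1 1 1e-15 1e-15 50.0 0.0 5 170 10 175 8 178 0.95 -",
    f)
  hits <- parse_hmm_hits(f, "domtblout")
  expect_equal(hits$evalue, 1e-15)
  expect_equal(hits$score, 50.2)

  writeLines(c("ok - prof - 1e-04 12.0", "bad - prof -"), f)
  expect_error(parse_hmm_hits(f, "tblout"), ":2:")
})

test_that("the E-value pre-filter is exact and monotone in the cutoff", {
  hits <- data.frame(id = c("a", "b"), evalue = c(1e-12, 1e-8),
                     score = c(40, 20))
  expect_identical(hmm_prefilter(hits, 1e-10), "a")
  expect_identical(hmm_prefilter(hits, 1e-15), character(0))

  set.seed(10)
  hits5 <- data.frame(id = paste0("h", 1:5),
                      evalue = 10^stats::runif(5, -14, -6),
                      score = stats::runif(5, 10, 60))
  kept <- hmm_prefilter(hits5, 1e-10)
  expect_setequal(kept, hits5$id[hits5$evalue <= 1e-10])
  expect_identical(kept, kept[order(hits5$evalue[match(kept, hits5$id)])])

  cutoffs <- sort(10^stats::runif(6, -14, -6))
  sizes <- vapply(cutoffs, function(ct) length(hmm_prefilter(hits5, ct)),
                  numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("candidate ranking reproduces the worked intersection example", {
  # top-2 hydrophobicity = {A, B}; top-2 enclosure/exposure = {B, C}
  cavity <- data.frame(
    id = c("A", "B", "C", "D", "E"),
    hydrophobicity = c(0.9, 0.8, 0.3, 0.2, 0.1),
    enclosure = c(0.30, 0.80, 0.90, 0.20, 0.10),
    exposure = rep(1, 5),
    triad_ok = TRUE)
  hits <- data.frame(id = c("A", "B", "C", "D", "E"),
                     evalue = 10^-(20:16), score = 50:46)
  out <- rank_candidates(c("A", "B", "C", "D", "E"), hits, cavity,
                         n_shortlist = 5L, n_final = 1L)
  expect_identical(out$id, "B")
  expect_false(attr(out, "short"))
})

test_that("triad filtering, short sets and constant metrics behave as specified", {
  hits <- data.frame(id = paste0("c", 1:4), evalue = 10^-(15:12),
                     score = 40:37)
  cavity <- data.frame(id = paste0("c", 1:4),
                       hydrophobicity = c(0.4, 0.3, 0.2, 0.1),
                       enclosure = c(0.5, 0.6, 0.7, 0.8),
                       exposure = rep(1, 4),
                       triad_ok = FALSE)
  expect_warning(out <- rank_candidates(cavity$id, hits, cavity),
                 "triad")
  expect_equal(nrow(out), 0L)
  expect_true(attr(out, "short"))

  cavity$triad_ok <- TRUE
  expect_warning(out <- rank_candidates(cavity$id, hits, cavity,
                                        n_shortlist = 4L, n_final = 10L),
                 "returning all")
  expect_equal(nrow(out), 4L)

  # hydrophobicity constant: order is set by the ratio ranks
  cavity$hydrophobicity <- 0.5
  out <- rank_candidates(cavity$id, hits, cavity, n_shortlist = 4L,
                         n_final = 2L)
  expect_identical(out$id[1:2], c("c4", "c3"))   # highest enclosure first
})

test_that("ranking is invariant to input row order and checks cavity coverage", {
  set.seed(12)
  n <- 12L
  ids <- sprintf("x%02d", 1:n)
  hits <- data.frame(id = ids, evalue = 10^stats::runif(n, -20, -11),
                     score = stats::runif(n, 30, 60))
  cavity <- data.frame(id = ids,
                       hydrophobicity = stats::runif(n),
                       enclosure = stats::runif(n, 0.5, 0.9),
                       exposure = stats::runif(n, 0.3, 0.7),
                       triad_ok = rep(c(TRUE, TRUE, TRUE, FALSE), 3))
  out1 <- rank_candidates(ids, hits, cavity, n_shortlist = 10L, n_final = 3L)
  perm <- sample(n)
  out2 <- rank_candidates(ids[perm], hits[perm, ], cavity[rev(perm), ],
                          n_shortlist = 10L, n_final = 3L)
  expect_identical(out1, out2)

  expect_error(rank_candidates(ids, hits, cavity[-1, ],
                               n_shortlist = 10L, n_final = 3L),
               "missing for shortlisted")
  expect_error(rank_candidates(ids, hits, cavity[, -2]),
               "missing column")
})

test_that("profile building degrades explicitly without HMMER and self-hits with it", {
  msa <- withr::local_tempfile(fileext = ".fasta")
  db <- withr::local_tempfile(fileext = ".fasta")
  rec <- gen_protein(60L, seed = 31L, id = "seed1")
  msa_recs <- list(rec,
                   protein_record("seed2", rec$sequence),
                   protein_record("seed3", rec$sequence))
  write_fasta(msa_recs, msa)
  db_recs <- c(list(protein_record("target_hit", rec$sequence)),
               lapply(1:4, function(i) gen_protein(60L, seed = 100L + i,
                                                   id = paste0("bg", i))))
  write_fasta(db_recs, db)

  withr::with_envvar(c(PATH = tempdir()), {
    expect_error(build_profile_and_search(msa, db),
                 "external tool unavailable")
  })

  hits <- build_profile_and_search(msa, db)
  expect_true(nrow(hits) >= 1L)
  expect_identical(hits$id[1], "target_hit")

  empty_db <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty_db)
  expect_equal(nrow(build_profile_and_search(msa, empty_db)), 0L)
})
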