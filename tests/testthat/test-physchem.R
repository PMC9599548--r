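brute_aac <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  sapply(promisc:::AA20, function(a) sum(ch == a) / length(ch))
}

test_that("amino-acid composition equals direct letter counting", {
  expect_equal(unname(aac(protein_record("h", "AAAA"))),
               c(1, rep(0, 19)))
  v <- aac(protein_record("q", "ACDE"))
  expect_equal(unname(v[c("A", "C", "D", "E")]), rep(0.25, 4))
  expect_equal(sum(v), 1)

  rec <- gen_protein(200L, seed = 21L, id = "r200")
  expect_equal(aac(rec), brute_aac(rec$sequence))
})

test_that("k-mer composition counts overlapping words and normalizes", {
  v <- kmer_composition(protein_record("a", "AAA"), k = 2L)
  expect_equal(unname(v["AA"]), 1)
  expect_equal(sum(v), 1)

  v <- kmer_composition(protein_record("b", "ACAC"), k = 2L)
  expect_equal(unname(v[c("AC", "CA")]), c(2 / 3, 1 / 3))

  rec <- gen_protein(80L, seed = 2L, id = "s")
  expect_equal(sum(kmer_composition(rec, 2L)), 1)
  expect_equal(sum(kmer_composition(rec, 3L)), 1)
  expect_error(kmer_composition(protein_record("t", "AC"), k = 3L),
               "shorter")
})

test_that("k-mer composition matches brute-force enumeration on short sequences", {
  rec <- gen_protein(30L, seed = 5L, id = "bf")
  ch <- strsplit(rec$sequence, "")[[1]]
  words <- vapply(seq_len(length(ch) - 1L),
                  function(i) paste(ch[i:(i + 1L)], collapse = ""),
                  character(1))
  v <- kmer_composition(rec, 2L)
  for (w in unique(words))
    expect_equal(unname(v[w]), sum(words == w) / length(words))
  expect_equal(sum(v > 0), length(unique(words)))
})

test_that("CTD composition and transitions follow the class partitions", {
  # all residues in one hydrophobicity class
  v <- ctd_features(protein_record("p", "RKEDQN"), parts = c("C", "T"))
  expect_equal(unname(v["hydrophobicity.comp.polar"]), 1)
  expect_equal(unname(v["hydrophobicity.trans.polar_neutral"]), 0)

  # 10 A then 10 C: A neutral, C hydrophobic -> single transition 1/19
  blocks <- paste0(strrep("A", 10), strrep("C", 10))
  v <- ctd_features(protein_record("b", blocks))
  expect_equal(unname(v["hydrophobicity.trans.neutral_hydrophobic"]), 1 / 19)
  expect_equal(unname(v["hydrophobicity.trans.polar_neutral"]), 0)
  expect_equal(unname(v["hydrophobicity.trans.polar_hydrophobic"]), 0)

  # distribution landmarks of an absent class are all zero
  expect_true(all(v[grepl("hydrophobicity.dist.polar", names(v))] == 0))
  # distribution of the first class: first occurrence at position 1
  expect_equal(unname(v["hydrophobicity.dist.neutral.first"]), 1 / 20)
  expect_equal(unname(v["hydrophobicity.dist.neutral.last"]), 10 / 20)
})

test_that("autocorrelation honors the zero-variance convention and brute force", {
  v <- autocorrelation_features(protein_record("h", strrep("A", 30)),
                                nlag = 4L)
  expect_true(all(v == 0))
  expect_length(v, length(promisc:::AA_SCALES) * 4L)

  # strictly alternating sequence: Moran lag-1 must be negative and equal
  # to the direct formula
  rec <- protein_record("alt", strrep("AV", 15))
  v <- autocorrelation_features(rec, nlag = 2L, type = "moran")
  z <- promisc:::standardize_scale(promisc:::AA_SCALES$hydropathy)
  x <- z[strsplit(rec$sequence, "")[[1]]]
  xbar <- mean(x)
  direct <- mean((x[-length(x)] - xbar) * (x[-1] - xbar)) /
    mean((x - xbar)^2)
  expect_lt(direct, 0)
  expect_equal(unname(v["hydropathy.lag1"]), direct)

  expect_error(autocorrelation_features(protein_record("s", "ACDEF"),
                                        nlag = 10L), "nlag")
})

test_that("the default physchem registry totals 2274 dimensions", {
  reg <- default_physchem_registry()
  expect_identical(registry_dims(reg), 2274L)
  rec <- gen_protein(100L, seed = 31L, id = "d")
  v <- compute_all_physchem(rec)
  expect_length(v, 2274L)
  expect_false(anyDuplicated(names(v)) > 0)
})

test_that("registry subsets, schema stability and length independence hold", {
  reg_aac <- registry_subset(default_physchem_registry(), "aac")
  rec <- gen_protein(100L, seed = 1L, id = "a")
  expect_length(compute_all_physchem(rec, reg_aac), 20L)

  rec2 <- gen_protein(100L, seed = 2L, id = "b")
  v1 <- compute_all_physchem(rec)
  v2 <- compute_all_physchem(rec2)
  expect_identical(names(v1), names(v2))
  expect_false(isTRUE(all.equal(v1, v2)))

  # same schema for different lengths (length-independence contract)
  v3 <- compute_all_physchem(gen_protein(250L, seed = 3L, id = "c"))
  expect_identical(names(v1), names(v3))
})

test_that("composition-family blocks lie in [0,1] and sum to one", {
  rec <- gen_protein(120L, seed = 8L, id = "comp")
  v <- compute_all_physchem(rec)
  for (fam in c("physchem.aac.", "physchem.dpc.", "physchem.gaac.",
                "physchem.gtpc.", "physchem.ctriad.")) {
    block <- v[startsWith(names(v), fam)]
    expect_true(all(block >= 0 & block <= 1))
    expect_equal(sum(block), 1)
  }
})

test_that("short sequences fail with the limiting family named", {
  rec <- protein_record("short", "ACDEFGHIKL")   # length 10
  expect_error(compute_all_physchem(rec), "moran|socnumber|nlag|minimum")
  # but a registry whose requirements it meets works
  v <- compute_all_physchem(rec, registry_subset(default_physchem_registry(),
                                                 c("aac", "dpc", "ctdc")))
  expect_length(v, 441L)
})

test_that("non-canonical residues are excluded from composition counts", {
  v1 <- aac(protein_record("x", "ACDXXE"))
  v2 <- aac(protein_record("y", "ACDE"))
  expect_equal(v1, v2)
})
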