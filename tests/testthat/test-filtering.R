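test_that("keyword exclusion drops flagged headers with the trigger", {
  rec <- make_records(c("A1", "A2", "A3"),
                      description = c("hypothetical protein",
                                      "FAD-dependent oxidoreductase",
                                      "Partial oxidoreductase"))
  res <- exclude_by_keywords(rec)
  expect_equal(res$dropped$accession, c("A1", "A3"))
  expect_equal(res$dropped$reason, c("hypothetical", "partial"))
  expect_equal(res$kept$accession, "A2")
})

test_that("keyword exclusion matches the generator's planted fraction", {
  fam <- simulate_family(simulation_config(n_sequences = 100, n_clades = 4,
                                           keyword_fraction = 0.1, seed = 21))
  res <- exclude_by_keywords(fam$records)
  expect_equal(nrow(res$dropped), sum(fam$truth$sequences$has_keyword))
  expect_setequal(res$dropped$accession,
                  fam$truth$sequences$accession[fam$truth$sequences$has_keyword])
})

test_that("length filter keeps the inclusive 420-460 window", {
  set.seed(1)
  lens <- c(419, 420, 430, 460, 461)
  rec <- make_records(sprintf("A%d", seq_along(lens)),
                      residues = vapply(lens, random_protein, ""))
  kept <- length_filter(rec)
  expect_equal(kept$accession, c("A2", "A3", "A4"))

  # brute-force recount on random lengths
  lens <- sample(400:480, 500, replace = TRUE)
  rec <- make_records(sprintf("B%03d", seq_along(lens)),
                      residues = vapply(lens, random_protein, ""))
  expect_equal(nrow(length_filter(rec)), sum(lens >= 420 & lens <= 460))
})

test_that("global alignment matches the forced identity cases", {
  expect_equal(global_align("ACDE", "ACDE")$identity, 1.0)
  expect_equal(global_align("ACDE", "ACDF")$identity, 0.75)
  expect_error(global_align("ACDE", "ACB1"), "non-amino-acid")
})

test_that("alignment scores equal the independent DP oracle", {
  set.seed(42)
  S <- blosum62()
  for (i in 1:30) {
    a <- random_protein(12)
    b <- random_protein(sample(8:14, 1))
    al <- global_align(a, b)
    expect_equal(al$score, nw_score_oracle(a, b, S), tolerance = 1e-9)
    # gap-stripping recovers the inputs
    expect_equal(gsub("-", "", al$aligned_a), a)
    expect_equal(gsub("-", "", al$aligned_b), b)
  }
})

test_that("alignment score agrees with Biostrings pairwiseAlignment", {
  set.seed(7)
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  for (i in 1:10) {
    a <- random_protein(40)
    b <- random_protein(38)
    al <- global_align(a, b)
    ref <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         substitutionMatrix = e$BLOSUM62,
                                         gapOpening = 11, gapExtension = 1)
    expect_equal(al$score, Biostrings::score(ref), tolerance = 1e-9)
  }
})

test_that("identity is symmetric and 1 on self", {
  set.seed(3)
  for (i in 1:10) {
    a <- random_protein(30)
    b <- random_protein(32)
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
  a <- random_protein(50)
  expect_equal(pairwise_identity(a, a), 1)
})

test_that("identity band keeps strictly inside (0.35, 0.97)", {
  set.seed(8)
  ref <- random_protein(430)
  # gapless mutants: identity is exactly 1 - k/430
  fracs <- c(0, 0.02, 0.05, 0.30, 0.50, 0.60, 0.70, 0.80)
  ks <- round(fracs * 430)
  rec <- make_records(sprintf("A%02d", seq_along(ks)),
                      residues = vapply(ks, function(k) mutate_exact(ref, k),
                                        ""))
  kept <- identity_band_filter(rec, ref)
  truth_id <- 1 - ks / 430
  expect_setequal(kept$accession,
                  rec$accession[truth_id > 0.35 & truth_id < 0.97])
  # the reference itself (identity 1) is excluded by the upper bound
  expect_false("A01" %in% kept$accession)
  ids <- attr(kept, "identity")
  expect_lt(max(abs(unname(ids) - truth_id)), 0.02)
})

test_that("filters commute", {
  set.seed(12)
  ref <- random_protein(430)
  lens <- sample(c(410, 425, 440, 465), 20, replace = TRUE)
  rec <- make_records(sprintf("A%02d", 1:20),
                      residues = vapply(lens, random_protein, ""),
                      description = sample(c("ok protein",
                                             "hypothetical protein"), 20,
                                           replace = TRUE))
  cfg <- filter_config(min_identity = 0)
  o1 <- identity_band_filter(
    length_filter(exclude_by_keywords(rec, cfg)$kept, cfg), ref, cfg)
  o2 <- exclude_by_keywords(
    length_filter(identity_band_filter(rec, ref, cfg), cfg), cfg)$kept
  expect_setequal(o1$accession, o2$accession)
})

test_that("estimated identity decreases monotonically with planted divergence", {
  set.seed(99)
  ref <- random_protein(200)
  ks <- sort(sample(2:120, 100))
  ids <- vapply(ks, function(k) pairwise_identity(mutate_exact(ref, k), ref),
                numeric(1))
  rho <- suppressWarnings(stats::cor(ks, ids, method = "spearman"))
  expect_lt(rho, -0.95)
})
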