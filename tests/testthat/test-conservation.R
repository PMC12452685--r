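col_msa <- function(...) {
  cols <- list(...)
  rows <- do.call(paste0, cols)
  protein_msa(stats::setNames(rows, paste0("r", seq_along(rows))))
}

test_that("column scores follow the 0-11 physicochemical scale", {
  props <- residue_properties()
  # absolute conservation
  t1 <- profile_columns(col_msa(c("V", "V", "V", "V")))
  expect_equal(t1$profiles$score, 11)
  # full property conservation despite residue variation
  t2 <- profile_columns(col_msa(c("V", "I", "L", "I")))
  expect_equal(t2$profiles$score, 10)
  # mixed-property column equals the brute-force intersection oracle
  t3 <- profile_columns(col_msa(c("D", "K", "D", "K")))
  expect_equal(t3$profiles$score,
               score_oracle(c("D", "K", "D", "K"), props))

  # random columns always agree with the oracle
  set.seed(13)
  for (i in 1:40) {
    chars <- sample(c(AA, "-"), 12, replace = TRUE,
                    prob = c(rep(1, 20), 4))
    tr <- profile_columns(col_msa(chars))
    expect_equal(tr$profiles$score, score_oracle(chars, props),
                 info = paste(chars, collapse = ""))
  }
})

test_that("gappy columns are penalized and counts are conserved", {
  tr <- profile_columns(col_msa(c("V", "V", "V", "-", "-")))
  expect_equal(tr$profiles$gap_count, 2)
  expect_lte(tr$profiles$score, 9)  # 10 properties uniform, -1 for gaps
  expect_equal(tr$profiles$gap_count + sum(tr$counts[AA_ALPHABET, 1]), 5)
  expect_error(profile_columns(protein_msa(character(0))))
})

test_that("modal frequencies include gap rows in the denominator", {
  tr <- profile_columns(col_msa(c("V", "V", "V", "V", "-")))
  expect_equal(tr$profiles$top_freq, 0.8)
  tr2 <- profile_columns(col_msa(c("V", "V", "I", "I", "-")))
  expect_equal(tr2$profiles$top2_freq, 0.8)
  expect_lte(tr2$profiles$top_freq, tr2$profiles$top2_freq)
})

test_that("replacing a residue by the modal residue never lowers the score", {
  set.seed(29)
  for (i in 1:30) {
    chars <- sample(c(AA, "-"), 10, replace = TRUE, prob = c(rep(1, 20), 3))
    tr <- profile_columns(col_msa(chars))
    modal <- tr$profiles$modal1
    s0 <- tr$profiles$score
    for (p in which(chars != "-" & chars != modal)) {
      chars2 <- chars
      chars2[p] <- modal
      s1 <- profile_columns(col_msa(chars2))$profiles$score
      expect_gte(s1, s0)
    }
  }
})

test_that("a fully conserved alignment yields one all-fixed motif", {
  row <- "VIGAGSVGLLWAACDEFGHI"
  msa <- protein_msa(stats::setNames(rep(row, 8), paste0("r", 1:8)))
  mots <- extract_motifs(profile_columns(msa))
  expect_equal(length(mots), 1)
  expect_equal(mots[[1]]$start_column, 1)
  expect_equal(mots[[1]]$end_column, 20)
  expect_true(all(vapply(mots[[1]]$tokens, function(t) t$type == "fixed",
                         logical(1))))
  expect_equal(render_motif(mots[[1]]),
               paste(strsplit(row, "")[[1]], collapse = "-"))
})

test_that("motif extraction recovers planted patterns token-equal", {
  km <- known_motifs()
  sim <- simulate_alignment(km[paste0("M", 1:8)], n_rows = 200,
                            n_cols = 400, conservation = 0.95, seed = 101)
  mots <- extract_motifs(profile_columns(sim$msa))
  expect_equal(length(mots), 8)
  for (i in 1:8)
    expect_true(motifs_equal(mots[[i]], sim$truth$patterns[[i]]))
  # blocks are disjoint and ordered
  starts <- vapply(mots, `[[`, 1L, "start_column")
  ends <- vapply(mots, `[[`, 1L, "end_column")
  expect_true(all(diff(starts) > 0))
  expect_true(all(ends[-8] < starts[-1]))
  # recovered at the planted offsets
  expect_equal(unname(starts), sim$truth$offsets)
})

test_that("uniform random alignments yield no motifs", {
  for (seed in 1:5) {
    set.seed(seed)
    rows <- vapply(rep(120, 200), random_protein, "")
    mots <- extract_motifs(profile_columns(protein_msa(rows)))
    expect_equal(length(mots), 0)
  }
})

test_that("PRM detector decomposes the printed composite spacing", {
  rep <- detect_prm("PAAAPAAAAAAPAAAAAPAAPAAAAAAAAPAAAP")
  expect_equal(rep$n_prolines, 7)
  expect_equal(rep$composite,
               "P-x-x-x-P-(x)6-P-(x)5-P-x-x-P-(x)8-P-x-x-x-P")
  expect_equal(sum(rep$submotifs$type == "PxxxP"), 2)
  expect_equal(sum(rep$submotifs$type == "PxxP"), 1)
  # the composite regenerates the proline spacings exactly
  expect_equal(prm_spacings(rep$composite), diff(rep$proline_columns) - 1)

  empty <- detect_prm("AAAAGGGG")
  expect_equal(empty$n_prolines, 0)
  expect_equal(empty$composite, "")
})

test_that("PRM detector recovers planted proline spacings from an alignment", {
  set.seed(55)
  spacing <- c(2, 5, 3, 7)
  pos <- cumsum(c(4, spacing + 1))
  n <- 150
  mat <- matrix(sample(setdiff(AA, "P"), n * 40, replace = TRUE), n, 40)
  for (p in pos) {
    keep <- runif(n) < 0.9
    mat[keep, p] <- "P"
  }
  msa <- protein_msa(apply(mat, 1, paste, collapse = ""))
  rep <- detect_prm(profile_columns(msa))
  expect_equal(rep$proline_columns, pos)
  expect_equal(prm_spacings(rep$composite), spacing)
})
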