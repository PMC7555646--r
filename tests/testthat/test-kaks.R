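codon_aln <- function(a, b) {
  structure(list(a = a, b = b, gene_a = "a", gene_b = "b"),
            class = "codon_alignment")
}

test_that("NG86 site and difference counts match hand values", {
  # TTT (Phe): 3rd-position T->C is synonymous; all others nonsyn -> S = 1/3
  aln <- codon_aln("TTT", "TTC")
  res <- ng86_kaks(aln)
  expect_equal(res$S, 1 / 3)
  expect_equal(res$N, 3 - 1 / 3)
  expect_equal(res$sd, 1)
  expect_equal(res$nd, 0)
  # JC on pS = 3: saturated -> ks NA
  expect_true(is.na(res$ks))
  expect_equal(res$ka, 0)
  expect_true(res$saturated)

  # a longer context where pS is small: 10 identical codons + the TTT/TTC pair
  pad <- rep("GGG", 10)             # Gly: 3rd position fully synonymous S=1
  res2 <- ng86_kaks(codon_aln(c(pad, "TTT"), c(pad, "TTC")))
  expect_equal(res2$S, 10 + 1 / 3)
  expect_equal(res2$sd, 1)
  p <- 1 / (10 + 1 / 3)
  expect_equal(res2$ks, -3 / 4 * log(1 - 4 / 3 * p))
  expect_equal(res2$ka, 0)
  expect_identical(res2$selection, "purifying")
})

test_that("NG86 agrees with the independent oracle on random codon pairs", {
  set.seed(41)
  sense <- setdiff(names(.ORACLE_GC), .ORACLE_STOPS)
  for (r in 1:15) {
    ca <- sample(sense, 25, replace = TRUE)
    cb <- ca
    mut <- sample(25, 6)
    cb[mut] <- sample(sense, 6, replace = TRUE)
    res <- ng86_kaks(codon_aln(ca, cb))
    want <- oracle_ng86(ca, cb)
    expect_equal(res$S, want$S, tolerance = 1e-12)
    expect_equal(res$N, want$N, tolerance = 1e-12)
    expect_equal(res$sd, want$sd, tolerance = 1e-12)
    expect_equal(res$nd, want$nd, tolerance = 1e-12)
    expect_equal(res$ks, want$ks, tolerance = 1e-12)
    expect_equal(res$ka, want$ka, tolerance = 1e-12)
  }
})

test_that("codon alignment drops gapped columns and validates input", {
  aln <- codon_align("MK-F", "M-AF",
                     cds_a = "ATGAAATTT", cds_b = "ATGGCCTTC")
  expect_identical(aln$a, c("ATG", "TTT"))
  expect_identical(aln$b, c("ATG", "TTC"))
  expect_error(codon_align("MKF", "MK", "ATGAAATTT", "ATGAAA"),
               "unequal lengths")
  expect_error(codon_align("MKF", "MKF", "ATGAAA", "ATGAAATTT"),
               "does not match")
  expect_error(codon_align("M*", "MK", "ATGTAA", "ATGAAA"), "stop")
})

test_that("divergence time and selection classes behave at the edges", {
  expect_equal(divergence_time(0.03, gamma = 1.5e-8), 1.0)   # 1 MYA
  expect_equal(divergence_time(0.6, gamma = 1.5e-8), 20.0)
  expect_true(is.na(divergence_time(NA_real_)))
  expect_identical(classify_selection(c(0.2, 1, 3, NA)),
                   c("purifying", "neutral", "positive", "undefined"))
  expect_identical(classify_selection(0.95, neutral_band = 0.1), "neutral")
})

test_that("Ks histogram uses half-open bins with exact-edge tolerance", {
  h <- ks_histogram(c(0.05, 0.1, 0.15, 0.3), bin_width = 0.1)
  expect_identical(h$count[h$bin_start == 0], 1L)
  expect_identical(h$count[abs(h$bin_start - 0.1) < 1e-12], 2L)  # 0.1 upper bin
  expect_identical(h$count[abs(h$bin_start - 0.3) < 1e-12], 1L)
  expect_message(h2 <- ks_histogram(c(0.05, NA)), "dropped")
  expect_identical(sum(h2$count), 1L)
})
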