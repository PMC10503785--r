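test_that("the genetic code table has 61 sense codons in TCAG order", {
  gc <- genetic_code()
  expect_length(gc$codons, 61)
  expect_equal(gc$codons[1:4], c("TTT", "TTC", "TTA", "TTG"))
  expect_false(any(gc$stop_codons %in% gc$codons))
  expect_setequal(gc$stop_codons, c("TAA", "TAG", "TGA"))
  expect_equal(unname(gc$aa), unname(Biostrings::GENETIC_CODE[gc$codons]))
})

test_that("codon pair classification matches the brute-force oracle", {
  gc <- genetic_code()
  labels <- c("syn_tv", "syn_ts", "nonsyn_tv", "nonsyn_ts")
  got <- matrix(NA_character_, 61, 61)
  got[gc$pairs[, c("i", "j")]] <- labels[gc$pairs[, "type"]]
  got[gc$pairs[, c("j", "i")]] <- labels[gc$pairs[, "type"]]
  want <- matrix(NA_character_, 61, 61)
  for (i in 1:61) {
    for (j in 1:61) {
      if (i != j) want[i, j] <- oracle_pair_class(gc$codons[i], gc$codons[j])
    }
  }
  expect_identical(got, want)
})

test_that("rate matrix obeys row sums, detailed balance and rate ratios", {
  pi <- equal_freqs()
  for (pars in list(c(1, 1), c(2, 0.5), c(5, 2), c(0.5, 0))) {
    Q <- build_rate_matrix(pars[1], pars[2], pi)
    expect_lt(max(abs(rowSums(Q))), 1e-12)
    pq <- as.numeric(pi) * unclass(Q)
    expect_lt(max(abs(pq - t(pq))), 1e-15)  # detailed balance
  }
  # kappa=2, omega=0.5: transition/synonymous vs transversion/nonsynonymous
  Qu <- build_rate_matrix(2, 0.5, pi, scale = FALSE)
  expect_equal(Qu["TTT", "TTC"] / Qu["TTT", "GTT"], (2 * 1) / (1 * 0.5))
  # kappa=1, omega=1, equal freqs: all allowed moves share one rate
  Q1 <- build_rate_matrix(1, 1, pi, scale = FALSE)
  off <- Q1[upper.tri(Q1)]
  expect_length(unique(round(off[off > 0], 14)), 1L)
  # omega=0 silences every nonsynonymous exchange
  Q0 <- build_rate_matrix(2, 0, pi, scale = FALSE)
  gc <- genetic_code()
  nonsyn <- gc$pairs[gc$pairs[, "type"] > 2, , drop = FALSE]
  expect_true(all(Q0[nonsyn[, c("i", "j")]] == 0))
  # mean rate 1 after scaling
  Qs <- build_rate_matrix(2, 0.5, pi)
  expect_equal(-sum(as.numeric(pi) * diag(Qs)), 1, tolerance = 1e-12)
})

test_that("invalid rate-matrix parameters are rejected", {
  pi <- equal_freqs()
  expect_error(build_rate_matrix(0, 0.5, pi), "kappa")
  expect_error(build_rate_matrix(2, -0.1, pi), "omega")
  expect_error(build_rate_matrix(2, 0.5, rep(1, 61)), "frequencies")
})

test_that("apply_k implements the selection-intensity exponent", {
  expect_equal(apply_k(0.2, 1), 0.2)
  expect_equal(apply_k(0.2, 0), 1)
  expect_equal(apply_k(0.25, 0.5), 0.5)
  expect_equal(apply_k(0, 0), 1)   # continuity convention
  expect_equal(apply_k(0, 2), 0)
  expect_error(apply_k(-1, 1), "nonnegative")
})

test_that("transition probabilities are stochastic and match the series oracle", {
  pi <- equal_freqs()
  Q <- build_rate_matrix(2.5, 0.3, pi)
  expect_equal(transition_probabilities(Q, 0), diag(61), ignore_attr = TRUE)
  Pinf <- transition_probabilities(Q, 500)
  expect_lt(max(abs(sweep(Pinf, 2, as.numeric(pi)))), 1e-6)
  for (t in c(0.01, 0.1, 0.7)) {
    P <- transition_probabilities(Q, t)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
    expect_true(all(P >= 0 & P <= 1 + 1e-12))
    expect_lt(max(abs(P - oracle_expm(Q, t))), 1e-8)
  }
  expect_error(transition_probabilities(Q, -1), "nonnegative")
})

test_that("frequency schemes are valid and respond to alignment content", {
  aln <- codon_alignment(c(A = "ATGAAATTT", B = "ATGAAGTTC",
                           C = "ATGCAATTT"))
  for (s in c("equal", "F1x4", "F3x4", "empirical")) {
    pi <- codon_frequencies(s, aln)
    expect_equal(sum(pi), 1, tolerance = 1e-12)
    expect_true(all(pi >= 0))
  }
  expect_equal(as.numeric(codon_frequencies("equal")), rep(1 / 61, 61))
  emp <- codon_frequencies("empirical", aln)
  expect_gt(emp["ATG"], emp["GGG"])  # observed codons outweigh unseen ones
})

test_that("in-frame stop codons are a hard error", {
  expect_error(codon_alignment(c(A = "ATGTAA", B = "ATGCAA")), "stop")
})
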