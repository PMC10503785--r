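test_that("single-tip and two-tip likelihoods match closed forms", {
  pi <- equal_freqs()
  gc <- genetic_code()
  spec <- codon_model_spec(2, 0.5, pi)
  # one tip: stationary probability of the observed codon
  tr1 <- tagged_tree(ape::read.tree(text = "(A:0.4,B:0.1);"))
  aln1 <- codon_alignment(c(A = "ATG", B = "---"))
  expect_equal(as.numeric(log_likelihood(tr1, aln1, spec)),
               log(1 / 61), tolerance = 1e-10)
  # two tips: direct summation over the root state
  aln2 <- codon_alignment(c(A = "ATG", B = "ACG"))
  Q <- build_rate_matrix(2, 0.5, pi)
  P1 <- transition_probabilities(Q, 0.4)
  P2 <- transition_probabilities(Q, 0.1)
  i <- match("ATG", gc$codons); j <- match("ACG", gc$codons)
  expect_equal(as.numeric(log_likelihood(tr1, aln2, spec)),
               log(sum(as.numeric(pi) * P1[, i] * P2[, j])),
               tolerance = 1e-10)
})

test_that("pruning equals exhaustive enumeration on small random instances", {
  set.seed(11)
  pi <- equal_freqs()
  for (rep in 1:12) {
    ntax <- sample(3:4, 1)
    phy <- ape::rtree(ntax, rooted = FALSE)
    phy$edge.length <- runif(nrow(phy$edge), 0.02, 0.5)
    tr <- tagged_tree(phy)
    spec <- codon_model_spec(runif(1, 1, 4), runif(1, 0.05, 1.5), pi)
    aln <- simulate_alignment(tr, spec, 4, seed = rep)
    ll <- as.numeric(log_likelihood(tr, aln, spec))
    trav <- selax:::tree_traversal(phy)
    Q <- build_rate_matrix(spec$kappa, spec$omega, pi)
    P_list <- lapply(trav$lengths, function(t) transition_probabilities(Q, t))
    states <- matrix(selax:::codon_index(as.vector(unclass(aln)[phy$tip.label, ])),
                     nrow = ntax)
    oracle <- sum(vapply(seq_len(ncol(states)), function(s) {
      oracle_site_loglik(trav, P_list, as.numeric(pi), states[, s])
    }, numeric(1)))
    expect_equal(ll, oracle, tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to taxon order and handles missing data", {
  pi <- equal_freqs()
  tr <- tree6(tag = FALSE)
  spec <- codon_model_spec(2, 0.4, pi)
  aln <- simulate_alignment(tr, spec, 60, seed = 5)
  ll <- log_likelihood(tr, aln, spec)
  perm <- codon_alignment(unclass(aln)[rev(rownames(aln)), ])
  expect_equal(as.numeric(log_likelihood(tr, perm, spec)), as.numeric(ll))
  # gapping a whole column in every taxon drops it without error
  m <- unclass(aln)
  m[, 3] <- "---"
  ll2 <- log_likelihood(tr, codon_alignment(m), spec)
  expect_equal(attr(ll2, "n_dropped"), 1L)
  # a partially gapped taxon acts as missing data, likelihood increases
  m2 <- unclass(aln)
  m2["t1", 1:10] <- "---"
  expect_gt(as.numeric(log_likelihood(tr, codon_alignment(m2), spec)),
            as.numeric(ll))
})

test_that("likelihood errors on taxon mismatch", {
  tr <- tree3()
  aln <- codon_alignment(c(A = "ATG", B = "ATG", X = "ATG"))
  expect_error(log_likelihood(tr, aln, codon_model_spec(2, 1, equal_freqs())),
               "absent")
})

test_that("site-category mixtures weight categories by their proportions", {
  pi <- equal_freqs()
  tr <- tree3()
  aln <- codon_alignment(c(A = "ATGAAA", B = "ATGAAG", C = "ATGCAA"))
  lls <- vapply(c(0.1, 1.0), function(w) {
    as.numeric(log_likelihood(tr, aln, codon_model_spec(2, w, pi)))
  }, numeric(1))
  mix <- codon_model_spec(2, list(omega = c(0.1, 1.0), probs = c(0.3, 0.7)),
                          pi)
  # per-site mixture of two single-omega models (sites are independent and
  # here each column is mixed identically)
  sitewise <- function(w) {
    vapply(1:2, function(s) {
      a1 <- codon_alignment(unclass(aln)[, s, drop = FALSE])
      as.numeric(log_likelihood(tr, a1, codon_model_spec(2, w, pi)))
    }, numeric(1))
  }
  expected <- sum(log(0.3 * exp(sitewise(0.1)) + 0.7 * exp(sitewise(1.0))))
  expect_equal(as.numeric(log_likelihood(tr, aln, mix)), expected,
               tolerance = 1e-10)
})

test_that("simulation respects degenerate regimes", {
  pi <- equal_freqs()
  tr <- tree6(tag = FALSE)
  # omega = 0: no nonsynonymous change anywhere
  a0 <- simulate_alignment(tr, codon_model_spec(2, 0, pi), 120, seed = 3)
  aa <- translate_alignment(a0)
  expect_true(all(apply(unclass(aa), 2, function(col) {
    length(unique(col)) == 1L
  })))
  # zero branch lengths: all sequences identical
  phy0 <- tr$phy; phy0$edge.length[] <- 0
  az <- simulate_alignment(tagged_tree(phy0), codon_model_spec(2, 1, pi),
                           50, seed = 4)
  expect_equal(nrow(unique(unclass(az))), 1L)
  # determinism
  s1 <- simulate_alignment(tr, codon_model_spec(2, 0.5, pi), 40, seed = 9)
  s2 <- simulate_alignment(tr, codon_model_spec(2, 0.5, pi), 40, seed = 9)
  expect_identical(unclass(s1), unclass(s2))
})

test_that("long equal-frequency simulations approach stationarity", {
  pi <- equal_freqs()
  tr <- tagged_tree(ape::read.tree(text = "(A:3,B:3);"))
  a <- simulate_alignment(tr, codon_model_spec(1, 1, pi), 4000, seed = 21)
  counts <- tabulate(selax:::codon_index(as.vector(unclass(a))), nbins = 61)
  n <- sum(counts)
  se <- sqrt(n * (1 / 61) * (1 - 1 / 61))
  expect_true(all(abs(counts - n / 61) < 5 * se))
})
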