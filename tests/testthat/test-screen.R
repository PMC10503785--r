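mock_two <- function(ofg, obg, p) {
  list(omega_fg = ofg, omega_bg = obg, p_value = p, converged = TRUE)
}
mock_relax <- function(k, p) list(k = k, p_value = p, converged = TRUE)

test_that("the intersection rule classifies genes", {
  expect_equal(classify_gene(mock_two(0.30, 0.08, 0.01),
                             mock_relax(0.4, 0.01))$call, "relaxed")
  expect_equal(classify_gene(mock_two(0.05, 0.20, 0.01),
                             mock_relax(1.8, 0.01))$call, "constrained")
  # discordant directions: significant both ways but omega up, k up
  expect_equal(classify_gene(mock_two(0.30, 0.08, 0.01),
                             mock_relax(1.8, 0.01))$call, "neither")
  # only one test significant
  expect_equal(classify_gene(mock_two(0.30, 0.08, 0.30),
                             mock_relax(0.4, 0.01))$call, "neither")
  failed <- mock_two(0.3, 0.1, 0.01); failed$converged <- FALSE
  expect_equal(classify_gene(failed, mock_relax(0.4, 0.01))$call, "failed")
})

test_that("screen_partition handles an empty gene list", {
  res <- screen_partition(list(), tree6(),
                          partition_def("SR1", list(tips = c("t1", "t2"))))
  expect_equal(res$counts$n_relaxed, 0L)
  expect_equal(res$counts$n_total_with_output, 0L)
})

test_that("partition comparison matches the hand-computed chi-square", {
  a <- data.frame(partition = "SR1", n_relaxed = 30, n_constrained = 2,
                  n_total_with_output = 100)
  b <- data.frame(partition = "SR2", n_relaxed = 5, n_constrained = 1,
                  n_total_with_output = 100)
  res <- compare_partitions(a, b)
  tab <- rbind(c(30, 5), c(70, 95))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  by_hand <- sum((tab - expected)^2 / expected)
  expect_equal(res$statistic, by_hand, tolerance = 1e-12)
  # chi-square equals the squared two-proportion z statistic
  p1 <- 30 / 100; p2 <- 5 / 100; pp <- 35 / 200
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / 100 + 1 / 100))
  expect_equal(res$statistic, z^2, tolerance = 1e-12)
  # identical proportions: statistic 0, p 1
  same <- compare_partitions(
    data.frame(partition = "A", n_relaxed = 10, n_total_with_output = 100),
    data.frame(partition = "B", n_relaxed = 10, n_total_with_output = 100))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # zero totals rejected, sparse tables fall back to the exact test
  expect_error(compare_partitions(
    a, data.frame(partition = "C", n_relaxed = 0, n_total_with_output = 0)),
    "zero")
  expect_warning(
    sparse <- compare_partitions(
      data.frame(partition = "A", n_relaxed = 1, n_total_with_output = 40),
      data.frame(partition = "B", n_relaxed = 2, n_total_with_output = 40)),
    "Fisher")
  expect_equal(sparse$method, "fisher")
})

test_that("branch omega trend reproduces the exact rank test", {
  om <- c(a = 0.5, b = 0.6, c = 0.7, d = 0.1, e = 0.2, f = 0.3)
  res <- branch_omega_trend(om, c("a", "b", "c"))
  expect_equal(res$U, 9)
  expect_equal(res$p_value, 0.1)
  orc <- oracle_mw(om[1:3], om[4:6])
  expect_equal(res$U, orc$U)
  expect_equal(res$p_value, orc$p)
  # identical groups: p = 1 under the tie-corrected approximation
  tied <- c(a = 1, b = 1, c = 1, d = 1)
  expect_equal(branch_omega_trend(tied, c("a", "b"))$p_value, 1)
  expect_error(branch_omega_trend(om, "a"), "at least 2")
})

test_that("per-branch relaxed fractions lie in [0,1] and spot the planted branch", {
  expect_equal(nrow(per_branch_relaxed_fraction(list(), tree6())), 0L)
  tr <- tag_clade(tree6(tag = FALSE), "t6", "test")
  genes <- lapply(1:3, function(i) {
    simulate_alignment(tr, sim_spec(k = 0.1, tree = tr), 700, seed = 400 + i)
  })
  tab <- per_branch_relaxed_fraction(genes, tr)
  expect_true(all(tab$fraction_k_lt_1 >= 0 & tab$fraction_k_lt_1 <= 1))
  expect_equal(tab$n_genes, rep(3L, nrow(tab)))
  top <- tab$branch[which.max(tab$fraction_k_lt_1)]
  expect_equal(tab$fraction_k_lt_1[tab$branch == "t6"],
               max(tab$fraction_k_lt_1))
})
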