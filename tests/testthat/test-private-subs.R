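test_that("definitional private-substitution cases", {
  base <- matrix("E", 15, 3, dimnames = list(sprintf("s%02d", 1:15), NULL))
  m <- base
  m["s01", 2] <- "K"
  aln <- amino_alignment(m)
  recs <- find_private_substitutions(aln, "s01")
  expect_equal(nrow(recs), 1L)
  expect_equal(recs$column, 1L)  # 0-based
  expect_equal(recs$from, "E")
  expect_equal(recs$to, "K")
  expect_equal(recs$classification, "radical")
  # background disagreement kills the record under unanimity
  m2 <- base
  m2["s01", 2] <- "K"; m2["s05", 2] <- "D"
  expect_equal(nrow(find_private_substitutions(amino_alignment(m2), "s01")),
               0L)
  # ...but is tolerated under a relaxed consensus threshold
  expect_equal(nrow(find_private_substitutions(amino_alignment(m2), "s01",
                                               min_background_agreement = 0.9)),
               1L)
  # focal gap: column skipped
  m3 <- base; m3["s01", 2] <- "-"
  expect_equal(nrow(find_private_substitutions(amino_alignment(m3), "s01")),
               0L)
  expect_error(find_private_substitutions(aln, "nope"), "not in alignment")
  expect_error(find_private_substitutions(
    amino_alignment(base[1:2, ]), "s01"), "3 taxa")
})

test_that("classification is a symmetric lookup over the scheme", {
  expect_equal(classify_substitution("D", "E"), "conservative")
  expect_equal(classify_substitution("E", "K"), "radical")
  expect_error(classify_substitution("E", "E"), "self")
  expect_error(classify_substitution("E", "X"), "nonstandard")
  sch <- category_scheme()
  for (a in selax:::AA20) {
    for (b in selax:::AA20) {
      if (a == b) next
      expect_identical(classify_substitution(a, b, sch),
                       classify_substitution(b, a, sch))
    }
  }
})

test_that("custom schemes validate their partition", {
  expect_error(category_scheme(list(a = c("K", "R"), b = c("R", "D"))),
               "overlap")
  expect_error(category_scheme(list(a = selax:::AA20[1:10])), "cover")
  two <- category_scheme(list(small = c("G", "A", "S", "T", "C"),
                              rest = setdiff(selax:::AA20,
                                             c("G", "A", "S", "T", "C"))),
                         name = "two_class")
  expect_equal(classify_substitution("G", "A", two), "conservative")
  expect_equal(classify_substitution("G", "W", two), "radical")
})

test_that("the finder matches the column-scan oracle on random alignments", {
  set.seed(42)
  for (rep in 1:8) {
    n_taxa <- sample(5:12, 1)
    n_cols <- 200
    taxa <- sprintf("x%02d", seq_len(n_taxa))
    m <- matrix(sample(selax:::AA20, n_cols, replace = TRUE), n_taxa, n_cols,
                byrow = TRUE, dimnames = list(taxa, NULL))
    mut <- matrix(runif(n_taxa * n_cols) < 0.08, n_taxa, n_cols)
    m[mut] <- sample(selax:::AA20, sum(mut), replace = TRUE)
    gap <- matrix(runif(n_taxa * n_cols) < 0.05, n_taxa, n_cols)
    m[gap] <- "-"
    aln <- amino_alignment(m)
    for (focal in sample(taxa, 3)) {
      got <- find_private_substitutions(aln, focal)
      want <- oracle_private_scan(m, focal)
      expect_equal(got[c("taxon", "column", "from", "to")], want,
                   ignore_attr = TRUE)
    }
  }
})

test_that("unanimity output is invariant to background order", {
  fx <- make_private_sub_fixture(n_taxa = 8, n_cols = 120, planted = 3,
                                 seed = 9)
  m <- unclass(fx$aln)
  recs1 <- find_private_substitutions(fx$aln, "tax01")
  shuffled <- amino_alignment(m[c("tax01", sample(rownames(m)[-1])), ])
  recs2 <- find_private_substitutions(shuffled, "tax01")
  expect_equal(recs1, recs2)
})

test_that("lineage summaries count, fraction and conserve totals", {
  fx <- make_private_sub_fixture(n_taxa = 6, n_cols = 400, planted = 10,
                                 seed = 13)
  recs <- do.call(rbind, lapply(rownames(fx$aln), function(tx) {
    find_private_substitutions(fx$aln, tx)
  }))
  summ <- lineage_summary(recs)
  expect_equal(sum(summ$by_lineage$n_total), nrow(recs))
  expect_true(all(summ$by_lineage$n_total == 10))
  # planted 50/50 radical-conservative mix gives fraction 0.5 exactly
  planted <- data.frame(
    taxon = "tax01",
    column = 1:100,
    from = rep(c("D", "D"), 50),
    to = rep(c("E", "K"), 50),  # conservative, radical alternating
    stringsAsFactors = FALSE)
  other <- data.frame(taxon = "tax02", column = 1:4, from = "D",
                      to = c("E", "E", "K", "K"),
                      classification = c("conservative", "conservative",
                                         "radical", "radical"),
                      stringsAsFactors = FALSE)
  planted$classification <- classify_substitution(planted$from, planted$to)
  summ2 <- lineage_summary(rbind(planted, other))
  expect_equal(
    summ2$by_lineage$radical_fraction[summ2$by_lineage$taxon == "tax01"],
    0.5)
  # zero-record lineage: fraction reported missing, not 0
  summ3 <- lineage_summary(rbind(planted, other),
                           taxa = c("tax01", "tax02", "tax03"))
  row3 <- summ3$by_lineage[summ3$by_lineage$taxon == "tax03", ]
  expect_equal(row3$n_total, 0)
  expect_true(is.na(row3$radical_fraction))
  expect_error(lineage_summary(planted), "2 lineages")
})

test_that("planted fixtures are recovered exactly, with and without gaps", {
  for (gap_rate in c(0, 0.1)) {
    fx <- make_private_sub_fixture(n_taxa = 15, n_cols = 300, planted = 12,
                                   gap_rate = gap_rate, seed = 5)
    recs <- do.call(rbind, lapply(rownames(fx$aln), function(tx) {
      find_private_substitutions(fx$aln, tx)
    }))
    key <- function(d) paste(d$taxon, d$column, d$from, d$to)
    expect_setequal(key(recs), key(fx$truth))
  }
  # zero plants, zero noise: zero records
  fx0 <- make_private_sub_fixture(n_taxa = 6, n_cols = 50, planted = 0,
                                  variability = 0, seed = 2)
  expect_equal(nrow(find_private_substitutions(fx0$aln, "tax01")), 0L)
})
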