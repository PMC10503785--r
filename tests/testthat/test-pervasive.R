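# a small hand-built catalog: 4 coding, 3 TE, 3 pervasive contigs
planted_catalog <- function() {
  contigs <- data.frame(
    id = c(paste0("c", 1:4), paste0("t", 1:3), paste0("p", 1:3)),
    length = c(rep(900, 4), rep(600, 3), rep(400, 3)),
    orf_codons = c(300, 300, 20, 10, 0, 0, 0, 0, 0, 0))
  # c3, c4 have short ORFs but strong same-strand gene overlap
  blocks <- data.frame(
    contig = c("c1", "c2", "c3", "c4", "t1", "t2", "t3",
               "p1", "p1", "p2", "p3"),
    chrom = "chr1",
    start = c(1001, 3001, 5001, 7001, 9001, 11001, 13001,
              15001, 16501, 20001, 30001),
    end = c(1900, 3900, 5900, 7900, 9600, 11600, 13600,
            15400, 16900, 20400, 30400),
    strand = "+")
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1001, 3001, 5001, 7001),
                             c(1900, 3900, 5900, 7900)), strand = "+")
  repeats <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(9001, 11001, 13001), c(9600, 11600, 13600)))
  transcript_catalog(contigs, blocks, genes = genes, repeats = repeats)
}

test_that("classification recovers planted categories and rules", {
  cats <- classify_contigs(planted_catalog())
  expect_equal(as.vector(table(cats)[c("coding", "TE", "pervasive")]),
               c(4L, 3L, 3L))
  # repeat overlap 0.9 and no ORF -> TE
  catalog <- transcript_catalog(
    data.frame(id = "x", length = 1000, orf_codons = 0),
    data.frame(contig = "x", chrom = "chr1", start = 1, end = 1000,
               strand = "+"),
    repeats = GenomicRanges::GRanges("chr1",
                                     IRanges::IRanges(1, 900)))
  expect_equal(as.character(classify_contigs(catalog)), "TE")
  # below the repeat threshold it is pervasive instead
  catalog2 <- transcript_catalog(
    data.frame(id = "x", length = 1000, orf_codons = 0),
    data.frame(contig = "x", chrom = "chr1", start = 1, end = 1000,
               strand = "+"),
    repeats = GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100)))
  expect_equal(as.character(classify_contigs(catalog2)), "pervasive")
  # unplaced contigs are separated out
  catalog3 <- transcript_catalog(
    data.frame(id = c("a", "b"), length = c(500, 500),
               orf_codons = c(0, 0)),
    data.frame(contig = "a", chrom = "chr1", start = 1, end = 500,
               strand = "+"))
  expect_equal(as.character(classify_contigs(catalog3)), c("pervasive",
                                                           "unplaced"))
})

test_that("coding evidence respects strand", {
  genes_minus <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(1, 1000), strand = "-")
  catalog <- transcript_catalog(
    data.frame(id = "x", length = 1000, orf_codons = 0),
    data.frame(contig = "x", chrom = "chr1", start = 1, end = 1000,
               strand = "+"),
    genes = genes_minus)
  expect_equal(catalog$contigs$gene_overlap, 0)
  expect_equal(as.character(classify_contigs(catalog)), "pervasive")
})

test_that("category assignment matches a rule-by-rule oracle on a big catalog", {
  tg <- make_toy_genome(toy_genome_design(seed = 8))
  cats <- classify_contigs(tg$catalog)
  tab <- tg$catalog$contigs
  oracle <- vapply(seq_len(nrow(tab)), function(i) {
    if (!tab$placed[i]) return("unplaced")
    if (tab$orf_codons[i] >= 100 || tab$gene_overlap[i] >= 0.5) {
      return("coding")
    }
    if (tab$repeat_overlap[i] >= 0.25) return("TE")
    "pervasive"
  }, character(1))
  expect_equal(as.character(cats), oracle)
  expect_equal(as.character(cats), unname(tg$truth$category))
})

test_that("span merging does interval arithmetic and matches the mask oracle", {
  mk <- function(starts, ends, ids = paste0("p", seq_along(starts))) {
    contigs <- data.frame(id = ids, length = ends - starts + 1,
                          orf_codons = 0)
    blocks <- data.frame(contig = ids, chrom = "chr1", start = starts,
                         end = ends, strand = "+")
    cat <- transcript_catalog(contigs, blocks)
    pervasive_genome_span(cat, classify_contigs(cat))
  }
  # overlapping [100,200) and [150,300) in 0-based half-open terms:
  # 1-based closed [101,200] and [151,300] merge to 200 bp
  expect_equal(mk(c(101, 151), c(200, 300))$total_bp, 200)
  expect_equal(mk(c(1, 201), c(100, 300))$total_bp, 200)
  set.seed(99)
  starts <- sample.int(5000, 300, replace = TRUE)
  ends <- starts + sample.int(200, 300, replace = TRUE)
  got <- mk(starts, ends)$total_bp
  expect_equal(got, oracle_mask_bp(starts, ends, max(ends)))
  # bounds check
  cat <- transcript_catalog(
    data.frame(id = "p", length = 100, orf_codons = 0),
    data.frame(contig = "p", chrom = "chr1", start = 50, end = 149,
               strand = "+"))
  expect_error(pervasive_genome_span(cat, classify_contigs(cat),
                                     chrom_sizes = c(chr1 = 100)),
               "bounds")
})

test_that("transcriptional effort normalizes, excludes unplaced, flags empty", {
  cats <- factor(setNames(c("coding", "TE", "pervasive", "unplaced"),
                          c("a", "b", "c", "d")),
                 levels = c("coding", "TE", "pervasive", "unplaced"))
  expr <- matrix(c(60, 20, 20, 10,
                   0, 0, 0, 0), ncol = 2,
                 dimnames = list(c("a", "b", "c", "d"), c("t1", "t2")))
  eff <- transcriptional_effort(expr, cats)
  expect_equal(eff$pervasive[1], 0.20)
  expect_equal(eff$coding[1] + eff$TE[1] + eff$pervasive[1], 1,
               tolerance = 1e-12)
  expect_true(is.na(eff$pervasive[2]))
  # scaling a tissue's counts leaves fractions unchanged
  eff2 <- transcriptional_effort(expr * 7, cats)
  expect_equal(eff2$pervasive[1], eff$pervasive[1])
  expect_error(transcriptional_effort(-expr, cats), "negative")
})

test_that("genome-size correlation behaves on monotone and reversed inputs", {
  prof <- data.frame(species = letters[1:11],
                     genome_size = seq(1e6, 2e6, length.out = 11),
                     pervasive_span = seq(5e4, 4e5, length.out = 11))
  up <- genome_size_correlation(prof, n_perm = 999, seed = 4)
  expect_equal(up$rho, 1)
  expect_equal(up$p_permutation, 1 / 1000, tolerance = 1e-2)
  prof$pervasive_span <- rev(prof$pervasive_span)
  down <- genome_size_correlation(prof, n_perm = 999, seed = 4)
  expect_equal(down$rho, -1)
  expect_error(genome_size_correlation(prof[1:3, ]), "4 species")
})
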