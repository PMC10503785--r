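#' Default 15-taxon screening tree
#'
#' A fixed 15-taxon tree shipped with the package: a 5-taxon focal clade
#' (`lf_1`..`lf_5`, the "lungfish-like" group whose branches are tagged
#' `test`), a 6-taxon sister group (`tet_1`..`tet_6`) and 4 outgroup taxa
#' (`fish_1`..`fish_4`). Branch lengths are fixed constants chosen so that
#' desk-scale alignments (hundreds of codons) retain phylogenetic signal
#' without saturation; the shape emulates a vertebrate screen with a
#' focal clade at readable scale, it is not an inferred phylogeny.
#'
#' @param tag_focal tag the focal clade (including its stem) as `"test"`?
#' @return a [tagged_tree].
#' @export
default_screen_tree <- function(tag_focal = TRUE) {
  txt <- paste0(
    "((fish_1:0.25,fish_2:0.22):0.06,(fish_3:0.20,fish_4:0.18):0.05,",
    "(((lf_1:0.04,lf_2:0.05):0.03,(lf_3:0.06,(lf_4:0.04,lf_5:0.05):0.02)",
    ":0.03):0.12,((tet_1:0.12,tet_2:0.14):0.05,((tet_3:0.10,tet_4:0.12)",
    ":0.04,(tet_5:0.15,tet_6:0.13):0.04):0.05):0.10):0.08);")
  tr <- tagged_tree(ape::read.tree(text = txt))
  if (tag_focal) tr <- tag_clade(tr, focal_taxa(), "test", stem = TRUE)
  tr
}

#' @rdname default_screen_tree
#' @export
focal_taxa <- function() paste0("lf_", 1:5)

#' Design of a synthetic gene set
#'
#' Parameters of the planted-truth gene-set generator. Defaults reflect the
#' screening scenario the package targets: a 15-taxon tree with a 5-taxon
#' focal clade, a conserved-gene omega distribution dominated by purifying
#' selection, a fifth of genes evolving with strongly relaxed selection
#' (k = 0.3) on the focal clade, and gene lengths of a few hundred codons.
#'
#' @param n_genes number of genes.
#' @param fraction_relaxed fraction of genes planted as relaxed, in `[0,1]`.
#' @param k_relaxed selection intensity on focal branches of relaxed genes
#'   (>= 0; < 1 means relaxation).
#' @param tree a [tagged_tree] whose `test` branches receive `k_relaxed`;
#'   default [default_screen_tree()].
#' @param kappa transition/transversion ratio of the simulation.
#' @param omega_categories base site-category distribution (list with
#'   `omega` and `probs`).
#' @param length_sampler function(n) returning n codon lengths.
#' @param seed integer seed.
#' @return list of class `gene_set_design`.
#' @export
gene_set_design <- function(n_genes = 50, fraction_relaxed = 0.2,
                            k_relaxed = 0.3,
                            tree = default_screen_tree(),
                            kappa = 2.5,
                            omega_categories = list(
                              omega = c(0.05, 0.35, 1.2),
                              probs = c(0.45, 0.45, 0.10)),
                            length_sampler = function(n) {
                              pmin(pmax(round(rlnorm(n, log(300), 0.25)),
                                        150), 800)
                            },
                            seed = 1) {
  if (fraction_relaxed < 0 || fraction_relaxed > 1) {
    stop("fraction_relaxed must be in [0, 1]")
  }
  if (k_relaxed < 0) stop("k_relaxed must be nonnegative")
  if (n_genes < 1) stop("n_genes must be positive")
  structure(list(n_genes = as.integer(n_genes),
                 fraction_relaxed = fraction_relaxed,
                 k_relaxed = k_relaxed, tree = tree, kappa = kappa,
                 omega_categories = omega_categories,
                 length_sampler = length_sampler, seed = as.integer(seed)),
            class = "gene_set_design")
}

#' Generate a gene set with planted relaxation
#'
#' Simulates per-gene codon alignments on the design's tree. Exactly
#' `round(n_genes * fraction_relaxed)` genes are planted as relaxed: their
#' test branches evolve with every omega category raised to `k_relaxed`
#' ([apply_k()]); all other genes evolve with k = 1 everywhere.
#' Deterministic given the design seed.
#'
#' @param design a [gene_set_design()].
#' @param dir optional directory: writes one FASTA per gene plus a
#'   `truth.tsv` table.
#' @return list with `genes` (named list of [codon_alignment]s), `truth`
#'   (data.frame: gene, n_codons, relaxed, k) and `tree`.
#' @export
make_gene_set <- function(design, dir = NULL) {
  stopifnot(inherits(design, "gene_set_design"))
  set.seed(design$seed)
  n <- design$n_genes
  n_relaxed <- as.integer(round(n * design$fraction_relaxed))
  relaxed <- rep(FALSE, n)
  relaxed[sample.int(n, n_relaxed)] <- TRUE
  lens <- design$length_sampler(n)
  gene_seeds <- sample.int(.Machine$integer.max - 1L, n)
  tree <- design$tree
  test_ids <- tagged_branches(tree, "test")
  freqs <- codon_frequencies("equal")
  ids <- sprintf("gene%03d", seq_len(n))
  genes <- vector("list", n)
  for (i in seq_len(n)) {
    k_map <- if (relaxed[i]) {
      setNames(rep(design$k_relaxed, length(test_ids)), test_ids)
    } else NULL
    spec <- codon_model_spec(design$kappa, design$omega_categories, freqs,
                             k_map = k_map)
    genes[[i]] <- simulate_alignment(tree, spec, lens[i],
                                     seed = gene_seeds[i])
  }
  names(genes) <- ids
  truth <- data.frame(gene = ids, n_codons = lens, relaxed = relaxed,
                      k = ifelse(relaxed, design$k_relaxed, 1),
                      stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      write_alignment(genes[[i]], file.path(dir, paste0(ids[i], ".fasta")))
    }
    write_tsv(truth, file.path(dir, "truth.tsv"), stage = "simulate_genes",
              seed = design$seed,
              config = design[c("n_genes", "fraction_relaxed", "k_relaxed")])
    write_tagged_newick(tree, file.path(dir, "tree.nwk"))
  }
  list(genes = genes, truth = truth, tree = tree)
}

#' Design of a toy genome
#'
#' Parameters of the toy-genome generator behind the pervasive-transcription
#' tests: a single chromosome carrying intron-containing coding genes,
#' repeat (TE) intervals, and pervasive transcripts placed in intergenic
#' non-repeat space, plus per-tissue read counts hitting category effort
#' targets. Default pervasive effort targets span 0.243-0.3868 across five
#' tissues, the range these analyses are designed to resolve.
#'
#' @param genome_size chromosome length, bp.
#' @param n_genes number of coding genes (4 exons of 300 bp, 3 introns of
#'   500 bp each).
#' @param te_fraction fraction of the genome covered by repeat intervals.
#' @param pervasive_fraction fraction of the genome covered by pervasive
#'   primary-transcript spans.
#' @param pervasive_effort named per-tissue target fraction of reads on
#'   pervasive contigs (names = tissues).
#' @param te_effort per-tissue target fraction of reads on TE contigs
#'   (recycled over tissues).
#' @param read_depth reads per tissue.
#' @param seed integer seed.
#' @return list of class `toy_genome_design`.
#' @export
toy_genome_design <- function(genome_size = 1e6, n_genes = 30,
                              te_fraction = 0.15, pervasive_fraction = 0.25,
                              pervasive_effort = c(liver = 0.2430,
                                                   brain = 0.2800,
                                                   lung = 0.3100,
                                                   gill = 0.3400,
                                                   testis = 0.3868),
                              te_effort = 0.15,
                              read_depth = 1e5, seed = 1) {
  if (te_fraction + pervasive_fraction > 0.9) {
    stop("te_fraction + pervasive_fraction leave too little room for genes")
  }
  if (read_depth <= 0) stop("read_depth must be positive")
  if (any(pervasive_effort + te_effort >= 1)) {
    stop("per-tissue efforts exceed 1")
  }
  structure(list(genome_size = genome_size, n_genes = as.integer(n_genes),
                 te_fraction = te_fraction,
                 pervasive_fraction = pervasive_fraction,
                 pervasive_effort = pervasive_effort,
                 te_effort = rep_len(te_effort, length(pervasive_effort)),
                 read_depth = read_depth, seed = as.integer(seed)),
            class = "toy_genome_design")
}

#' Generate a toy genome with planted transcript categories
#'
#' Lays out, left to right along one chromosome with randomized spacer
#' gaps: coding genes (4 x 300 bp exons separated by 500 bp introns, one
#' transcript each with an ORF spanning its exons), TE intervals (1 kb
#' repeats, each with one fully repeat-overlapping transcript), and
#' pervasive transcripts (two 500 bp blocks spanning a 1 kb intron) in
#' intergenic non-repeat space. Read counts per tissue are allocated to
#' categories at the design's effort targets - exactly (largest-remainder
#' rounding) in `counts_mode = "exact"`, or multinomially with those
#' expectations in `"multinomial"` mode - and split uniformly among the
#' category's contigs. An error is raised when the requested fractions
#' cannot be packed into the genome.
#'
#' @param design a [toy_genome_design()].
#' @param counts_mode `"exact"` (deterministic, hits targets exactly when
#'   `read_depth * target` is integral) or `"multinomial"`.
#' @param dir optional output directory (GFF3 gene annotation, repeat BED,
#'   blocks and counts TSV, truth TSV).
#' @return list with `catalog` (a [transcript_catalog()]), `genes` and
#'   `repeats` (`GRanges`), `counts` (contig x tissue matrix), and `truth`
#'   (list: `category` per contig, `pervasive_span_bp`, `effort` per
#'   tissue x category).
#' @export
make_toy_genome <- function(design, counts_mode = c("exact", "multinomial"),
                            dir = NULL) {
  stopifnot(inherits(design, "toy_genome_design"))
  counts_mode <- match.arg(counts_mode)
  set.seed(design$seed)
  G <- design$genome_size
  exon_w <- 300; intron_w <- 500; n_exon <- 4
  gene_span <- n_exon * exon_w + (n_exon - 1) * intron_w
  te_w <- 1000
  perv_block <- 500; perv_intron <- 1000
  perv_span <- 2 * perv_block + perv_intron

  n_te <- round(design$te_fraction * G / te_w)
  n_perv <- round(design$pervasive_fraction * G / perv_span)
  spans <- c(rep(gene_span, design$n_genes), rep(te_w, n_te),
             rep(perv_span, n_perv))
  kind <- c(rep("gene", design$n_genes), rep("te", n_te),
            rep("perv", n_perv))
  slack <- G - sum(spans) - length(spans)  # >= 1 bp gap between features
  if (slack < 0) {
    stop("infeasible packing: requested features need ", sum(spans),
         " bp plus gaps but the genome has ", G)
  }
  ord <- sample(length(spans))
  spans <- spans[ord]; kind <- kind[ord]
  # randomized intergenic gaps: >= 1 bp each, jointly consuming the slack
  gaps <- 1 + as.numeric(rmultinom(1, slack, rep(1, length(spans))))
  starts <- cumsum(gaps) + cumsum(c(0, head(spans, -1)))
  stopifnot(max(starts + spans - 1) <= G)

  blocks <- list(); contigs <- list()
  gene_rows <- list(); repeat_rows <- list()
  gi <- ti <- pi_ <- 0L
  for (f in seq_along(spans)) {
    s <- starts[f]
    if (kind[f] == "gene") {
      gi <- gi + 1L
      id <- sprintf("cod%03d", gi)
      ex_start <- s + (seq_len(n_exon) - 1) * (exon_w + intron_w)
      blocks[[id]] <- data.frame(contig = id, chrom = "chr1",
                                 start = ex_start,
                                 end = ex_start + exon_w - 1, strand = "+")
      contigs[[id]] <- data.frame(id = id, length = n_exon * exon_w,
                                  orf_codons = n_exon * exon_w / 3)
      gene_rows[[id]] <- blocks[[id]]
    } else if (kind[f] == "te") {
      ti <- ti + 1L
      id <- sprintf("te%03d", ti)
      blocks[[id]] <- data.frame(contig = id, chrom = "chr1", start = s,
                                 end = s + te_w - 1, strand = "+")
      contigs[[id]] <- data.frame(id = id, length = te_w, orf_codons = 0)
      repeat_rows[[id]] <- data.frame(chrom = "chr1", start = s,
                                      end = s + te_w - 1)
    } else {
      pi_ <- pi_ + 1L
      id <- sprintf("perv%03d", pi_)
      b_start <- c(s, s + perv_block + perv_intron)
      blocks[[id]] <- data.frame(contig = id, chrom = "chr1",
                                 start = b_start,
                                 end = b_start + perv_block - 1,
                                 strand = "+")
      contigs[[id]] <- data.frame(id = id, length = 2 * perv_block,
                                  orf_codons = 0)
    }
  }
  blocks <- do.call(rbind, blocks)
  contigs <- do.call(rbind, contigs)
  rownames(blocks) <- rownames(contigs) <- NULL
  genes_gr <- GenomicRanges::GRanges(
    seqnames = "chr1",
    ranges = IRanges::IRanges(
      unlist(lapply(gene_rows, `[[`, "start")),
      unlist(lapply(gene_rows, `[[`, "end"))),
    strand = "+",
    type = "exon")
  rep_df <- do.call(rbind, repeat_rows)
  repeats_gr <- GenomicRanges::GRanges(
    seqnames = "chr1",
    ranges = IRanges::IRanges(rep_df$start, rep_df$end), strand = "*")
  catalog <- transcript_catalog(contigs, blocks, genes = genes_gr,
                                repeats = repeats_gr)

  truth_cat <- setNames(rep("pervasive", nrow(contigs)), contigs$id)
  truth_cat[startsWith(contigs$id, "te")] <- "TE"
  truth_cat[startsWith(contigs$id, "cod")] <- "coding"

  tissues <- names(design$pervasive_effort)
  counts <- matrix(0L, nrow(contigs), length(tissues),
                   dimnames = list(contigs$id, tissues))
  for (t in seq_along(tissues)) {
    pe <- unname(design$pervasive_effort[t])
    te <- unname(design$te_effort[t])
    tgt <- c(coding = 1 - pe - te, TE = te, pervasive = pe)
    if (counts_mode == "exact") {
      tot <- largest_remainder(tgt * design$read_depth)
    } else {
      tot <- as.numeric(rmultinom(1, design$read_depth, tgt))
    }
    names(tot) <- names(tgt)
    for (cat in names(tot)) {
      members <- contigs$id[truth_cat == cat]
      if (counts_mode == "exact") {
        alloc <- largest_remainder(rep(tot[cat] / length(members),
                                       length(members)))
      } else {
        alloc <- as.numeric(rmultinom(1, tot[cat],
                                      rep(1, length(members))))
      }
      counts[members, t] <- alloc
    }
  }

  perv_ids <- contigs$id[truth_cat == "pervasive"]
  perv_spans <- catalog$spans[names(catalog$spans) %in% perv_ids]
  truth <- list(
    category = truth_cat,
    pervasive_span_bp = sum(GenomicRanges::width(GenomicRanges::reduce(
      perv_spans, ignore.strand = TRUE))),
    effort = vapply(seq_along(tissues), function(t) {
      design$pervasive_effort[t]
    }, numeric(1))
  )
  names(truth$effort) <- tissues

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    rtracklayer::export(genes_gr, file.path(dir, "genes.gff3"),
                        format = "gff3")
    write_bed(repeats_gr, file.path(dir, "repeats.bed"))
    write_tsv(blocks, file.path(dir, "blocks.tsv"), stage = "simulate_genome",
              seed = design$seed)
    cdf <- data.frame(contig = rownames(counts), counts, check.names = FALSE)
    write_tsv(cdf, file.path(dir, "counts.tsv"), stage = "simulate_genome",
              seed = design$seed)
    write_tsv(data.frame(contig = names(truth_cat), category = truth_cat),
              file.path(dir, "truth.tsv"), stage = "simulate_genome",
              seed = design$seed)
  }
  list(catalog = catalog, genes = genes_gr, repeats = repeats_gr,
       counts = counts, truth = truth, design = design)
}

# integer allocation preserving the total: floor + distribute remainders
# to the largest fractional parts
largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- round(sum(x)) - sum(fl)
  if (rem > 0) {
    up <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[up] <- fl[up] + 1
  }
  as.integer(fl)
}

#' Species batch with monotone pervasive spans
#'
#' Builds per-species profiles from a batch of toy genomes whose genome
#' sizes increase and whose pervasive fractions increase with size, so the
#' planted span is strictly monotone in genome size - the positive-control
#' configuration for [genome_size_correlation()].
#'
#' @param n_species number of species (default 11).
#' @param base_size genome size of the smallest species.
#' @param size_step multiplicative size increment between species.
#' @param seed integer seed.
#' @return data.frame of species profiles: `species`, `genome_size`,
#'   `pervasive_span`, `pervasive_fraction`.
#' @export
make_species_profiles <- function(n_species = 11, base_size = 4e5,
                                  size_step = 1.25, seed = 1) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_species)
  rows <- lapply(seq_len(n_species), function(i) {
    g <- round(base_size * size_step ^ (i - 1))
    frac <- 0.10 + 0.02 * (i - 1)
    d <- toy_genome_design(genome_size = g, n_genes = 10,
                           te_fraction = 0.10, pervasive_fraction = frac,
                           seed = seeds[i])
    tg <- make_toy_genome(d)
    data.frame(species = sprintf("sp%02d", i), genome_size = g,
               pervasive_span = tg$truth$pervasive_span_bp,
               pervasive_fraction = tg$truth$pervasive_span_bp / g)
  })
  do.call(rbind, rows)
}

#' Amino-acid alignment with planted private substitutions
#'
#' Builds an alignment in which each planted record is guaranteed
#' recoverable: at a planted column the background is unanimous for the
#' `from` residue (background gaps, drawn at `gap_rate`, are capped below
#' the finder's default tolerance there) and the focal taxon carries `to`.
#' Remaining columns are conserved, except that a `variability` fraction
#' receives a two-taxon deviation - enough to break background unanimity
#' without creating a private substitution, so planted records are the
#' only ones present.
#'
#' @param n_taxa number of taxa (taxa are named `tax01`, `tax02`, ...).
#' @param n_cols alignment columns.
#' @param planted data.frame with columns `taxon`, `column` (1-based),
#'   `from`, `to`; or an integer: that many random plants per taxon.
#' @param variability fraction of non-planted columns given a two-taxon
#'   deviation (default 0.1).
#' @param gap_rate background gap rate (default 0).
#' @param seed integer seed.
#' @return list with `aln` (an [amino_alignment]) and `truth` (the planted
#'   records, 0-based `column`, with `classification` added).
#' @export
make_private_sub_fixture <- function(n_taxa = 15, n_cols = 300, planted = 5,
                                     variability = 0.1, gap_rate = 0,
                                     seed = 1) {
  set.seed(seed)
  taxa <- sprintf("tax%02d", seq_len(n_taxa))
  if (is.numeric(planted) && length(planted) == 1L) {
    need <- planted * n_taxa
    if (need > n_cols) stop("more plants than columns")
    cols <- sample.int(n_cols, need)
    res_pairs <- t(vapply(seq_len(need), function(i) sample(AA20, 2),
                          character(2)))
    planted <- data.frame(taxon = rep(taxa, each = planted),
                          column = cols, from = res_pairs[, 1],
                          to = res_pairs[, 2], stringsAsFactors = FALSE)
  }
  if (anyDuplicated(planted[c("taxon", "column")])) {
    stop("conflicting plants: duplicate (taxon, column)")
  }
  if (anyDuplicated(planted$column)) {
    stop("conflicting plants: a column may be planted for one taxon only")
  }
  if (any(planted$from == planted$to)) stop("plants must change the residue")

  m <- matrix(sample(AA20, n_cols, replace = TRUE), nrow = n_taxa,
              ncol = n_cols, byrow = TRUE, dimnames = list(taxa, NULL))
  free_cols <- setdiff(seq_len(n_cols), planted$column)
  n_var <- round(length(free_cols) * variability)
  var_cols <- sample(free_cols, n_var)
  var_pair <- list()
  for (j in var_cols) {
    pair <- sample(n_taxa, 2)
    dev <- sample(setdiff(AA20, m[1, j]), 1)
    m[pair, j] <- dev
    var_pair[[as.character(j)]] <- pair
  }
  if (gap_rate > 0) {
    gaps <- matrix(runif(n_taxa * n_cols) < gap_rate, n_taxa, n_cols)
    # a gap must not delete one of a two-taxon deviation (the survivor
    # would look like a spurious private substitution)
    for (j in var_cols) gaps[var_pair[[as.character(j)]], j] <- FALSE
    # keep planted columns within the finder's gap tolerance, and the
    # focal residue itself present
    max_bg_gaps <- floor(0.2 * (n_taxa - 1))
    for (r in seq_len(nrow(planted))) {
      j <- planted$column[r]
      gaps[match(planted$taxon[r], taxa), j] <- FALSE
      excess <- which(gaps[, j])
      if (length(excess) > max_bg_gaps) {
        gaps[excess[-seq_len(max_bg_gaps)], j] <- FALSE
      }
    }
    m[gaps] <- "-"
  }
  for (r in seq_len(nrow(planted))) {
    j <- planted$column[r]
    keep_gap <- m[, j] == "-"
    m[, j] <- planted$from[r]
    m[keep_gap, j] <- "-"
    m[match(planted$taxon[r], taxa), j] <- planted$to[r]
  }
  truth <- planted
  truth$column <- truth$column - 1L
  truth$classification <- classify_substitution(truth$from, truth$to)
  list(aln = amino_alignment(m), truth = truth)
}
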