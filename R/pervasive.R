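#' Transcript catalog
#'
#' The per-contig evidence table driving the pervasive-transcription
#' pipeline: each assembled contig (transcript) with its length, open
#' reading frame evidence, genome placement as a set of aligned blocks, the
#' primary-transcript span (min-to-max aligned coordinate, i.e. including
#' introns), and overlap fractions with annotated genes (same strand,
#' coding evidence) and with repeat annotation (computed on the aligned
#' blocks, not the intron-inclusive span). Coordinates follow the
#' Bioconductor convention (1-based, closed intervals, as in `GRanges`);
#' BED input is converted on read by rtracklayer.
#'
#' @param contigs data.frame with columns `id`, `length` and optionally
#'   `orf_codons` (longest ORF, in codons; 0 when absent).
#' @param blocks aligned blocks: a `GRanges` with metadata column `contig`,
#'   or a data.frame with columns `contig`, `chrom`, `start`, `end`,
#'   `strand` (1-based closed). Contigs without blocks are retained as
#'   unplaced.
#' @param genes gene annotation (`GRanges`, e.g. from [read_gff3()]);
#'   used for strand-aware coding-evidence overlap. `NULL` = none.
#' @param repeats repeat annotation (`GRanges` or `NULL`).
#' @return object of class `transcript_catalog`: list with `contigs` (the
#'   evidence table, one row per contig, columns `id`, `length`,
#'   `orf_codons`, `aligned_bp`, `gene_overlap`, `repeat_overlap`,
#'   `placed`), `blocks` and `spans` (named `GRanges` of primary spans).
#' @export
transcript_catalog <- function(contigs, blocks, genes = NULL, repeats = NULL) {
  stopifnot(is.data.frame(contigs), all(c("id", "length") %in% names(contigs)))
  if (anyDuplicated(contigs$id)) stop("duplicate contig ids")
  if (is.null(contigs$orf_codons)) contigs$orf_codons <- 0L
  if (is.data.frame(blocks)) {
    blocks <- GenomicRanges::GRanges(
      seqnames = blocks$chrom,
      ranges = IRanges::IRanges(blocks$start, blocks$end),
      strand = blocks$strand, contig = blocks$contig)
  }
  if (any(GenomicRanges::start(blocks) < 1)) {
    stop("block start < 1: coordinates must be 1-based closed")
  }
  unknown <- setdiff(unique(blocks$contig), contigs$id)
  if (length(unknown)) {
    stop("blocks reference unknown contig(s): ",
         paste(head(unknown, 5), collapse = ", "))
  }
  by_contig <- S4Vectors::split(blocks, factor(blocks$contig,
                                               levels = contigs$id))
  spans <- unlist(range(by_contig, ignore.strand = FALSE))
  red_us <- GenomicRanges::reduce(by_contig, ignore.strand = TRUE)
  red_s <- GenomicRanges::reduce(by_contig, ignore.strand = FALSE)
  aligned_bp <- sum(GenomicRanges::width(red_us))

  # bp of overlap between each contig's (reduced) blocks and an annotation
  overlap_bp <- function(red_list, ann, ignore_strand) {
    out <- setNames(rep(0, length(red_list)), names(red_list))
    if (is.null(ann) || !length(ann)) return(out)
    ann <- GenomicRanges::reduce(ann, ignore.strand = ignore_strand)
    flat <- unlist(red_list, use.names = FALSE)
    who <- rep(names(red_list), S4Vectors::elementNROWS(red_list))
    hits <- GenomicRanges::findOverlaps(flat, ann,
                                        ignore.strand = ignore_strand)
    if (!length(hits)) return(out)
    ov <- GenomicRanges::width(GenomicRanges::pintersect(
      flat[S4Vectors::queryHits(hits)], ann[S4Vectors::subjectHits(hits)],
      ignore.strand = TRUE))
    agg <- tapply(ov, who[S4Vectors::queryHits(hits)], sum)
    out[names(agg)] <- agg
    out
  }
  # coding evidence respects strand; repeat association does not
  gene_bp <- overlap_bp(red_s, genes, ignore_strand = FALSE)
  rep_bp <- overlap_bp(red_us, repeats, ignore_strand = TRUE)
  tab <- data.frame(
    id = contigs$id,
    length = contigs$length,
    orf_codons = contigs$orf_codons,
    aligned_bp = aligned_bp,
    gene_overlap = ifelse(aligned_bp > 0, gene_bp / aligned_bp, 0),
    repeat_overlap = ifelse(aligned_bp > 0, rep_bp / aligned_bp, 0),
    placed = aligned_bp > 0,
    stringsAsFactors = FALSE
  )
  structure(list(contigs = tab, blocks = blocks, spans = spans),
            class = "transcript_catalog")
}

#' @export
print.transcript_catalog <- function(x, ...) {
  cat("Transcript catalog:", nrow(x$contigs), "contigs,",
      sum(x$contigs$placed), "placed\n")
  invisible(x)
}

#' Classify contigs as coding, TE-associated or pervasive
#'
#' Rule-based categorization: a placed contig is \emph{coding} if its
#' longest ORF reaches `min_orf_codons` codons or its same-strand overlap
#' with annotated genes reaches `gene_overlap_threshold`; otherwise
#' \emph{TE} if its repeat-overlap fraction reaches `repeat_threshold`;
#' otherwise \emph{pervasive} (noncoding, non-repeat-associated - the
#' category that pools intergenic noncoding RNAs and transcriptional
#' leakage, which this pipeline does not attempt to separate). Contigs
#' without genome placement are reported as `unplaced` and excluded from
#' category denominators.
#'
#' @param catalog a [transcript_catalog()].
#' @param min_orf_codons ORF length threshold, codons (default 100).
#' @param gene_overlap_threshold same-strand exonic overlap fraction
#'   (default 0.5).
#' @param repeat_threshold repeat-overlap fraction (default 0.25).
#' @return factor of categories (`coding`, `TE`, `pervasive`, `unplaced`)
#'   named by contig id.
#' @export
classify_contigs <- function(catalog, min_orf_codons = 100,
                             gene_overlap_threshold = 0.5,
                             repeat_threshold = 0.25) {
  stopifnot(inherits(catalog, "transcript_catalog"))
  tab <- catalog$contigs
  cat <- ifelse(!tab$placed, "unplaced",
         ifelse(tab$orf_codons >= min_orf_codons |
                tab$gene_overlap >= gene_overlap_threshold, "coding",
         ifelse(tab$repeat_overlap >= repeat_threshold, "TE", "pervasive")))
  factor(setNames(cat, tab$id),
         levels = c("coding", "TE", "pervasive", "unplaced"))
}

#' Genomic footprint of pervasive transcription
#'
#' The union (merge of overlapping intervals, strand ignored) of the
#' primary-transcript spans - i.e. including introns - of all contigs in
#' the `pervasive` category.
#'
#' @param catalog a [transcript_catalog()].
#' @param categories factor from [classify_contigs()].
#' @param chrom_sizes optional named vector of chromosome lengths; spans
#'   beyond them raise an error.
#' @return list with `total_bp`, `per_chromosome` (data.frame `chrom`,
#'   `bp`) and `intervals` (the merged `GRanges`).
#' @export
pervasive_genome_span <- function(catalog, categories, chrom_sizes = NULL) {
  stopifnot(inherits(catalog, "transcript_catalog"))
  ids <- names(categories)[categories == "pervasive"]
  spans <- catalog$spans[names(catalog$spans) %in% ids]
  merged <- GenomicRanges::reduce(spans, ignore.strand = TRUE)
  if (!is.null(chrom_sizes)) {
    ends <- GenomicRanges::end(merged)
    lim <- chrom_sizes[as.character(GenomicRanges::seqnames(merged))]
    if (any(is.na(lim)) || any(ends > lim)) {
      stop("pervasive span outside chromosome bounds")
    }
  }
  w <- GenomicRanges::width(merged)
  per_chrom <- stats::aggregate(
    w, list(chrom = as.character(GenomicRanges::seqnames(merged))), sum)
  names(per_chrom)[2] <- "bp"
  list(total_bp = sum(w), per_chromosome = per_chrom, intervals = merged)
}

#' Per-tissue transcriptional effort by category
#'
#' For each tissue, the fraction of mapped reads attributable to each
#' contig category (coding / TE / pervasive). Unplaced contigs are
#' excluded from the denominator; their read share is reported in the
#' `excluded_fraction` attribute.
#'
#' @param expr contig x tissue matrix of nonnegative read counts (rownames
#'   = contig ids).
#' @param categories factor from [classify_contigs()].
#' @return data.frame with columns `tissue`, `coding`, `TE`, `pervasive`
#'   (fractions summing to 1 per tissue; `NA` for all-zero tissues).
#' @export
transcriptional_effort <- function(expr, categories) {
  if (any(expr < 0)) stop("negative read counts")
  if (is.null(rownames(expr))) stop("expr needs contig ids as rownames")
  miss <- setdiff(rownames(expr), names(categories))
  if (length(miss)) stop("contigs without category: ",
                         paste(head(miss, 5), collapse = ", "))
  cats <- categories[rownames(expr)]
  keep <- cats != "unplaced"
  excluded <- colSums(expr[!keep, , drop = FALSE]) / pmax(colSums(expr), 1)
  expr <- expr[keep, , drop = FALSE]
  cats <- droplevels(cats[keep])
  out <- lapply(colnames(expr), function(ts) {
    v <- expr[, ts]
    tot <- sum(v)
    if (tot == 0) {
      data.frame(tissue = ts, coding = NA_real_, TE = NA_real_,
                 pervasive = NA_real_)
    } else {
      s <- tapply(v, cats, sum, default = 0)
      data.frame(tissue = ts,
                 coding = unname(s["coding"]) / tot,
                 TE = unname(s["TE"]) / tot,
                 pervasive = unname(s["pervasive"]) / tot)
    }
  })
  out <- do.call(rbind, out)
  attr(out, "excluded_fraction") <- excluded
  out
}

#' Correlation of pervasive span with genome size
#'
#' Spearman rank correlation between assembled genome size and the total
#' pervasively transcribed genomic span across species, with a seeded
#' permutation p-value (two-sided, on |rho|) alongside the classical
#' large-sample approximation. Ties are handled by average ranks.
#'
#' @param profiles data.frame with columns `species`, `genome_size`,
#'   `pervasive_span` (one row per species, >= 4 species).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed for the permutation draw.
#' @return list with `rho`, `p_permutation`, `p_approx`, `n_perm`.
#' @export
genome_size_correlation <- function(profiles, n_perm = 10000, seed = 1) {
  stopifnot(all(c("species", "genome_size", "pervasive_span") %in%
                  names(profiles)))
  if (nrow(profiles) < 4) stop("need at least 4 species")
  x <- profiles$genome_size
  y <- profiles$pervasive_span
  rho <- cor(x, y, method = "spearman")
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    if (abs(cor(x, sample(y), method = "spearman")) >= abs(rho) - 1e-12) {
      hits <- hits + 1L
    }
  }
  p_perm <- (hits + 1) / (n_perm + 1)
  p_approx <- tryCatch(
    suppressWarnings(stats::cor.test(x, y, method = "spearman"))$p.value,
    error = function(e) NA_real_)
  list(rho = rho, p_permutation = p_perm, p_approx = p_approx,
       n_perm = n_perm)
}
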