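#' Physicochemical category scheme for amino acids
#'
#' A partition of the 20 standard residues into property classes, used to
#' classify substitutions as conservative (within-class) or radical
#' (between-class). The default scheme partitions residues into four
#' charge/polarity classes: positively charged (K, R, H), negatively
#' charged (D, E), polar uncharged (S, T, N, Q, C, Y, G) and nonpolar
#' (A, V, L, I, P, F, M, W). Any alternative partition can be supplied,
#' e.g. read from a plain-text table with [read_category_scheme()].
#'
#' @param classes named list of character vectors; must be disjoint and
#'   jointly cover the 20 standard residues.
#' @param name scheme label.
#' @return object of class `category_scheme`: a named character vector
#'   mapping each residue to its class.
#' @export
category_scheme <- function(classes = NULL, name = "charge_polarity") {
  if (is.null(classes)) {
    classes <- list(
      positive = c("K", "R", "H"),
      negative = c("D", "E"),
      polar = c("S", "T", "N", "Q", "C", "Y", "G"),
      nonpolar = c("A", "V", "L", "I", "P", "F", "M", "W")
    )
  }
  all_res <- unlist(classes, use.names = FALSE)
  if (anyDuplicated(all_res)) stop("classes overlap")
  if (!setequal(all_res, AA20)) {
    stop("classes must jointly cover exactly the 20 standard residues")
  }
  map <- rep(names(classes), lengths(classes))
  names(map) <- all_res
  structure(map[AA20], name = name, class = "category_scheme")
}

#' Classify an amino-acid substitution as radical or conservative
#'
#' @param from_res,to_res standard one-letter residues, `from_res !=
#'   to_res`. Vectorized.
#' @param scheme a [category_scheme()].
#' @return `"conservative"` if both residues share a property class,
#'   `"radical"` otherwise. Symmetric in its arguments.
#' @examples
#' classify_substitution("D", "E")  # conservative (both negative)
#' classify_substitution("E", "K")  # radical (negative -> positive)
#' @export
classify_substitution <- function(from_res, to_res,
                                  scheme = category_scheme()) {
  bad <- !(from_res %in% AA20) | !(to_res %in% AA20)
  if (any(bad)) {
    stop("nonstandard residue(s): ",
         paste(unique(c(from_res[bad], to_res[bad])), collapse = ", "))
  }
  if (any(from_res == to_res)) stop("self-substitution (from == to)")
  ifelse(unname(scheme[from_res]) == unname(scheme[to_res]),
         "conservative", "radical")
}

#' Find lineage-private amino-acid substitutions
#'
#' Scans an amino-acid alignment for columns where the focal taxon carries
#' a standard residue that differs from a background consensus held by at
#' least `min_background_agreement` of the non-gap background taxa (default
#' 1, i.e. strict unanimity). The substitution is oriented background ->
#' focal. Columns gapped or ambiguous in the focal taxon are skipped, as
#' are columns where more than `max_background_gap` of the background is
#' gapped/ambiguous; "private" is defined on the observed alignment, with
#' no ancestral-state reconstruction.
#'
#' @param aln an [amino_alignment] with >= 3 taxa.
#' @param focal_taxon name of the focal lineage.
#' @param min_background_agreement minimum fraction of non-gap background
#'   taxa sharing the consensus residue (1 = unanimity).
#' @param max_background_gap maximum tolerated fraction of background taxa
#'   that are gapped/ambiguous in a column (default 0.2).
#' @param scheme a [category_scheme()] for the radical/conservative call.
#' @return data.frame of substitution records: `taxon`, `column` (0-based),
#'   `from` (background consensus), `to` (focal residue), `classification`.
#' @export
find_private_substitutions <- function(aln, focal_taxon,
                                       min_background_agreement = 1,
                                       max_background_gap = 0.2,
                                       scheme = category_scheme()) {
  stopifnot(inherits(aln, "amino_alignment"))
  m <- unclass(aln)
  if (nrow(m) < 3) stop("need at least 3 taxa")
  if (!focal_taxon %in% rownames(m)) {
    stop("focal taxon '", focal_taxon, "' not in alignment")
  }
  focal <- m[focal_taxon, ]
  bg <- m[setdiff(rownames(m), focal_taxon), , drop = FALSE]
  nbg <- nrow(bg)

  recs <- lapply(seq_len(ncol(m)), function(j) {
    f <- focal[j]
    if (!f %in% AA20) return(NULL)
    col <- bg[, j]
    obs <- col[col %in% AA20]
    if ((nbg - length(obs)) / nbg > max_background_gap) return(NULL)
    if (!length(obs)) return(NULL)
    tab <- table(obs)
    cons <- names(tab)[which.max(tab)]
    if (max(tab) / length(obs) < min_background_agreement) return(NULL)
    if (cons == f) return(NULL)
    data.frame(taxon = focal_taxon, column = j - 1L, from = cons, to = f,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  if (is.null(out)) {
    out <- data.frame(taxon = character(), column = integer(),
                      from = character(), to = character(),
                      stringsAsFactors = FALSE)
  }
  out$classification <- if (nrow(out)) {
    classify_substitution(out$from, out$to, scheme)
  } else character()
  out
}

#' Per-lineage summary of private substitutions
#'
#' Counts and radical fractions per lineage, with pairwise two-proportion
#' comparisons of the radical fraction between lineages (chi-squared
#' without continuity correction; Fisher's exact test when any expected
#' count is below 5), multiple-testing corrected.
#'
#' @param records a data.frame of substitution records as returned by
#'   [find_private_substitutions()] (rows from several lineages combined),
#'   or a list of such data.frames.
#' @param correction p-value adjustment method for the pairwise
#'   comparisons (see [stats::p.adjust()]; default `"BH"`).
#' @param taxa lineages to summarize; defaults to those present in
#'   `records`, but supplying the full taxon set also reports lineages
#'   with zero records (fraction `NA`).
#' @return list with `by_lineage` (taxon, n_total, n_radical,
#'   radical_fraction - `NA` for lineages with zero records) and
#'   `pairwise` (taxon_a, taxon_b, p_value, p_adjusted).
#' @export
lineage_summary <- function(records, correction = "BH", taxa = NULL) {
  if (is.list(records) && !is.data.frame(records)) {
    records <- do.call(rbind, records)
  }
  if (is.null(taxa)) taxa <- unique(records$taxon)
  if (length(taxa) < 2) stop("records from at least 2 lineages required")
  by_lineage <- do.call(rbind, lapply(taxa, function(tx) {
    r <- records[records$taxon == tx, ]
    n <- nrow(r)
    nr <- sum(r$classification == "radical")
    data.frame(taxon = tx, n_total = n, n_radical = nr,
               radical_fraction = if (n > 0) nr / n else NA_real_,
               stringsAsFactors = FALSE)
  }))
  pairs <- utils::combn(taxa, 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- by_lineage[by_lineage$taxon == pairs[1, i], ]
    b <- by_lineage[by_lineage$taxon == pairs[2, i], ]
    p <- if (a$n_total == 0 || b$n_total == 0) {
      NA_real_
    } else {
      tab <- rbind(c(a$n_radical, a$n_total - a$n_radical),
                   c(b$n_radical, b$n_total - b$n_radical))
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        fisher.test(tab)$p.value
      } else {
        chisq.test(tab, correct = FALSE)$p.value
      }
    }
    data.frame(taxon_a = pairs[1, i], taxon_b = pairs[2, i], p_value = p,
               stringsAsFactors = FALSE)
  }))
  pw$p_adjusted <- p.adjust(pw$p_value, correction)
  list(by_lineage = by_lineage, pairwise = pw)
}
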