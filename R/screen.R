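#' Branch partition definition
#'
#' Names a split of the tree's branches into a test (foreground) set and the
#' complementary reference (background) set, in the style of the SR-type
#' partitions used to contrast a focal clade against the rest of the tree.
#'
#' @param name partition label (e.g. `"SR1"`).
#' @param test_branches character vector of branch ids (see [branch_ids()]),
#'   or a list `list(tips = ..., stem = TRUE)` describing a clade to tag.
#' @return object of class `partition_def`.
#' @export
partition_def <- function(name, test_branches) {
  stopifnot(is.character(name), length(name) == 1L)
  structure(list(name = name, test_branches = test_branches),
            class = "partition_def")
}

# apply a partition to a tree -> tagged_tree with test/reference tags
apply_partition <- function(tree, partition) {
  stopifnot(inherits(tree, "tagged_tree"), inherits(partition, "partition_def"))
  tree$tags[] <- "reference"
  tb <- partition$test_branches
  if (is.list(tb)) {
    tree <- tag_clade(tree, tb$tips, "test",
                      stem = isTRUE(tb$stem) || is.null(tb$stem))
  } else {
    ids <- names(tree$tags)
    unknown <- setdiff(tb, ids)
    if (length(unknown)) {
      stop("partition '", partition$name, "' names unknown branch(es): ",
           paste(unknown, collapse = ", "))
    }
    tree$tags[tb] <- "test"
  }
  tree
}

#' Classify one gene from its two-ratio and relaxation fits
#'
#' The intersection rule of the gene screen: a gene is called
#' \emph{relaxed} when the two-ratio branch test and the relaxation test are
#' both significant at `alpha` AND their directions agree on weakened
#' selection in the foreground (omega_fg > omega_bg and k < 1);
#' \emph{constrained} when both are significant with omega_fg < omega_bg and
#' k > 1; \emph{neither} when significance or direction fails; and
#' \emph{failed} when either fit did not converge (failed genes are excluded
#' from all denominators).
#'
#' @param two_ratio a two-ratio `fit_result` carrying `p_value` (see
#'   [fit_gene()]), or a list with `omega_fg`, `omega_bg`, `p_value`,
#'   `converged`.
#' @param relax a `relax_fit` (or list with `k`, `p_value`, `converged`).
#' @param alpha per-gene significance level (applied to the p-values as
#'   given; adjust them beforehand for a corrected screen).
#' @param gene gene identifier carried into the result.
#' @return one-row data.frame: gene, omega_fg, omega_bg, k, p_two_ratio,
#'   p_relax, call.
#' @export
classify_gene <- function(two_ratio, relax, alpha = 0.05, gene = NA_character_) {
  ofg <- if (!is.null(two_ratio$estimates)) {
    unname(two_ratio$estimates["omega_fg"])
  } else two_ratio$omega_fg
  obg <- if (!is.null(two_ratio$estimates)) {
    unname(two_ratio$estimates["omega_bg"])
  } else two_ratio$omega_bg
  p2 <- two_ratio$p_value
  pk <- relax$p_value
  k <- relax$k
  ok <- isTRUE(two_ratio$converged) && isTRUE(relax$converged)
  call <- if (!ok) {
    "failed"
  } else if (p2 < alpha && pk < alpha && ofg > obg && k < 1) {
    "relaxed"
  } else if (p2 < alpha && pk < alpha && ofg < obg && k > 1) {
    "constrained"
  } else {
    "neither"
  }
  data.frame(gene = gene, omega_fg = ofg, omega_bg = obg, k = k,
             p_two_ratio = p2, p_relax = pk, call = call,
             stringsAsFactors = FALSE)
}

#' Two-ratio and relaxation fits for one gene
#'
#' The per-gene protocol of the screen: branch lengths are estimated under
#' the one-ratio model, then held fixed for a two-ratio fit (with a
#' likelihood-ratio test against the one-ratio null, 1 df) and a
#' [fit_relax()] test on the same tagging.
#'
#' @param tree a [tagged_tree] with a `"test"` tagging.
#' @param aln a [codon_alignment].
#' @param freqs codon frequencies; default F3x4 from `aln`.
#' @param control a [fit_control()].
#' @return list with `one_ratio`, `two_ratio` (fit_result with `lrt` and
#'   `p_value` added) and `relax` (a `relax_fit`).
#' @export
fit_gene <- function(tree, aln, freqs = NULL, control = fit_control()) {
  if (is.null(freqs)) freqs <- codon_frequencies("F3x4", aln)
  one <- fit_branch_model(tree, aln, "one_ratio", freqs = freqs,
                          control = control)
  if (!one$converged) {
    two <- one
    two$p_value <- NA_real_
    rel <- structure(list(k = NA_real_, p_value = NA_real_, converged = FALSE,
                          note = one$note), class = "relax_fit")
    return(list(one_ratio = one, two_ratio = two, relax = rel))
  }
  two <- fit_branch_model(tree, aln, "two_ratio", freqs = freqs,
                          branch_lengths = one, control = control)
  two$lrt <- 2 * (two$lnL - one$lnL)
  two$p_value <- pchisq(max(two$lrt, 0), df = 1, lower.tail = FALSE)
  rel <- fit_relax(tree, aln, freqs = freqs, branch_lengths = one,
                   control = control)
  list(one_ratio = one, two_ratio = two, relax = rel)
}

#' Screen a gene set under one branch partition
#'
#' Runs the two-ratio + relaxation protocol ([fit_gene()]) on every gene
#' with the partition's test/reference tagging, classifies each gene by the
#' intersection rule ([classify_gene()]), and aggregates relaxed /
#' constrained counts. Genes whose fits do not converge are reported as
#' `failed` and excluded from the total ("produced an output" counts only
#' converged genes). P-values are Benjamini-Hochberg adjusted across genes
#' within each test by default.
#'
#' @param genes named list of [codon_alignment]s.
#' @param tree a [tagged_tree] (tags are overwritten by the partition).
#' @param partition a [partition_def].
#' @param alpha significance level applied after correction.
#' @param correction `"BH"` (default) or `"none"` for raw p-values.
#' @param control a [fit_control()].
#' @return object of class `screen_result`: list with `partition`, `counts`
#'   (one-row data.frame: n_relaxed, n_constrained, n_total_with_output) and
#'   `genes` (per-gene table).
#' @export
screen_partition <- function(genes, tree, partition, alpha = 0.05,
                             correction = c("BH", "none"),
                             control = fit_control()) {
  correction <- match.arg(correction)
  tree <- apply_partition(tree, partition)
  if (!length(genes)) {
    counts <- data.frame(partition = partition$name, n_relaxed = 0L,
                         n_constrained = 0L, n_total_with_output = 0L)
    return(structure(list(partition = partition, counts = counts,
                          genes = data.frame()), class = "screen_result"))
  }
  ids <- if (!is.null(names(genes))) names(genes) else {
    sprintf("gene%03d", seq_along(genes))
  }
  fits <- lapply(genes, function(a) fit_gene(tree, a, control = control))
  p2 <- vapply(fits, function(f) f$two_ratio$p_value, numeric(1))
  pk <- vapply(fits, function(f) f$relax$p_value, numeric(1))
  if (correction == "BH") {
    p2 <- p.adjust(p2, "BH")
    pk <- p.adjust(pk, "BH")
  }
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    f$two_ratio$p_value <- p2[i]
    f$relax$p_value <- pk[i]
    classify_gene(f$two_ratio, f$relax, alpha = alpha, gene = ids[i])
  })
  tab <- do.call(rbind, rows)
  counts <- data.frame(partition = partition$name,
                       n_relaxed = sum(tab$call == "relaxed"),
                       n_constrained = sum(tab$call == "constrained"),
                       n_total_with_output = sum(tab$call != "failed"))
  structure(list(partition = partition, counts = counts, genes = tab),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Screen [", x$counts$partition, "]: ", x$counts$n_relaxed, " relaxed, ",
      x$counts$n_constrained, " constrained of ",
      x$counts$n_total_with_output, " genes with output\n", sep = "")
  invisible(x)
}

#' Compare relaxed-gene proportions between two partitions
#'
#' Pearson chi-squared test (no continuity correction, so the statistic
#' equals the squared two-proportion z statistic) on the 2x2 table of
#' relaxed vs non-relaxed genes in two partitions. When any expected cell
#' count falls below 5 the function warns and reports Fisher's exact test
#' instead.
#'
#' @param a,b `screen_result`s or their `counts` rows (need columns
#'   `n_relaxed` and `n_total_with_output`).
#' @param what count to compare; `"relaxed"` (default) or `"constrained"`.
#' @return list with `statistic`, `p_value`, `method` and the 2x2 `table`.
#' @export
compare_partitions <- function(a, b, what = c("relaxed", "constrained")) {
  what <- match.arg(what)
  ca <- if (inherits(a, "screen_result")) a$counts else a
  cb <- if (inherits(b, "screen_result")) b$counts else b
  col <- paste0("n_", what)
  x <- c(ca[[col]], cb[[col]])
  n <- c(ca$n_total_with_output, cb$n_total_with_output)
  if (any(n == 0)) stop("partition with zero genes with output")
  tab <- rbind(hit = x, rest = n - x)
  colnames(tab) <- c(ca$partition[1], cb$partition[1])
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    warning("expected cell count < 5; using Fisher's exact test")
    ft <- fisher.test(tab)
    return(list(statistic = NA_real_, p_value = ft$p.value,
                method = "fisher", table = tab))
  }
  ct <- chisq.test(tab, correct = FALSE)
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       method = "chisq", table = tab)
}

#' Rank test for elevated omega on focal branches
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test comparing the per-branch
#' omega estimates of a free-ratio fit between a focal branch set and all
#' remaining branches: the concatenated-gene trend test of the pipeline.
#' The exact null distribution is used when both groups are small
#' (min(n1, n2) <= 8) and there are no ties; otherwise the tie-corrected
#' normal approximation.
#'
#' @param free_fit a free-ratio `fit_result` (estimates named
#'   `omega_<branch id>`), or a numeric vector of per-branch omega named by
#'   branch id.
#' @param focal_branches character vector of branch ids forming the focal
#'   group (>= 2, and >= 2 others).
#' @return list with `U` (statistic for the focal group), `p_value`,
#'   `focal_omega`, `other_omega`.
#' @export
branch_omega_trend <- function(free_fit, focal_branches) {
  om <- if (inherits(free_fit, "fit_result")) {
    est <- free_fit$estimates
    est <- est[startsWith(names(est), "omega_")]
    setNames(unname(est), sub("^omega_", "", names(est)))
  } else free_fit
  miss <- setdiff(focal_branches, names(om))
  if (length(miss)) stop("no omega for branch(es): ",
                         paste(miss, collapse = ", "))
  x <- om[focal_branches]
  y <- om[setdiff(names(om), focal_branches)]
  if (length(x) < 2 || length(y) < 2) {
    stop("need at least 2 branches in each group")
  }
  if (length(unique(c(x, y))) == 1L) {
    # fully tied data: no evidence either way
    return(list(U = length(x) * length(y) / 2, p_value = 1,
                focal_omega = x, other_omega = y))
  }
  exact <- min(length(x), length(y)) <= 8 && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided",
                                     exact = exact, correct = FALSE))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       focal_omega = x, other_omega = y)
}

#' Per-branch fraction of genes with k < 1
#'
#' For each branch, the fraction of genes whose branch-specific selection
#' intensity from the general-descriptive profile ([fit_general_descriptive()])
#' is below 1 - the per-branch "proportion of potentially relaxed genes".
#'
#' @param genes named list of [codon_alignment]s (or a precomputed list of
#'   `gd_fit` objects).
#' @param tree a [tagged_tree].
#' @param control a [fit_control()].
#' @return data.frame with columns `branch`, `n_genes`, `fraction_k_lt_1`;
#'   empty for an empty gene list.
#' @export
per_branch_relaxed_fraction <- function(genes, tree, control = fit_control()) {
  if (!length(genes)) {
    return(data.frame(branch = character(), n_genes = integer(),
                      fraction_k_lt_1 = numeric()))
  }
  fits <- lapply(genes, function(g) {
    if (inherits(g, "gd_fit")) g else {
      fit_general_descriptive(tree, g, control = control)
    }
  })
  kmat <- do.call(rbind, lapply(fits, `[[`, "k"))
  data.frame(branch = colnames(kmat),
             n_genes = nrow(kmat),
             fraction_k_lt_1 = colMeans(kmat < 1),
             row.names = NULL)
}
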