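#' Phylogenetic log-likelihood of a codon alignment
#'
#' Felsenstein-pruning log-likelihood of a codon alignment on a tagged tree
#' under a [codon_model_spec], summed over sites. For site-category models
#' the per-site likelihood is the proportion-weighted mixture over
#' categories, with each category's omega raised to the branch's selection
#' intensity k on test branches. Columns that are gapped or ambiguous in a
#' taxon contribute a partial likelihood of 1 at that tip (standard
#' missing-data convention); columns missing in every taxon are dropped
#' (their count is available as `attr(, "n_dropped")`).
#'
#' @param tree a [tagged_tree]; its tips must be a subset of the alignment
#'   taxa.
#' @param aln a [codon_alignment].
#' @param spec a [codon_model_spec].
#' @return the log-likelihood (scalar), with attribute `n_dropped`.
#' @examples
#' tr <- tagged_tree(ape::read.tree(text = "((A:0.2,B:0.2):0.1,C:0.3);"))
#' aln <- codon_alignment(c(A = "ATGAAA", B = "ATGAAG", C = "ATGCAA"))
#' spec <- codon_model_spec(kappa = 2, omega = 0.5)
#' log_likelihood(tr, aln, spec)
#' @export
log_likelihood <- function(tree, aln, spec) {
  stopifnot(inherits(tree, "tagged_tree"), inherits(aln, "codon_alignment"),
            inherits(spec, "codon_model_spec"))
  dat <- likelihood_data(tree, aln)
  ll <- loglik_from_data(dat, spec, tree)
  attr(ll, "n_dropped") <- dat$n_dropped
  ll
}

# Precompute everything likelihood evaluations share across parameter values:
# postorder traversal, compressed site patterns, genetic-code pair table.
likelihood_data <- function(tree, aln) {
  phy <- tree$phy
  miss <- setdiff(phy$tip.label, rownames(aln))
  if (length(miss)) {
    stop("tree tip(s) absent from alignment: ", paste(miss, collapse = ", "))
  }
  trav <- tree_traversal(phy)
  m <- unclass(aln)[phy$tip.label, , drop = FALSE]
  idx <- matrix(codon_index(as.vector(m)), nrow = nrow(m))
  states <- idx - 1L
  states[is.na(states)] <- -1L
  all_missing <- colSums(states >= 0L) == 0L
  n_dropped <- sum(all_missing)
  states <- states[, !all_missing, drop = FALSE]
  key <- apply(states, 2, paste, collapse = ",")
  first <- !duplicated(key)
  pat <- states[, first, drop = FALSE]
  w <- as.numeric(table(factor(key, levels = key[first])))
  list(trav = trav, patterns = pat, weights = w,
       edge_ids = branch_ids(phy)[trav$orig_index],
       nsites = ncol(states), n_dropped = n_dropped)
}

loglik_from_data <- function(dat, spec, tree, lengths = NULL) {
  if (is.null(lengths)) lengths <- dat$trav$lengths
  omega_eff <- effective_omega_matrix(tree, spec, dat$edge_ids)
  cpp_codon_loglik(
    dat$trav$edge, lengths, dat$patterns, dat$weights,
    as.numeric(spec$freqs), spec$kappa, omega_eff,
    category_probs(spec), genetic_code()$pairs
  )
}
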