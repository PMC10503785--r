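#' Simulate a codon alignment along a tree
#'
#' Evolves codon sequences along a tagged tree under a [codon_model_spec]:
#' the root state of each site is drawn from the stationary frequencies, a
#' site category is drawn i.i.d. from the category proportions, and states
#' evolve down each branch with the transition probabilities of that
#' branch's effective rate matrix (category omega raised to the branch's k).
#' Deterministic given the seed.
#'
#' @param tree a [tagged_tree].
#' @param spec a [codon_model_spec].
#' @param n_sites number of codon sites, > 0.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a [codon_alignment] of the tree's tips, with attribute
#'   `site_categories` (the drawn category index per site).
#' @export
simulate_alignment <- function(tree, spec, n_sites, seed = NULL) {
  stopifnot(inherits(tree, "tagged_tree"), inherits(spec, "codon_model_spec"))
  if (!is.numeric(n_sites) || n_sites < 1) stop("n_sites must be positive")
  n_sites <- as.integer(n_sites)
  if (!is.null(seed)) set.seed(seed)
  gc <- genetic_code()
  pi <- as.numeric(spec$freqs)
  trav <- tree_traversal(tree$phy)
  edge_ids <- branch_ids(tree$phy)[trav$orig_index]
  omega_eff <- effective_omega_matrix(tree, spec, edge_ids)
  probs <- category_probs(spec)
  ncat <- length(probs)

  cat_of_site <- sample.int(ncat, n_sites, replace = TRUE, prob = probs)
  states <- matrix(NA_integer_, trav$nnode, n_sites)
  states[trav$root, ] <- sample.int(61L, n_sites, replace = TRUE, prob = pi)

  # preorder = reversed postorder; transition matrices cached per
  # (branch length, effective omega)
  Pcache <- new.env(parent = emptyenv())
  for (e in rev(seq_len(nrow(trav$edge)))) {
    parent <- trav$edge[e, 1]; child <- trav$edge[e, 2]
    t_e <- trav$lengths[e]
    for (cc in seq_len(ncat)) {
      sel <- which(cat_of_site == cc)
      if (!length(sel)) next
      key <- paste(signif(t_e, 12), signif(omega_eff[cc, e], 12))
      P <- Pcache[[key]]
      if (is.null(P)) {
        Q <- build_rate_matrix(spec$kappa, omega_eff[cc, e], spec$freqs)
        P <- transition_probabilities(Q, t_e)
        Pcache[[key]] <- P
      }
      ps <- states[parent, sel]
      for (s in unique(ps)) {
        take <- sel[ps == s]
        states[child, take] <-
          sample.int(61L, length(take), replace = TRUE, prob = P[s, ])
      }
    }
  }

  tips <- states[seq_len(trav$ntip), , drop = FALSE]
  m <- matrix(gc$codons[tips], nrow = trav$ntip,
              dimnames = list(tree$phy$tip.label, NULL))
  out <- codon_alignment(m)
  attr(out, "site_categories") <- cat_of_site
  out
}
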