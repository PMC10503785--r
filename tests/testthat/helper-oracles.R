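# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: codon pair classification re-derives everything
# from Biostrings' genetic code by string comparison, the likelihood oracle
# sums over internal-state assignments explicitly, and the interval oracle
# counts bases in a boolean mask.

# classify an ordered codon pair: NA if not a single-nucleotide sense pair,
# else one of "syn_tv", "syn_ts", "nonsyn_tv", "nonsyn_ts"
oracle_pair_class <- function(c1, c2) {
  code <- Biostrings::GENETIC_CODE
  if (code[[c1]] == "*" || code[[c2]] == "*") return(NA_character_)
  a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
  d <- which(a != b)
  if (length(d) != 1L) return(NA_character_)
  purines <- c("A", "G")
  is_ts <- (a[d] %in% purines) == (b[d] %in% purines)
  is_syn <- code[[c1]] == code[[c2]]
  paste0(if (is_syn) "syn" else "nonsyn", "_", if (is_ts) "ts" else "tv")
}

# unscaled GY94 rate for i -> j built purely from the oracle classifier
oracle_rate <- function(c1, c2, kappa, omega, pi) {
  cls <- oracle_pair_class(c1, c2)
  if (is.na(cls)) return(0)
  r <- unname(pi[c2])
  if (grepl("ts", cls)) r <- r * kappa
  if (grepl("nonsyn", cls)) r <- r * omega
  r
}

# matrix exponential via scaling-and-squaring on a truncated Taylor series;
# independent of the package's eigendecomposition route
oracle_expm <- function(Q, t) {
  A <- unclass(Q) * t
  n <- 0
  while (max(abs(A)) > 0.5) { A <- A / 2; n <- n + 1 }
  P <- diag(nrow(A)); term <- diag(nrow(A))
  for (k in 1:25) {
    term <- term %*% A / k
    P <- P + term
  }
  for (i in seq_len(n)) P <- P %*% P
  P
}

# Site log-likelihood by exhaustive enumeration over all internal-node
# states.  P_of_edge(e) must return the transition matrix of postorder
# edge e; tips gives each tip's codon state (index or NA).
oracle_site_loglik <- function(trav, P_list, pi, tip_states) {
  internal <- sort(unique(c(trav$edge[trav$edge[, 1] > trav$ntip, 1],
                            trav$edge[trav$edge[, 2] > trav$ntip, 2])))
  grid <- as.matrix(do.call(expand.grid, rep(list(1:61), length(internal))))
  state_of <- function(node) {
    if (node <= trav$ntip) rep(tip_states[node], nrow(grid)) else {
      grid[, match(node, internal)]
    }
  }
  pr <- pi[state_of(trav$root)]
  for (e in seq_len(nrow(trav$edge))) {
    to <- state_of(trav$edge[e, 2])
    if (all(is.na(to))) next  # missing tip: partial likelihood 1
    pr <- pr * P_list[[e]][cbind(state_of(trav$edge[e, 1]), to)]
  }
  log(sum(pr))
}

# exhaustive column scanner for private substitutions (set comparison,
# written independently of find_private_substitutions)
oracle_private_scan <- function(m, focal, max_bg_gap = 0.2) {
  std <- selax:::AA20
  bg_taxa <- setdiff(rownames(m), focal)
  hits <- list()
  for (j in seq_len(ncol(m))) {
    f <- m[focal, j]
    if (!(f %in% std)) next
    bg <- m[bg_taxa, j]
    n_bad <- sum(!(bg %in% std))
    if (n_bad / length(bg) > max_bg_gap) next
    obs <- unique(bg[bg %in% std])
    if (length(obs) != 1L) next
    if (obs == f) next
    hits[[length(hits) + 1L]] <- data.frame(
      taxon = focal, column = j - 1L, from = obs, to = f,
      stringsAsFactors = FALSE)
  }
  if (length(hits)) do.call(rbind, hits) else {
    data.frame(taxon = character(), column = integer(), from = character(),
               to = character(), stringsAsFactors = FALSE)
  }
}

# total covered bases of a set of 1-based closed intervals, by boolean mask
oracle_mask_bp <- function(starts, ends, max_pos) {
  mask <- logical(max_pos)
  for (i in seq_along(starts)) mask[starts[i]:ends[i]] <- TRUE
  sum(mask)
}

# exact two-sided Mann-Whitney p-value by enumerating all group assignments
oracle_mw <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  combs <- utils::combn(length(pooled), n1)
  U_all <- apply(combs, 2, function(idx) {
    xx <- pooled[idx]; yy <- pooled[-idx]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  })
  r <- rank(pooled)[seq_len(n1)]
  U_obs <- sum(r) - n1 * (n1 + 1) / 2
  p <- 2 * min(mean(U_all <= U_obs + 1e-9), mean(U_all >= U_obs - 1e-9))
  list(U = U_obs, p = min(1, p))
}

# small fixed trees used throughout
tree3 <- function() tagged_tree(ape::read.tree(
  text = "(A:0.2,B:0.3,C:0.25);"))
tree6 <- function(tag = TRUE) {
  tr <- tagged_tree(ape::read.tree(text = paste0(
    "(((t1:0.10,t2:0.10):0.08,(t3:0.10,t4:0.10):0.08):0.05,",
    "t5:0.20,t6:0.20);")))
  if (tag) tr <- tag_clade(tr, c("t1", "t2"), "test")
  tr
}

equal_freqs <- function() codon_frequencies("equal")

# the study-scale site-category distribution used by the simulations
base_categories <- function() {
  list(omega = c(0.05, 0.35, 1.2), probs = c(0.45, 0.45, 0.10))
}

sim_spec <- function(k = NULL, tree = NULL, kappa = 2.5) {
  k_map <- if (!is.null(k) && !is.null(tree)) {
    ids <- tagged_branches(tree, "test")
    setNames(rep(k, length(ids)), ids)
  } else NULL
  codon_model_spec(kappa, base_categories(), equal_freqs(), k_map = k_map)
}
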