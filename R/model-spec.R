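#' Codon model specification
#'
#' Bundles the parameters of a GY94-style codon model: the
#' transition/transversion ratio kappa, an omega structure, stationary codon
#' frequencies, and an optional per-branch selection-intensity map k. The
#' omega structure is one of:
#' \describe{
#'   \item{single}{one omega for the whole tree (`omega` a scalar);}
#'   \item{two_ratio}{`omega = c(fg = ..., bg = ...)`, foreground omega on
#'     branches tagged `"test"`, background elsewhere;}
#'   \item{free}{`omega` a vector named by branch id, one per branch;}
#'   \item{site_categories}{`omega` a list with elements `omega` (category
#'     ratios) and `probs` (mixing proportions summing to 1); each site
#'     belongs to one category, i.i.d.}
#' }
#' On a branch with selection intensity `k` (from `k_map`), a site category
#' with ratio `w` evolves with effective ratio `w^k` ([apply_k()]); `k = 1`
#' on every branch unless the model is a relaxation model.
#'
#' @param kappa transition/transversion ratio, > 0.
#' @param omega the omega structure (see above).
#' @param freqs a [codon_frequencies] object.
#' @param k_map named numeric vector of per-branch k exponents (branch ids
#'   as in [branch_ids()]); unnamed scalar applies to all branches; omitted
#'   branches default to 1.
#' @return object of class `codon_model_spec`.
#' @export
codon_model_spec <- function(kappa, omega, freqs = codon_frequencies("equal"),
                             k_map = NULL) {
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0) {
    stop("kappa must be a single positive number")
  }
  if (is.list(omega)) {
    structure_type <- "site_categories"
    if (!all(c("omega", "probs") %in% names(omega))) {
      stop("site-category omega needs elements 'omega' and 'probs'")
    }
    if (length(omega$omega) != length(omega$probs)) {
      stop("category omegas and probabilities differ in length")
    }
    if (any(omega$omega < 0)) stop("negative omega")
    if (any(omega$probs < 0) || abs(sum(omega$probs) - 1) > 1e-8) {
      stop("category proportions must be nonnegative and sum to 1")
    }
  } else {
    if (any(omega < 0)) stop("negative omega")
    nm <- names(omega)
    if (length(omega) == 1L && is.null(nm)) {
      structure_type <- "single"
    } else if (length(omega) == 2L && setequal(nm, c("fg", "bg"))) {
      structure_type <- "two_ratio"
    } else if (!is.null(nm)) {
      structure_type <- "free"
    } else {
      stop("omega must be a scalar, c(fg=,bg=), a branch-named vector, ",
           "or a site-category list")
    }
  }
  validate_frequencies(as.numeric(freqs))
  if (!is.null(k_map) && any(k_map < 0)) stop("k must be nonnegative")
  structure(list(kappa = kappa, omega = omega, freqs = freqs,
                 k_map = k_map, structure = structure_type),
            class = "codon_model_spec")
}

#' @export
print.codon_model_spec <- function(x, ...) {
  cat("Codon model: kappa =", format(x$kappa, digits = 4),
      "| omega structure:", x$structure, "\n")
  if (!is.null(x$k_map) && any(x$k_map != 1)) {
    cat("  selection intensity k on",
        sum(x$k_map != 1), "branch(es) differs from 1\n")
  }
  invisible(x)
}

# ncat x nedges matrix of effective omega in a given edge order,
# after applying the per-branch k exponent.
effective_omega_matrix <- function(tree, spec, edge_order_ids) {
  nedge <- length(edge_order_ids)
  tags <- tree$tags[edge_order_ids]
  if (spec$structure == "site_categories") {
    base <- spec$omega$omega
  } else if (spec$structure == "single") {
    base <- unname(spec$omega)
  } else if (spec$structure == "two_ratio") {
    m <- matrix(ifelse(tags == "test", spec$omega["fg"], spec$omega["bg"]),
                nrow = 1)
    return(apply_k_edges(m, tree, spec, edge_order_ids))
  } else {  # free
    miss <- setdiff(edge_order_ids, names(spec$omega))
    if (length(miss)) {
      stop("free-ratio omega missing for branch(es): ",
           paste(miss, collapse = ", "))
    }
    m <- matrix(unname(spec$omega[edge_order_ids]), nrow = 1)
    return(apply_k_edges(m, tree, spec, edge_order_ids))
  }
  m <- matrix(base, nrow = length(base), ncol = nedge)
  apply_k_edges(m, tree, spec, edge_order_ids)
}

apply_k_edges <- function(m, tree, spec, edge_order_ids) {
  k <- rep(1, length(edge_order_ids))
  names(k) <- edge_order_ids
  if (!is.null(spec$k_map)) {
    if (is.null(names(spec$k_map)) && length(spec$k_map) == 1L) {
      k[] <- spec$k_map
    } else {
      k[intersect(names(spec$k_map), edge_order_ids)] <-
        spec$k_map[intersect(names(spec$k_map), edge_order_ids)]
    }
  }
  for (e in seq_along(k)) if (k[e] != 1) m[, e] <- apply_k(m[, e], k[e])
  m
}

category_probs <- function(spec) {
  if (spec$structure == "site_categories") spec$omega$probs else 1
}
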