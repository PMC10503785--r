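#' Optimizer settings for codon-model fits
#'
#' @param rel_tol relative log-likelihood convergence tolerance.
#' @param par_tol parameter convergence tolerance.
#' @param eval_max,iter_max optimizer effort caps per start.
#' @param kappa_bounds,omega_bounds,blen_bounds,k_bounds box constraints on
#'   the natural parameter scales; k is bounded to `[0, 50]`.
#' @return list of class `fit_control`.
#' @export
fit_control <- function(rel_tol = 1e-8, par_tol = 1e-6,
                        eval_max = 3000, iter_max = 400,
                        kappa_bounds = c(0.01, 100),
                        omega_bounds = c(1e-6, 50),
                        blen_bounds = c(1e-7, 20),
                        k_bounds = c(0, 50)) {
  structure(list(rel_tol = rel_tol, par_tol = par_tol, eval_max = eval_max,
                 iter_max = iter_max, kappa_bounds = kappa_bounds,
                 omega_bounds = omega_bounds, blen_bounds = blen_bounds,
                 k_bounds = k_bounds), class = "fit_control")
}

fit_result <- function(lnL, estimates, converged, n_evals, note = NULL,
                       branch_lengths = NULL) {
  structure(list(lnL = lnL, estimates = estimates, converged = converged,
                 n_evals = n_evals, note = note,
                 branch_lengths = branch_lengths),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Codon-model fit: lnL =", format(x$lnL, digits = 10),
      if (!x$converged) "(NOT converged)", "\n")
  print(round(x$estimates, 4))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

# Does the alignment contain any column with >= 2 distinct observed codons?
has_variation <- function(dat) {
  any(apply(dat$patterns, 2, function(col) {
    length(unique(col[col >= 0L])) > 1L
  }))
}

# shared nlminb wrapper with evaluation counting
run_nlminb <- function(start, objective, lower, upper, control) {
  env <- new.env(parent = emptyenv()); env$n <- 0L
  obj <- function(p) {
    env$n <- env$n + 1L
    v <- objective(p)
    if (!is.finite(v)) 1e12 else v
  }
  res <- nlminb(start, obj, lower = lower, upper = upper,
                control = list(rel.tol = control$rel_tol,
                               x.tol = control$par_tol,
                               eval.max = control$eval_max,
                               iter.max = control$iter_max))
  res$n_evals <- env$n
  res
}

# Two-stage multi-start: every start is run to a loose tolerance, then the
# best is polished to the full tolerance.  This keeps the multi-start
# robustness while spending the expensive final convergence only once.
multi_start <- function(starts, objective, lower, upper, control) {
  total <- 0L
  if (length(starts) > 1L) {
    loose <- control
    loose$rel_tol <- max(control$rel_tol, 1e-5)
    loose$eval_max <- min(control$eval_max, 500)
    loose$iter_max <- min(control$iter_max, 80)
    stage1 <- lapply(starts, function(s) {
      run_nlminb(s, objective, lower, upper, loose)
    })
    total <- sum(vapply(stage1, `[[`, 0L, "n_evals"))
    best_start <- stage1[[which.min(vapply(stage1, `[[`, 0, "objective"))]]$par
  } else {
    best_start <- starts[[1]]
  }
  best <- run_nlminb(best_start, objective, lower, upper, control)
  ok <- best$convergence == 0
  if (!ok) {
    # a cold restart from the stalled point usually resolves nlminb's
    # occasional "false convergence" on these surfaces
    retry <- run_nlminb(best$par, objective, lower, upper, control)
    if (retry$objective <= best$objective) {
      retry$n_evals <- best$n_evals + retry$n_evals
      best <- retry
    } else {
      best$n_evals <- best$n_evals + retry$n_evals
    }
    ok <- retry$convergence == 0
  }
  best$n_evals <- total + best$n_evals
  best$any_converged <- ok
  best
}

#' Fit a branch model (one-, two- or free-ratio)
#'
#' Maximum-likelihood fit of a GY94-style codon model in which omega is
#' shared by all branches (`one_ratio`), split into a foreground value on
#' branches tagged `"test"` and a background value elsewhere (`two_ratio`),
#' or free to differ on every branch (`free_ratio`). Branch lengths are
#' co-estimated under the one-ratio model and held fixed (at the supplied
#' `branch_lengths`, normally the one-ratio estimates) for the two- and
#' free-ratio fits; this one-ratio-first protocol is also what
#' [fit_gene()] and the gene screen use.
#'
#' @param tree a [tagged_tree] (a `"test"` tagging is required for
#'   `two_ratio`).
#' @param aln a [codon_alignment].
#' @param mode `"one_ratio"`, `"two_ratio"` or `"free_ratio"`.
#' @param freqs codon frequencies; default F3x4 estimated from `aln`.
#' @param branch_lengths optional fixed branch lengths (postorder-free:
#'   named by branch id); default: the tree's own lengths for two/free
#'   ratio, co-estimated for one-ratio.
#' @param optimize_branch_lengths co-estimate branch lengths (default: only
#'   in one-ratio mode).
#' @param control a [fit_control()].
#' @return a `fit_result` with elements `lnL`, `estimates` (kappa and the
#'   omega set), `converged`, `n_evals` and `branch_lengths` (named by
#'   branch id).
#' @export
fit_branch_model <- function(tree, aln,
                             mode = c("one_ratio", "two_ratio", "free_ratio"),
                             freqs = NULL, branch_lengths = NULL,
                             optimize_branch_lengths = (mode[1] == "one_ratio"),
                             control = fit_control()) {
  mode <- match.arg(mode)
  if (is.null(freqs)) freqs <- codon_frequencies("F3x4", aln)
  if (mode == "two_ratio" && !any(tree$tags == "test")) {
    stop("two-ratio fit requires at least one branch tagged 'test'")
  }
  dat <- likelihood_data(tree, aln)
  ids <- dat$edge_ids
  nedge <- length(ids)
  base_len <- resolve_lengths(dat, branch_lengths)

  if (!has_variation(dat)) {
    est <- switch(mode,
      one_ratio = c(kappa = NA_real_, omega = NA_real_),
      two_ratio = c(kappa = NA_real_, omega_fg = NA_real_,
                    omega_bg = NA_real_),
      free_ratio = c(kappa = NA_real_, setNames(rep(NA_real_, nedge),
                                                paste0("omega_", ids))))
    return(fit_result(NA_real_, est, converged = FALSE, n_evals = 0L,
                      note = "no variable sites; parameters unidentifiable",
                      branch_lengths = setNames(base_len, ids)))
  }

  lk_b <- log(control$kappa_bounds); lw_b <- log(control$omega_bounds)
  ll_b <- log(control$blen_bounds)
  clamp <- function(x, b) pmin(pmax(x, b[1] + 1e-9), b[2] - 1e-9)

  if (mode == "one_ratio") {
    np_len <- if (optimize_branch_lengths) nedge else 0L
    make_spec <- function(p) {
      codon_model_spec(exp(p[1]), exp(p[2]), freqs)
    }
    objective <- function(p) {
      len <- if (np_len) exp(p[3:(2 + nedge)]) else base_len
      -loglik_from_data(dat, make_spec(p), tree, lengths = len)
    }
    init_len <- if (np_len) clamp(log(pmax(base_len, 1e-4)), ll_b) else NULL
    starts <- list(c(log(2), log(0.3), init_len))
    lower <- c(lk_b[1], lw_b[1], rep(ll_b[1], np_len))
    upper <- c(lk_b[2], lw_b[2], rep(ll_b[2], np_len))
    best <- multi_start(starts, objective, lower, upper, control)
    p <- best$par
    est <- c(kappa = exp(p[1]), omega = exp(p[2]))
    fitted_len <- if (np_len) exp(p[3:(2 + nedge)]) else base_len
  } else if (mode == "two_ratio") {
    objective <- function(p) {
      spec <- codon_model_spec(exp(p[1]),
                               c(fg = exp(p[2]), bg = exp(p[3])), freqs)
      -loglik_from_data(dat, spec, tree, lengths = base_len)
    }
    starts <- list(c(log(2), log(0.3), log(0.3)),
                   c(log(2), log(1.0), log(0.1)))
    best <- multi_start(starts, objective, rep(c(lk_b[1], lw_b[1]), c(1, 2)),
                        rep(c(lk_b[2], lw_b[2]), c(1, 2)), control)
    p <- best$par
    est <- c(kappa = exp(p[1]), omega_fg = exp(p[2]), omega_bg = exp(p[3]))
    fitted_len <- base_len
  } else {
    objective <- function(p) {
      om <- setNames(exp(p[-1]), ids)
      spec <- codon_model_spec(exp(p[1]), om, freqs)
      -loglik_from_data(dat, spec, tree, lengths = base_len)
    }
    starts <- list(c(log(2), rep(log(0.3), nedge)))
    best <- multi_start(starts, objective,
                        c(lk_b[1], rep(lw_b[1], nedge)),
                        c(lk_b[2], rep(lw_b[2], nedge)), control)
    p <- best$par
    est <- c(kappa = exp(p[1]),
             setNames(exp(p[-1]), paste0("omega_", ids)))
    fitted_len <- base_len
  }
  fit_result(-best$objective, est, converged = best$any_converged,
             n_evals = best$n_evals,
             branch_lengths = setNames(fitted_len, ids))
}

# branch lengths in postorder-edge order, from a branch-id-named vector,
# a fit_result, or the tree itself
resolve_lengths <- function(dat, branch_lengths) {
  if (is.null(branch_lengths)) return(dat$trav$lengths)
  if (inherits(branch_lengths, "fit_result")) {
    branch_lengths <- branch_lengths$branch_lengths
  }
  if (is.null(names(branch_lengths))) {
    stop("branch_lengths must be named by branch id")
  }
  miss <- setdiff(dat$edge_ids, names(branch_lengths))
  if (length(miss)) stop("missing branch length for: ",
                         paste(miss, collapse = ", "))
  unname(branch_lengths[dat$edge_ids])
}

# --- relaxation models ------------------------------------------------------

# shared pieces of the 3-category omega distribution parameterization:
# par = (log kappa, w1, w2, w3, s1, s2 [, k]) with w1,w2 in (0,1], sorted,
# w3 in [1, 50], stick-breaking proportions s1, s2.
relax_par_spec <- function(p, freqs, k_map = NULL) {
  w12 <- sort(c(p[2], p[3]))
  probs <- c(p[5], (1 - p[5]) * p[6], (1 - p[5]) * (1 - p[6]))
  codon_model_spec(exp(p[1]),
                   list(omega = c(w12, p[4]), probs = probs),
                   freqs, k_map = k_map)
}

relax_bounds <- function(control, with_k) {
  lk <- log(control$kappa_bounds)
  lower <- c(lk[1], 1e-6, 1e-6, 1, 1e-3, 1e-3)
  upper <- c(lk[2], 1, 1, min(50, control$omega_bounds[2]), 0.999, 0.999)
  if (with_k) {
    lower <- c(lower, control$k_bounds[1])
    upper <- c(upper, control$k_bounds[2])
  }
  list(lower = lower, upper = upper)
}

relax_null_starts <- list(
  c(log(2), 0.05, 0.50, 1.5, 0.40, 0.60),
  c(log(2), 0.01, 0.20, 1.05, 0.60, 0.70),
  c(log(4), 0.30, 0.90, 2.5, 0.30, 0.50)
)

#' RELAX-style test for relaxed or intensified selection
#'
#' Fits a codon model with a shared 3-category omega distribution
#' (omega1 <= omega2 <= 1 <= omega3 for identifiability) twice: a null in
#' which the selection intensity k is fixed at 1 everywhere, and an
#' alternative in which a single free k (bounded to `[0, 50]`) is applied to
#' every branch tagged `"test"`. Twice the log-likelihood difference is
#' compared with a chi-squared distribution on 1 df: `k < 1` with a
#' significant test indicates relaxation of selection on the test branches,
#' `k > 1` intensification. Branch lengths are held fixed at the one-ratio
#' estimates (computed internally when not supplied). Optimization uses
#' multiple fixed starting points; the alternative additionally starts from
#' the null solution with k = 1, which guarantees the nesting inequality
#' `lnL_alt >= lnL_null` up to optimizer tolerance.
#'
#' @param tree a [tagged_tree] with at least one `"test"` branch.
#' @param aln a [codon_alignment].
#' @param freqs codon frequencies; default F3x4 from `aln`.
#' @param branch_lengths fixed branch lengths (named by branch id, or a
#'   one-ratio `fit_result`); default: fitted internally.
#' @param control a [fit_control()].
#' @return object of class `relax_fit`: list with `k` (the estimate),
#'   `lnL_null`, `lnL_alt`, `lrt` (2 delta lnL), `p_value`, `null` and
#'   `alt` fit results, and `converged`.
#' @export
fit_relax <- function(tree, aln, freqs = NULL, branch_lengths = NULL,
                      control = fit_control()) {
  test_ids <- tagged_branches(tree, "test")
  if (!length(test_ids)) stop("no branches tagged 'test'")
  if (is.null(freqs)) freqs <- codon_frequencies("F3x4", aln)
  dat <- likelihood_data(tree, aln)
  if (!has_variation(dat)) {
    return(structure(list(k = NA_real_, lnL_null = NA_real_,
                          lnL_alt = NA_real_, lrt = NA_real_,
                          p_value = NA_real_, null = NULL, alt = NULL,
                          converged = FALSE,
                          note = "no variable sites"), class = "relax_fit"))
  }
  if (is.null(branch_lengths)) {
    branch_lengths <- fit_branch_model(tree, aln, "one_ratio", freqs = freqs,
                                       control = control)
  }
  len <- resolve_lengths(dat, branch_lengths)

  b0 <- relax_bounds(control, with_k = FALSE)
  obj_null <- function(p) {
    -loglik_from_data(dat, relax_par_spec(p, freqs), tree, lengths = len)
  }
  null_best <- multi_start(relax_null_starts, obj_null, b0$lower, b0$upper,
                           control)

  k_map_of <- function(k) setNames(rep(k, length(test_ids)), test_ids)
  b1 <- relax_bounds(control, with_k = TRUE)
  obj_alt <- function(p) {
    -loglik_from_data(dat, relax_par_spec(p[-7], freqs, k_map_of(p[7])),
                      tree, lengths = len)
  }
  alt_starts <- lapply(c(1, 0.4, 2.5), function(k) c(null_best$par, k))
  alt_best <- multi_start(alt_starts, obj_alt, b1$lower, b1$upper, control)

  lnL_null <- -null_best$objective
  lnL_alt <- -alt_best$objective
  lrt <- 2 * (lnL_alt - lnL_null)
  p_value <- pchisq(max(lrt, 0), df = 1, lower.tail = FALSE)
  pn <- null_best$par; pa <- alt_best$par
  null_fit <- fit_result(lnL_null, relax_estimates(pn), null_best$any_converged,
                         null_best$n_evals)
  alt_fit <- fit_result(lnL_alt, c(relax_estimates(pa[-7]), k = pa[7]),
                        alt_best$any_converged, alt_best$n_evals)
  structure(list(k = unname(pa[7]), lnL_null = lnL_null, lnL_alt = lnL_alt,
                 lrt = lrt, p_value = p_value, null = null_fit,
                 alt = alt_fit,
                 converged = null_best$any_converged && alt_best$any_converged),
            class = "relax_fit")
}

relax_estimates <- function(p) {
  w12 <- sort(c(p[2], p[3]))
  c(kappa = exp(p[1]), omega1 = w12[1], omega2 = w12[2], omega3 = p[4],
    p1 = p[5], p2 = (1 - p[5]) * p[6], p3 = (1 - p[5]) * (1 - p[6]))
}

#' @export
print.relax_fit <- function(x, ...) {
  cat("RELAX-style test: k =", format(x$k, digits = 4),
      "| LRT =", format(x$lrt, digits = 4),
      "| p =", format(x$p_value, digits = 4),
      if (!x$converged) "(NOT converged)", "\n")
  invisible(x)
}

#' Per-branch selection intensity (general descriptive model)
#'
#' Fits the shared 3-category omega distribution with k = 1 everywhere,
#' then profiles the selection intensity of each branch in turn: branch b's
#' k is optimized over `[0, 50]` (Brent) with every other branch held at 1
#' and the shared distribution fixed at its null estimate. This
#' one-branch-at-a-time profiling is the package's tractable counterpart of
#' a joint per-branch-k fit; it identifies which branches pull toward
#' relaxation (k < 1) and is the basis of the per-branch relaxed-gene
#' fractions.
#'
#' @param tree a [tagged_tree] (tags are ignored; every branch is profiled).
#' @param aln a [codon_alignment] of at least 3 taxa.
#' @param freqs codon frequencies; default F3x4 from `aln`.
#' @param branch_lengths as in [fit_relax()].
#' @param control a [fit_control()].
#' @return object of class `gd_fit`: list with `k` (named per-branch
#'   estimates), `relaxed_branches` (ids with k < 1), `base` (the shared
#'   null fit) and `converged`.
#' @export
fit_general_descriptive <- function(tree, aln, freqs = NULL,
                                    branch_lengths = NULL,
                                    control = fit_control()) {
  if (length(tree$phy$tip.label) < 3) {
    stop("per-branch k is not identifiable on trees with fewer than 3 taxa")
  }
  if (is.null(freqs)) freqs <- codon_frequencies("F3x4", aln)
  dat <- likelihood_data(tree, aln)
  if (!has_variation(dat)) {
    stop("alignment has no variable sites; k not identifiable")
  }
  if (is.null(branch_lengths)) {
    branch_lengths <- fit_branch_model(tree, aln, "one_ratio", freqs = freqs,
                                       control = control)
  }
  len <- resolve_lengths(dat, branch_lengths)
  b0 <- relax_bounds(control, with_k = FALSE)
  obj_null <- function(p) {
    -loglik_from_data(dat, relax_par_spec(p, freqs), tree, lengths = len)
  }
  base <- multi_start(relax_null_starts, obj_null, b0$lower, b0$upper, control)
  pn <- base$par

  ids <- dat$edge_ids
  k_hat <- setNames(rep(NA_real_, length(ids)), ids)
  for (b in ids) {
    f <- function(k) {
      -loglik_from_data(dat, relax_par_spec(pn, freqs, setNames(k, b)),
                        tree, lengths = len)
    }
    opt <- optimize(f, interval = control$k_bounds, tol = 1e-3)
    k_hat[b] <- opt$minimum
  }
  structure(list(k = k_hat, relaxed_branches = names(k_hat)[k_hat < 1],
                 base = fit_result(-base$objective, relax_estimates(pn),
                                   base$any_converged, base$n_evals),
                 converged = base$any_converged),
            class = "gd_fit")
}

#' @export
print.gd_fit <- function(x, ...) {
  cat("General-descriptive fit:", length(x$k), "branches,",
      length(x$relaxed_branches), "with k < 1\n")
  invisible(x)
}
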