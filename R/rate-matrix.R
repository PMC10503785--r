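#' GY94-style codon instantaneous rate matrix
#'
#' Builds the 61x61 instantaneous rate matrix of a Goldman-Yang-style codon
#' model: codons differing at more than one nucleotide position exchange at
#' rate 0; a single-nucleotide change from codon i to codon j has rate
#' proportional to `pi_j`, multiplied by `kappa` if the change is a
#' transition and by `omega` if it is nonsynonymous. The diagonal is set so
#' rows sum to zero, and the matrix is rescaled so that the expected number
#' of substitutions per unit time at stationarity is 1, i.e. branch lengths
#' are measured in expected codon substitutions per site.
#'
#' @param kappa transition/transversion rate ratio, > 0.
#' @param omega nonsynonymous/synonymous rate ratio (dN/dS), >= 0.
#' @param freqs a [codon_frequencies] object (or plain 61-vector summing to 1).
#' @param scale if `FALSE`, skip the mean-rate-1 normalization (used by tests
#'   that check unscaled rate ratios).
#' @return 61x61 matrix of class `codon_rate_matrix`, with attributes `pi`,
#'   `kappa`, `omega` and `scale` (the divisor applied).
#' @examples
#' Q <- build_rate_matrix(2, 0.5, codon_frequencies("equal"))
#' max(abs(rowSums(Q)))  # ~ 0
#' @export
build_rate_matrix <- function(kappa, omega, freqs, scale = TRUE) {
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) ||
      kappa <= 0) {
    stop("kappa must be a single positive number")
  }
  if (!is.numeric(omega) || length(omega) != 1L || !is.finite(omega) ||
      omega < 0) {
    stop("omega must be a single nonnegative number")
  }
  pi <- as.numeric(freqs)
  validate_frequencies(pi)
  gc <- genetic_code()
  Q <- matrix(0, 61, 61, dimnames = list(gc$codons, gc$codons))
  p <- gc$pairs
  fac <- c(1, kappa, omega, kappa * omega)[p[, "type"]]
  Q[cbind(p[, "i"], p[, "j"])] <- fac * pi[p[, "j"]]
  Q[cbind(p[, "j"], p[, "i"])] <- fac * pi[p[, "i"]]
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pi * diag(Q))
  div <- 1
  if (scale) {
    if (rate <= 0) stop("degenerate rate matrix: zero total rate")
    div <- rate
    Q <- Q / rate
  }
  structure(Q, pi = pi, kappa = kappa, omega = omega, scale = div,
            class = c("codon_rate_matrix", "matrix", "array"))
}

#' Apply the selection-intensity exponent k to omega
#'
#' The branch action of a relaxation model: on a test branch with selection
#' intensity `k`, a site category with ratio `omega` evolves with effective
#' ratio `omega^k`. Values `k < 1` compress omega toward 1 (relaxation of
#' selection), `k > 1` push it away from 1 (intensification), `k = 0` is
#' complete relaxation (neutrality). The indeterminate case `0^0` is defined
#' as 1, preserving continuity in k at omega -> 0 (full relaxation of even
#' an infinitely constrained site is neutral).
#'
#' @param omega dN/dS ratio(s), >= 0.
#' @param k selection-intensity exponent(s), >= 0.
#' @return `omega ^ k`, vectorized with recycling.
#' @examples
#' apply_k(0.25, 0.5)  # 0.5
#' apply_k(0.2, 0)     # 1: fully relaxed
#' @export
apply_k <- function(omega, k) {
  if (any(omega < 0) || any(k < 0)) stop("omega and k must be nonnegative")
  out <- omega ^ k
  out[omega == 0 & k == 0] <- 1
  out
}

#' Codon transition probability matrix
#'
#' Computes `P(t) = exp(Q t)` for a reversible codon rate matrix by
#' eigendecomposition of the symmetrized matrix
#' `diag(sqrt(pi)) Q diag(1/sqrt(pi))`, which is numerically stable and
#' exact for the GY94 family (reversible by construction).
#'
#' @param Q a `codon_rate_matrix` from [build_rate_matrix()].
#' @param t branch length, >= 0 (expected substitutions per codon site).
#' @return 61x61 stochastic matrix; rows sum to 1.
#' @export
transition_probabilities <- function(Q, t) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0) {
    stop("branch length t must be a single nonnegative number")
  }
  ed <- eigen_rate_matrix(Q)
  P <- ed$C %*% (exp(ed$values * t) * ed$Cinv)
  P[P < 0] <- 0
  dimnames(P) <- dimnames(Q)
  P
}

# Eigendecomposition of a reversible Q via its symmetrization.
# Returns C, Cinv, values with Q = C diag(values) Cinv.
eigen_rate_matrix <- function(Q) {
  pi <- attr(Q, "pi")
  if (is.null(pi)) stop("Q lacks a 'pi' attribute; use build_rate_matrix()")
  s <- sqrt(pi)
  B <- unclass(Q) * (s %o% (1 / s))
  B <- (B + t(B)) / 2
  ed <- eigen(B, symmetric = TRUE)
  list(values = ed$values,
       C = ed$vectors / s,
       Cinv = t(ed$vectors) * rep(s, each = 61))
}
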