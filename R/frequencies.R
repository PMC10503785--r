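#' Codon stationary frequencies
#'
#' Equilibrium frequencies pi over the 61 sense codons, under one of the four
#' standard schemes: `equal` (1/61 each), `F1x4` (products of overall
#' nucleotide frequencies), `F3x4` (products of position-specific nucleotide
#' frequencies; the default in the model fits), or `empirical` (observed codon
#' proportions). Frequencies of the schemes that involve counting are
#' estimated from an alignment; stop-codon mass is redistributed by
#' renormalizing over sense codons.
#'
#' @param scheme one of `"equal"`, `"F1x4"`, `"F3x4"`, `"empirical"`.
#' @param aln a [codon_alignment] (required for all schemes except `equal`).
#' @return object of class `codon_frequencies`: numeric vector of 61
#'   probabilities named by codon, with attribute `scheme`.
#' @examples
#' pi <- codon_frequencies("equal")
#' sum(pi)  # 1
#' @export
codon_frequencies <- function(scheme = c("F3x4", "equal", "F1x4", "empirical"),
                              aln = NULL) {
  scheme <- match.arg(scheme)
  gc <- genetic_code()
  codons <- gc$codons
  if (scheme == "equal") {
    pi <- rep(1 / 61, 61)
  } else {
    if (is.null(aln)) stop("scheme '", scheme, "' requires an alignment")
    chars <- unlist(strsplit(as_codon_strings(aln), ""), use.names = FALSE)
    nt <- c("T", "C", "A", "G")
    if (scheme == "F1x4") {
      f <- prop.table(table(factor(chars[chars %in% nt], levels = nt)))
      pi <- vapply(strsplit(codons, ""), function(co) prod(f[co]), numeric(1))
    } else if (scheme == "F3x4") {
      pos <- rep_len(1:3, length(chars))
      f <- lapply(1:3, function(p) {
        v <- chars[pos == p]
        prop.table(table(factor(v[v %in% nt], levels = nt)))
      })
      pi <- vapply(strsplit(codons, ""),
                   function(co) f[[1]][co[1]] * f[[2]][co[2]] * f[[3]][co[3]],
                   numeric(1))
    } else {
      idx <- codon_index(as_codon_vector(aln))
      tab <- tabulate(idx[!is.na(idx)], nbins = 61)
      # pseudocount so no sense codon has zero stationary mass
      pi <- (tab + 0.5) / sum(tab + 0.5)
    }
    pi <- pi / sum(pi)
  }
  names(pi) <- codons
  validate_frequencies(pi)
  structure(pi, scheme = scheme, class = "codon_frequencies")
}

validate_frequencies <- function(pi) {
  if (length(pi) != 61L || any(!is.finite(pi)) || any(pi < 0) ||
      abs(sum(pi) - 1) > 1e-12) {
    stop("invalid codon frequencies: need 61 nonnegative values summing to 1")
  }
  invisible(pi)
}

#' @export
print.codon_frequencies <- function(x, ...) {
  cat("Codon frequencies (", attr(x, "scheme"), " scheme), 61 sense codons\n",
      sep = "")
  cat("  range:", format(range(unclass(x)), digits = 4), "\n")
  invisible(x)
}
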