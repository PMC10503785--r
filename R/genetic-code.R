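#' The standard genetic code over sense codons
#'
#' Builds the codon table used by every rate matrix and likelihood in the
#' package: the 61 sense codons of the standard genetic code, ordered
#' lexicographically over the alphabet T, C, A, G (the PAML convention, which
#' eases cross-checking against codeml output), together with their amino-acid
#' translations and a precomputed classification of every single-nucleotide
#' codon pair as transition/transversion and synonymous/nonsynonymous.
#'
#' @return An object of class `genetic_code`: a list with
#'   \describe{
#'     \item{codons}{character vector of the 61 sense codons, TCAG-lexicographic}
#'     \item{aa}{named character vector, amino acid per sense codon}
#'     \item{stop_codons}{the three stop codons}
#'     \item{pairs}{integer matrix (one row per unordered single-nucleotide
#'       sense-codon pair) with columns `i`, `j` (1-based codon indices) and
#'       `type` coding 1 = synonymous transversion, 2 = synonymous transition,
#'       3 = nonsynonymous transversion, 4 = nonsynonymous transition}
#'   }
#' @examples
#' gc <- genetic_code()
#' length(gc$codons)  # 61
#' gc$aa["ATG"]       # "M"
#' @export
genetic_code <- function() {
  if (!is.null(.selax_env$code)) return(.selax_env$code)
  nt <- c("T", "C", "A", "G")
  grid <- expand.grid(p3 = nt, p2 = nt, p1 = nt, stringsAsFactors = FALSE)
  codons_all <- paste0(grid$p1, grid$p2, grid$p3)
  aa_all <- Biostrings::GENETIC_CODE[codons_all]
  sense <- codons_all[aa_all != "*"]
  aa <- aa_all[aa_all != "*"]
  names(aa) <- sense
  stopifnot(length(sense) == 61L)

  ts_pair <- function(a, b) {
    (a %in% c("A", "G") && b %in% c("A", "G")) ||
      (a %in% c("C", "T") && b %in% c("C", "T"))
  }
  mat <- do.call(rbind, strsplit(sense, ""))
  pairs <- list()
  n <- length(sense)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      diff <- which(mat[i, ] != mat[j, ])
      if (length(diff) != 1L) next
      is_ts <- ts_pair(mat[i, diff], mat[j, diff])
      is_syn <- aa[i] == aa[j]
      type <- 1L + is_ts + 2L * !is_syn
      pairs[[length(pairs) + 1L]] <- c(i, j, type)
    }
  }
  pairs <- do.call(rbind, pairs)
  colnames(pairs) <- c("i", "j", "type")
  out <- structure(
    list(codons = sense, aa = aa, stop_codons = codons_all[aa_all == "*"],
         pairs = pairs),
    class = "genetic_code"
  )
  .selax_env$code <- out
  out
}

.selax_env <- new.env(parent = emptyenv())

#' Map codon strings to sense-codon indices
#'
#' @param x character vector of trinucleotides (T/C/A/G; `-`, `N` etc. allowed).
#' @return integer vector of 1-based indices into `genetic_code()$codons`;
#'   `NA` for gaps/ambiguities, and attribute `stop` flags in-frame stops.
#' @keywords internal
codon_index <- function(x) {
  gc <- genetic_code()
  x <- toupper(gsub("U", "T", x))
  idx <- match(x, gc$codons)
  is_stop <- x %in% gc$stop_codons
  attr(idx, "stop") <- is_stop
  idx
}
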