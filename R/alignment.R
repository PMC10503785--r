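#' Codon alignment
#'
#' An in-frame codon alignment: a character matrix of codon strings (one row
#' per taxon, one column per codon site). Gaps (`---`) and ambiguous codons
#' (anything containing a non-TCAG character) are retained and treated as
#' missing data by the likelihood machinery. In-frame stop codons are a hard
#' error: the conserved single-copy genes these analyses target should be
#' clean, and a stop indicates a frame or annotation problem.
#'
#' @param seqs named character vector of aligned nucleotide sequences
#'   (equal lengths, divisible by 3), or a character matrix of codons.
#' @return object of class `codon_alignment`: character matrix with rownames
#'   = taxa.
#' @export
codon_alignment <- function(seqs) {
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
      stop("sequences must have unique names")
    }
    n <- unique(nchar(seqs))
    if (length(n) != 1L) stop("sequences must be aligned (equal lengths)")
    if (n %% 3 != 0) stop("alignment length ", n, " is not divisible by 3")
    seqs <- toupper(gsub("U", "T", seqs))
    m <- matrix(unlist(lapply(seqs, function(s) {
      substring(s, seq(1, n, 3), seq(3, n, 3))
    }), use.names = FALSE), nrow = length(seqs), byrow = TRUE,
    dimnames = list(names(seqs), NULL))
  }
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
    stop("codon alignment requires unique taxon names")
  }
  gc <- genetic_code()
  stops <- matrix(m %in% gc$stop_codons, nrow = nrow(m))
  if (any(stops)) {
    bad <- rownames(m)[which(rowSums(stops) > 0)]
    stop("in-frame stop codon(s) in: ", paste(bad, collapse = ", "))
  }
  structure(m, class = c("codon_alignment", "matrix", "array"))
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("Codon alignment:", nrow(x), "taxa x", ncol(x), "codon sites\n")
  invisible(x)
}

# full nucleotide strings per taxon
as_codon_strings <- function(aln) apply(unclass(aln), 1, paste0, collapse = "")

# flat codon vector (column-major over sites within taxa)
as_codon_vector <- function(aln) as.vector(t(unclass(aln)))

#' Amino-acid alignment
#'
#' @param seqs named character vector of aligned protein sequences, or a
#'   character matrix of single residues with taxon rownames.
#' @return object of class `amino_alignment`: character matrix, one residue
#'   per cell, uppercase.
#' @export
amino_alignment <- function(seqs) {
  if (is.matrix(seqs)) {
    m <- toupper(seqs)
  } else {
    if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
      stop("sequences must have unique names")
    }
    n <- unique(nchar(seqs))
    if (length(n) != 1L) stop("sequences must be aligned (equal lengths)")
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(m) <- names(seqs)
  }
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
    stop("amino alignment requires unique taxon names")
  }
  structure(m, class = c("amino_alignment", "matrix", "array"))
}

#' @export
print.amino_alignment <- function(x, ...) {
  cat("Amino-acid alignment:", nrow(x), "taxa x", ncol(x), "columns\n")
  invisible(x)
}

# The twenty standard residues
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Translate a codon alignment
#'
#' @param aln a [codon_alignment].
#' @return an [amino_alignment]; gap and ambiguous codons become `-`/`X`.
#' @export
translate_alignment <- function(aln) {
  gc <- genetic_code()
  m <- unclass(aln)
  aa <- matrix("X", nrow(m), ncol(m), dimnames = dimnames(m))
  aa[m == "---"] <- "-"
  idx <- match(m, gc$codons)
  aa[!is.na(idx)] <- gc$aa[idx[!is.na(idx)]]
  amino_alignment(aa)
}
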