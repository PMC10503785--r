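#' Read a FASTA file
#'
#' Thin wrapper around Biostrings' FASTA reader that accepts wrapped and
#' unwrapped dialects and CRLF line endings, and adds the validation the
#' pipeline needs: duplicate ids and empty sequences are explicit errors
#' naming the offending record and its header line number.
#'
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- setNames(as.character(ss), ids)
  lines <- readLines(path, warn = FALSE)
  header_lines <- which(startsWith(lines, ">"))
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    ln <- header_lines[which(ids == dup)[2]]
    stop("duplicate sequence id '", dup, "' at line ", ln)
  }
  empty <- which(nchar(seqs) == 0)
  if (length(empty)) {
    stop("empty sequence '", ids[empty[1]], "' at line ",
         header_lines[empty[1]])
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must have unique names")
  }
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read a codon alignment from FASTA
#'
#' @param path FASTA file of aligned in-frame nucleotide sequences.
#' @return a [codon_alignment].
#' @export
read_codon_alignment <- function(path) codon_alignment(read_fasta(path))

#' Read an amino-acid alignment from FASTA
#'
#' @param path FASTA file of aligned protein sequences.
#' @return an [amino_alignment].
#' @export
read_amino_alignment <- function(path) amino_alignment(read_fasta(path))

#' Write a codon or amino-acid alignment to FASTA
#'
#' @param aln a [codon_alignment] or [amino_alignment].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  write_fasta(apply(unclass(aln), 1, paste0, collapse = ""), path)
}

# --- tagged newick ----------------------------------------------------------

#' Read a newick tree with branch tags
#'
#' Parses a newick file (or string) in which branches may carry a tag in
#' curly braces after the branch length (or after the label when lengths
#' are absent), e.g. `((A:1,B:1):1{test},C:2);` tags the internal branch
#' as `test`. Untagged branches default to `reference`. Tags annotate the
#' branch leading to the node they follow.
#'
#' @param path path to a newick file, or (if `text` is given) ignored.
#' @param text optional newick string, used instead of `path`.
#' @return a [tagged_tree].
#' @export
read_tagged_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (!file.exists(path)) stop("no such file: ", path)
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  if (!grepl(";", text)) stop("malformed newick: missing ';'")
  if (grepl("\\{[^}]*\\{", text)) stop("malformed tag syntax")
  # move {tag} into the node-label position so ape can parse it
  sentinel <- "__TAG__"
  tagged <- gsub("([A-Za-z0-9_.|-]*)(:[0-9.eE+-]+)?\\{([A-Za-z0-9_.-]+)\\}",
                 paste0("\\1", sentinel, "\\3\\2"), text)
  phy <- ape::read.tree(text = tagged)
  if (is.null(phy)) stop("malformed newick")
  extract <- function(labels) {
    has <- grepl(sentinel, labels, fixed = TRUE)
    tag <- ifelse(has, sub(paste0(".*", sentinel), "", labels), NA)
    list(label = ifelse(has, sub(paste0(sentinel, ".*"), "", labels), labels),
         tag = tag)
  }
  tips <- extract(phy$tip.label)
  phy$tip.label <- tips$label
  nodes <- if (!is.null(phy$node.label)) extract(phy$node.label) else NULL
  if (!is.null(nodes)) phy$node.label <- nodes$label
  if (is.null(phy$edge.length)) phy$edge.length <- rep(1, nrow(phy$edge))
  tr <- tagged_tree(phy)
  ntip <- length(phy$tip.label)
  child <- phy$edge[, 2]
  tag_of_child <- rep(NA_character_, max(child))
  tag_of_child[seq_len(ntip)] <- tips$tag
  if (!is.null(nodes)) tag_of_child[ntip + seq_along(nodes$tag)] <- nodes$tag
  has_tag <- !is.na(tag_of_child[child])
  tr$tags[has_tag] <- tag_of_child[child[has_tag]]
  tr
}

#' Write a tagged tree to newick
#'
#' Inverse of [read_tagged_newick()]: branch tags other than `reference`
#' are written as `{tag}` after the branch length.
#'
#' @param tree a [tagged_tree].
#' @param path output path; `NULL` returns the newick string.
#' @param digits branch-length precision.
#' @return the newick string, invisibly if written to a file.
#' @export
write_tagged_newick <- function(tree, path = NULL, digits = 15) {
  stopifnot(inherits(tree, "tagged_tree"))
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  tag_of_child <- setNames(tree$tags, phy$edge[, 2])
  fmt <- function(x) sprintf("%.*g", digits, x)
  build <- function(node) {
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    inner <- if (length(kids)) {
      paste0("(", paste(vapply(kids, build, character(1)), collapse = ","),
             ")")
    } else ""
    lab <- if (node <= ntip) phy$tip.label[node] else ""
    e <- which(phy$edge[, 2] == node)
    suffix <- if (length(e)) {
      tg <- tree$tags[e]
      paste0(":", fmt(phy$edge.length[e]),
             if (tg != "reference") paste0("{", tg, "}") else "")
    } else ""
    paste0(inner, lab, suffix)
  }
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  out <- paste0(build(root), ";")
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

# --- annotations ------------------------------------------------------------

#' Read a GFF3 annotation
#'
#' @param path GFF3 file (1-based closed coordinates on disk, as the format
#'   specifies; returned unchanged in the `GRanges` convention).
#' @param feature optional feature type filter (GFF3 column 3).
#' @return a `GRanges`.
#' @export
read_gff3 <- function(path, feature = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (!is.null(feature)) gr <- gr[gr$type %in% feature]
  gr
}

#' Read a BED annotation
#'
#' BED's 0-based half-open coordinates are converted to the 1-based closed
#' `GRanges` convention by the importer, so a BED line `chr 0 10` and a
#' GFF3 line with start=1, end=10 describe the same interval and yield
#' identical ranges.
#'
#' @param path BED file.
#' @return a `GRanges`.
#' @export
read_bed <- function(path) rtracklayer::import(path, format = "bed")

#' Write intervals to BED
#'
#' @param gr a `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

# --- tables with provenance headers -----------------------------------------

# deterministic 32-bit FNV-1a hash of a config list (timestamps excluded by
# construction: only the deparsed key=value pairs enter the hash)
config_hash <- function(config) {
  if (length(config)) config <- config[order(names(config))]
  txt <- paste(names(config),
               vapply(config, function(v) paste(format(v), collapse = ","),
                      character(1)),
               sep = "=", collapse = ";")
  h <- 2166136261
  for (b in utf8ToInt(txt)) {
    h <- (h * 31 + b) %% 4294967296  # stays well below 2^53
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write a table as TSV with a provenance header
#'
#' Tab-separated values preceded by commented header lines recording the
#' package version, the stage name, the seed and a hash of the
#' configuration, so any output can be traced to the run that produced it;
#' reruns with identical configuration and inputs are byte-identical.
#' Missing values are written as `NA`.
#'
#' @param df a data.frame.
#' @param path output path.
#' @param stage pipeline stage name recorded in the header.
#' @param seed seed recorded in the header.
#' @param config optional named list hashed into the header.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, stage = "table", seed = NA, config = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# selax %s | stage=%s | seed=%s | config=%s",
                     as.character(utils::packageVersion("selax")),
                     stage, seed, config_hash(config)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path input path.
#' @return data.frame (comment lines skipped).
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE)
}

#' Read a residue category scheme from a text table
#'
#' One class per line: `class_name<TAB or spaces>residues` with residues
#' given as one-letter codes, separated or not (e.g.
#' `negative  D E` or `negative DE`).
#'
#' @param path text file path.
#' @param name scheme label (default: the file's base name).
#' @return a [category_scheme()].
#' @export
read_category_scheme <- function(path, name = NULL) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  classes <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "[ \t]+")[[1]]
    res <- unlist(strsplit(parts[-1], ""))
    classes[[parts[1]]] <- res[res != ""]
  }
  category_scheme(classes, name = if (is.null(name)) basename(path) else name)
}
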