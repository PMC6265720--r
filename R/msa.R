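#' @importFrom stats median optimize pchisq qnorm rbeta rexp rgamma runif sd
#'   setNames aggregate lm pf qgamma pgamma rbinom wilcox.test kruskal.test
#'   as.dist rgeom
#' @importFrom utils combn head
NULL

#' The 20 standard amino acid one-letter codes
#'
#' Alphabet used throughout: residues are restricted to these 20 symbols
#' plus the gap character \code{"-"} in alignments.
#' @export
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a multiple sequence alignment object
#'
#' A light container for an aligned protein family: named aligned sequences
#' over the 20 standard residues plus the gap character \code{"-"}, with a
#' family identifier. All rows must have equal aligned length.
#'
#' @param seqs named character vector of aligned sequences (gap char "-").
#' @param family_id character scalar family identifier.
#' @return an object of class \code{"msa"}.
#' @export
msa <- function(seqs, family_id = "family") {
  if (length(seqs) == 0L) stop("empty alignment")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names")
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("rows differ in aligned length")
  obj <- structure(list(family_id = family_id, seqs = seqs),
                   class = "msa")
  obj
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa '%s': %d sequences x %d columns\n",
              x$family_id, length(x$seqs), msa_ncol(x)))
  invisible(x)
}

#' Number of alignment columns
#' @param x an \code{msa}.
#' @return integer column count.
#' @export
msa_ncol <- function(x) nchar(x$seqs[[1L]])

#' Alignment as a character matrix
#'
#' @param x an \code{msa}.
#' @return character matrix, one row per sequence, rownames = sequence ids.
#' @export
msa_matrix <- function(x) {
  m <- do.call(rbind, strsplit(unname(x$seqs), "", fixed = TRUE))
  rownames(m) <- names(x$seqs)
  m
}

#' Ungapped sequences of an alignment
#' @param x an \code{msa}.
#' @return named character vector with gap characters removed.
#' @export
msa_ungap <- function(x) {
  vapply(x$seqs, function(s) gsub("-", "", s, fixed = TRUE), character(1))
}

#' Alignment-column to residue-index coordinate maps
#'
#' For each row, maps every alignment column (0-based) to the 0-based index
#' of the residue occupying it, or \code{NA} for gap cells.
#'
#' @param x an \code{msa}.
#' @return list (one per row) of integer vectors of length \code{msa_ncol(x)}.
#' @export
msa_coordinate_map <- function(x) {
  m <- msa_matrix(x)
  lapply(seq_len(nrow(m)), function(i) {
    res <- m[i, ] != "-"
    idx <- rep(NA_integer_, ncol(m))
    idx[res] <- seq_len(sum(res)) - 1L
    idx
  })
}

#' Read an aligned FASTA file into an msa
#' @param path FASTA file path.
#' @param family_id family identifier (defaults to the file name).
#' @return an \code{msa}.
#' @export
read_msa <- function(path, family_id = sub("\\.[^.]*$", "", basename(path))) {
  ss <- Biostrings::readAAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  msa(seqs, family_id = family_id)
}

#' Write an msa to aligned FASTA
#' @param x an \code{msa}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_msa <- function(x, path) {
  ss <- Biostrings::AAStringSet(x$seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
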