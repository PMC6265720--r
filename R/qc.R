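# Alignment suitability filtering: five conditions an aligned family must
# meet before site-rate inference (minimum pairwise identity, per-row
# coverage, clean alphabet, non-trivial variability, enough unique rows).

#' Pairwise p-distance between two aligned rows
#'
#' Fraction of mismatching residues among compared positions, where a
#' position is compared only if both rows carry a residue there (pairwise
#' deletion of gap columns). Identity is \code{1 - p_distance}.
#'
#' @param row_a,row_b aligned strings (or character vectors) of equal length.
#' @return mismatch fraction in [0, 1].
#' @export
p_distance <- function(row_a, row_b) {
  a <- if (length(row_a) == 1L) strsplit(row_a, "")[[1L]] else row_a
  b <- if (length(row_b) == 1L) strsplit(row_b, "")[[1L]] else row_b
  if (length(a) != length(b)) stop("rows differ in aligned length")
  cmp <- a != "-" & b != "-"
  n <- sum(cmp)
  if (n == 0L) stop("undefined distance: no position where both rows have a residue")
  sum(a[cmp] != b[cmp]) / n
}

#' Matrix of pairwise p-distances for an alignment
#' @param x an \code{msa}.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(x) {
  m <- msa_matrix(x)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      d[i, j] <- d[j, i] <- p_distance(m[i, ], m[j, ])
    }
  }
  d
}

#' Alignment suitability filters
#'
#' Applies five conditions to an aligned family and reports each measured
#' value alongside its verdict:
#' \enumerate{
#'   \item minimum pairwise identity (1 - p-distance) over all row pairs is
#'     at least \code{min_identity};
#'   \item every row's residue count is at least \code{min_coverage} times
#'     the alignment length;
#'   \item no characters outside the 20 standard residues and \code{"-"};
#'   \item fewer than \code{max_conserved} of the columns are conserved,
#'     where a conserved column is gap-free and invariant;
#'   \item at least \code{min_unique} distinct ungapped sequences.
#' }
#' Columns containing gaps count as non-conserved in condition 4 (consistent
#' with the downstream exclusion of gapped columns from labeling); this is a
#' documented convention, not forced by the rules themselves.
#'
#' @param x an \code{msa}.
#' @param min_identity minimum pairwise identity (default 0.30).
#' @param min_coverage minimum row length as fraction of alignment length
#'   (default 0.50).
#' @param max_conserved maximum conserved-column fraction, exclusive
#'   (default 0.90).
#' @param min_unique minimum number of distinct ungapped sequences (default 4).
#' @return a \code{qc_report} list: per-filter measured values and verdicts,
#'   and overall \code{pass} (true iff all five pass).
#' @export
qc_filter <- function(x, min_identity = 0.30, min_coverage = 0.50,
                      max_conserved = 0.90, min_unique = 4L) {
  if (!inherits(x, "msa")) stop("x must be an msa")
  m <- msa_matrix(x)
  nc <- ncol(m)
  if (nc == 0L) stop("empty alignment")

  dmat <- p_distance_matrix(x)
  min_ident <- if (nrow(m) > 1L) 1 - max(dmat) else 1

  row_res <- rowSums(m != "-")
  min_len_frac <- min(row_res) / nc

  ok_chars <- all(m %in% c(AA20, "-"))

  gap_free <- colSums(m == "-") == 0L
  invariant <- apply(m, 2L, function(col) length(unique(col)) == 1L)
  conserved_frac <- sum(gap_free & invariant) / nc

  n_unique <- length(unique(msa_ungap(x)))

  checks <- c(
    min_identity    = min_ident >= min_identity,
    min_coverage    = min_len_frac >= min_coverage,
    standard_chars  = ok_chars,
    not_conserved   = conserved_frac < max_conserved,
    unique_rows     = n_unique >= min_unique
  )
  structure(list(
    family_id = x$family_id,
    values = list(min_pairwise_identity = min_ident,
                  min_length_fraction = min_len_frac,
                  ambiguous_characters = !ok_chars,
                  conserved_fraction = conserved_frac,
                  n_unique_sequences = n_unique),
    checks = checks,
    pass = all(checks)
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report '%s': %s\n", x$family_id,
              if (x$pass) "PASS" else "FAIL"))
  for (nm in names(x$checks))
    cat(sprintf("  %-15s %s\n", nm, if (x$checks[[nm]]) "ok" else "FAIL"))
  invisible(x)
}
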