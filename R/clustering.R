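# Homolog clustering: all-vs-all local alignment, linkage by identity and
# footprint-coverage thresholds, then graph-based single linkage with
# cluster-size bounds.

#' Validate an unaligned protein record set
#'
#' Enforces the curation rules applied before clustering: sequences of at
#' least 30 residues, only the 20 standard amino acids (no X or other
#' ambiguity codes), no gap characters.
#'
#' @param seqs named character vector of unaligned sequences.
#' @param min_length minimum sequence length (default 30).
#' @return the validated named vector, invisibly unchanged.
#' @export
validate_protein_records <- function(seqs, min_length = 30L) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique ids")
  bad_len <- nchar(seqs) < min_length
  if (any(bad_len))
    stop("sequence(s) shorter than ", min_length, " residues: ",
         paste(names(seqs)[bad_len], collapse = ", "))
  chars <- unique(unlist(strsplit(unname(seqs), "")))
  extra <- setdiff(chars, AA20)
  if (length(extra) > 0L)
    stop("non-standard characters in input sequences: ",
         paste(extra, collapse = ", "))
  invisible(seqs)
}

#' Best local alignment between two protein sequences
#'
#' Smith-Waterman local alignment via \code{Biostrings::pairwiseAlignment}
#' with BLOSUM62 scores and affine gap penalties (defaults: open 11,
#' extend 1, the conventional protein-search setting). Identity is computed
#' as matches divided by the alignment footprint length, where the footprint
#' is the number of local-alignment columns including gap columns.
#'
#' @param a,b character scalars (protein sequences).
#' @param substitution substitution matrix name or matrix (default
#'   "BLOSUM62").
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @return list of class \code{"pairwise_hit"}: \code{identity},
#'   \code{footprint_length}, \code{score}.
#' @export
pairwise_local_align <- function(a, b, substitution = "BLOSUM62",
                                 gap_open = 11, gap_extend = 1) {
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = substitution,
    gapOpening = gap_open, gapExtension = gap_extend)
  score <- Biostrings::score(al)
  if (score <= 0) {
    return(structure(list(identity = 0, footprint_length = 0L, score = score),
                     class = "pairwise_hit"))
  }
  pat <- as.character(Biostrings::alignedPattern(al))
  sub <- as.character(Biostrings::alignedSubject(al))
  width <- nchar(pat)
  matches <- sum(strsplit(pat, "")[[1L]] == strsplit(sub, "")[[1L]])
  structure(list(identity = matches / width, footprint_length = width,
                 score = score), class = "pairwise_hit")
}

#' Linkage decision for a pairwise hit
#'
#' Two sequences are linked iff their pairwise identity is at least
#' \code{min_identity} and the alignment footprint covers at least
#' \code{min_coverage} of the longer sequence. Both thresholds inclusive.
#'
#' @param hit a \code{pairwise_hit}.
#' @param len_a,len_b full (unaligned) lengths of the two sequences.
#' @param min_identity identity threshold (default 0.40).
#' @param min_coverage footprint coverage of the longer sequence
#'   (default 0.90).
#' @return logical.
#' @export
link <- function(hit, len_a, len_b, min_identity = 0.40, min_coverage = 0.90) {
  hit$identity >= min_identity &&
    hit$footprint_length >= min_coverage * max(len_a, len_b)
}

#' All-vs-all linkage hits for a record set
#'
#' Applies an exact length-ratio prefilter before aligning: a pair whose
#' shorter sequence is less than \code{min_coverage * min_identity} of the
#' longer one can never satisfy both linkage thresholds (the footprint is at
#' most the shorter length, and matches at most the shorter length, so
#' either coverage or identity must fail), and is skipped without aligning.
#'
#' @param seqs named character vector of protein sequences.
#' @param min_identity,min_coverage linkage thresholds.
#' @param ... passed to \code{pairwise_local_align}.
#' @return data.frame (id_a, id_b, identity, footprint_length, linked).
#' @export
pairwise_hits <- function(seqs, min_identity = 0.40, min_coverage = 0.90,
                          ...) {
  validate_protein_records(seqs)
  ids <- names(seqs)
  n <- length(ids)
  rows <- list()
  for (i in seq_len(max(0L, n - 1L))) for (j in seq(i + 1L, n)) {
    la <- nchar(seqs[[i]]); lb <- nchar(seqs[[j]])
    if (min(la, lb) < min_coverage * min_identity * max(la, lb)) next
    hit <- pairwise_local_align(seqs[[i]], seqs[[j]], ...)
    rows[[length(rows) + 1L]] <- data.frame(
      id_a = ids[i], id_b = ids[j], identity = hit$identity,
      footprint_length = hit$footprint_length,
      linked = link(hit, la, lb, min_identity, min_coverage),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(id_a = character(0), id_b = character(0),
                      identity = numeric(0), footprint_length = integer(0),
                      linked = logical(0)))
  do.call(rbind, rows)
}

#' Single-linkage clusters from linkage edges
#'
#' Connected components of the graph whose vertices are the input ids and
#' whose edges are the linked pairs, filtered to components whose size lies
#' within \code{size_range} (inclusive). Singletons and out-of-range
#' components are dropped.
#'
#' @param ids character vector of all sequence ids.
#' @param edges data.frame with columns \code{id_a}, \code{id_b} and
#'   (optionally) logical \code{linked}; rows with \code{linked == FALSE}
#'   are ignored.
#' @param size_range two-element numeric, inclusive component-size bounds
#'   (default c(10, 300)).
#' @return list of class \code{"cluster_set"}: \code{clusters} (list of id
#'   character vectors, each sorted), \code{size_range}.
#' @export
single_linkage <- function(ids, edges, size_range = c(10, 300)) {
  if (nrow(edges) > 0L) {
    if ("linked" %in% names(edges)) edges <- edges[edges$linked, , drop = FALSE]
    unknown <- setdiff(unique(c(edges$id_a, edges$id_b)), ids)
    if (length(unknown) > 0L)
      stop("edges reference unknown ids: ", paste(unknown, collapse = ", "))
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(ids), name = ids)
  if (nrow(edges) > 0L)
    g <- igraph::add_edges(g, rbind(edges$id_a, edges$id_b))
  comp <- igraph::components(g)
  members <- split(ids, comp$membership)
  keep <- vapply(members, function(m)
    length(m) >= size_range[1L] && length(m) <= size_range[2L], logical(1))
  clusters <- unname(lapply(members[keep], sort))
  clusters <- clusters[order(vapply(clusters, `[`, character(1), 1L))]
  structure(list(clusters = clusters, size_range = size_range),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters (size range [%g, %g])\n",
              length(x$clusters), x$size_range[1L], x$size_range[2L]))
  invisible(x)
}

#' Cluster a record set end to end
#'
#' @param seqs named character vector of protein sequences.
#' @param min_identity,min_coverage linkage thresholds.
#' @param size_range inclusive cluster-size bounds.
#' @param ... passed to \code{pairwise_local_align}.
#' @return a \code{cluster_set}.
#' @export
cluster_sequences <- function(seqs, min_identity = 0.40, min_coverage = 0.90,
                              size_range = c(10, 300), ...) {
  hits <- pairwise_hits(seqs, min_identity, min_coverage, ...)
  single_linkage(names(seqs), hits, size_range)
}

#' Write cluster membership as TSV
#' @param cs a \code{cluster_set}.
#' @param path output path (columns cluster_id, sequence_id).
#' @return invisibly, the path.
#' @export
write_clusters_tsv <- function(cs, path) {
  df <- do.call(rbind, lapply(seq_along(cs$clusters), function(k)
    data.frame(cluster_id = sprintf("cluster%04d", k),
               sequence_id = cs$clusters[[k]], stringsAsFactors = FALSE)))
  if (is.null(df))
    df <- data.frame(cluster_id = character(0), sequence_id = character(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
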