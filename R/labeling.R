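# Conserved tri-factor site labeling: map per-residue annotation tracks onto
# alignment columns, exclude any column containing a gap, and assign the
# three binary factor labels only where the prediction is unanimous across
# all sequences.

#' Construct an annotation bundle from per-sequence tracks
#'
#' @param disorder named list of per-residue disorder propensity scores in
#'   [0, 1].
#' @param ss named list of per-residue secondary-structure states
#'   ("H"/"E"/"C").
#' @param domains named list of data.frames with 0-based half-open
#'   \code{start}, \code{end} residue intervals (merged if overlapping).
#' @return an \code{annotation_bundle}.
#' @export
annotation_bundle <- function(disorder, ss, domains) {
  ids <- names(disorder)
  if (!setequal(ids, names(ss)) || !setequal(ids, names(domains)))
    stop("disorder, ss and domain tracks must cover the same sequence ids")
  for (id in ids) {
    if (length(disorder[[id]]) != length(ss[[id]]))
      stop("track length mismatch for sequence ", id)
    if (any(disorder[[id]] < 0 | disorder[[id]] > 1))
      stop("disorder scores must lie in [0, 1] (sequence ", id, ")")
    if (!all(ss[[id]] %in% SS_STATES))
      stop("secondary-structure states must be H, E or C (sequence ", id, ")")
    ivs <- domains[[id]]
    n <- length(disorder[[id]])
    if (nrow(ivs) > 0L) {
      if (any(ivs$start < 0 | ivs$end > n | ivs$end <= ivs$start))
        stop("domain interval out of bounds for sequence ", id)
      domains[[id]] <- merge_intervals(ivs)
    }
  }
  structure(list(disorder = disorder, ss = ss, domains = domains),
            class = "annotation_bundle")
}

#' Map per-residue annotations onto alignment columns
#'
#' Uses the alignment coordinate map to place every sequence's disorder
#' score, secondary-structure state and domain membership at its alignment
#' column; gap cells carry NA.
#'
#' @param x an \code{msa}.
#' @param annotations an \code{annotation_bundle} covering every row, with
#'   track lengths equal to each row's ungapped length.
#' @return list of three matrices (rows x columns): \code{disorder}
#'   (numeric), \code{ss} (character), \code{in_domain} (logical).
#' @export
map_to_columns <- function(x, annotations) {
  ids <- names(x$seqs)
  missing <- setdiff(ids, names(annotations$disorder))
  if (length(missing) > 0L)
    stop("no annotations for sequence(s): ", paste(missing, collapse = ", "))
  cmap <- msa_coordinate_map(x)
  nc <- msa_ncol(x)
  dis <- matrix(NA_real_, length(ids), nc, dimnames = list(ids, NULL))
  ssm <- matrix(NA_character_, length(ids), nc, dimnames = list(ids, NULL))
  dom <- matrix(NA, length(ids), nc, dimnames = list(ids, NULL))
  ungapped <- msa_ungap(x)
  for (i in seq_along(ids)) {
    id <- ids[i]
    n_res <- nchar(ungapped[[id]])
    if (length(annotations$disorder[[id]]) != n_res)
      stop("track length (", length(annotations$disorder[[id]]),
           ") does not match ungapped length (", n_res,
           ") for sequence ", id)
    ridx <- cmap[[i]]  # 0-based residue index per column, NA at gaps
    res <- !is.na(ridx)
    dis[i, res] <- annotations$disorder[[id]][ridx[res] + 1L]
    ssm[i, res] <- annotations$ss[[id]][ridx[res] + 1L]
    in_dom <- rep(FALSE, n_res)
    ivs <- annotations$domains[[id]]
    if (nrow(ivs) > 0L) for (k in seq_len(nrow(ivs)))
      in_dom[seq(ivs$start[k] + 1L, ivs$end[k])] <- TRUE
    dom[i, res] <- in_dom[ridx[res] + 1L]
  }
  list(disorder = dis, ss = ssm, in_domain = dom)
}

#' Disorder label of one gap-free column
#'
#' "disordered" iff every score is strictly above the cutoff, "ordered" iff
#' every score is strictly below it; a score exactly at the cutoff, or a
#' mixed column, leaves the site unlabeled.
#'
#' @param scores numeric disorder scores of all sequences at the column.
#' @param cutoff disorder propensity cutoff (default 0.4).
#' @return "disordered", "ordered" or "unlabeled".
#' @export
label_disorder <- function(scores, cutoff = 0.4) {
  if (all(scores > cutoff)) "disordered"
  else if (all(scores < cutoff)) "ordered"
  else "unlabeled"
}

#' Secondary-structure label of one gap-free column
#'
#' "structured" iff all sequences are in a helix or all in a strand (the
#' same element type across sequences); "coil" iff all are in random coil;
#' otherwise unlabeled (mixed types satisfy neither clause).
#'
#' @param states character states ("H"/"E"/"C") of all sequences.
#' @return "structured", "coil" or "unlabeled".
#' @export
label_ss <- function(states) {
  if (all(states == "H") || all(states == "E")) "structured"
  else if (all(states == "C")) "coil"
  else "unlabeled"
}

#' Domain label of one gap-free column
#'
#' "domain" iff every sequence's residue lies inside a predicted domain,
#' "linker" iff none does; otherwise unlabeled.
#'
#' @param in_domain logical domain membership of all sequences.
#' @return "domain", "linker" or "unlabeled".
#' @export
label_domain <- function(in_domain) {
  if (all(in_domain)) "domain"
  else if (!any(in_domain)) "linker"
  else "unlabeled"
}

#' Build the conserved site-label table for a family
#'
#' Applies gap exclusion (a column with any gap character gets no labels)
#' and the three unanimity rules to every column.
#'
#' @param x an \code{msa}.
#' @param annotations an \code{annotation_bundle}.
#' @param cutoff disorder cutoff (default 0.4).
#' @return list of class \code{"site_label_table"}: \code{table} (data.frame
#'   with family_id, column_index 0-based, gap_free, disorder_label,
#'   ss_label, domain_label, tri_factor_complete) and \code{summary} (named
#'   site counts).
#' @export
build_label_table <- function(x, annotations, cutoff = 0.4) {
  mapped <- map_to_columns(x, annotations)
  nc <- msa_ncol(x)
  gap_free <- colSums(is.na(mapped$disorder)) == 0L
  dis_lab <- ss_lab <- dom_lab <- rep("unlabeled", nc)
  for (j in which(gap_free)) {
    dis_lab[j] <- label_disorder(mapped$disorder[, j], cutoff)
    ss_lab[j] <- label_ss(mapped$ss[, j])
    dom_lab[j] <- label_domain(mapped$in_domain[, j])
  }
  tri <- gap_free & dis_lab != "unlabeled" & ss_lab != "unlabeled" &
    dom_lab != "unlabeled"
  tab <- data.frame(
    family_id = x$family_id,
    column_index = seq_len(nc) - 1L,
    gap_free = gap_free,
    disorder_label = dis_lab, ss_label = ss_lab, domain_label = dom_lab,
    tri_factor_complete = tri,
    stringsAsFactors = FALSE)
  summary <- c(
    total_sites = nc,
    gap_free_sites = sum(gap_free),
    ordered_sites = sum(dis_lab == "ordered"),
    disordered_sites = sum(dis_lab == "disordered"),
    structured_sites = sum(ss_lab == "structured"),
    coil_sites = sum(ss_lab == "coil"),
    domain_sites = sum(dom_lab == "domain"),
    linker_sites = sum(dom_lab == "linker"),
    tri_factor_sites = sum(tri))
  structure(list(table = tab, summary = summary),
            class = "site_label_table")
}

#' @export
print.site_label_table <- function(x, ...) {
  cat("site_label_table:\n")
  print(x$summary)
  invisible(x)
}

#' Read annotation tracks from tabular files
#'
#' Formats mirror common predictor outputs: disorder as TSV
#' (sequence_id, residue_index 0-based, score), secondary structure as TSV
#' (sequence_id, states) with one H/E/C string per sequence, domains as TSV
#' (sequence_id, start, end[, domain_name]) with 0-based half-open
#' intervals.
#'
#' @param disorder_path,ss_path,domain_path file paths.
#' @return an \code{annotation_bundle}.
#' @export
read_annotations <- function(disorder_path, ss_path, domain_path) {
  dis <- utils::read.delim(disorder_path, stringsAsFactors = FALSE)
  ss <- utils::read.delim(ss_path, stringsAsFactors = FALSE)
  dom <- utils::read.delim(domain_path, stringsAsFactors = FALSE)
  ids <- unique(dis$sequence_id)
  dlist <- lapply(split(dis, dis$sequence_id), function(d)
    d$score[order(d$residue_index)])
  slist <- setNames(strsplit(ss$states, ""), ss$sequence_id)
  ivlist <- setNames(lapply(ids, function(id) {
    d <- dom[dom$sequence_id == id, , drop = FALSE]
    data.frame(start = as.integer(d$start), end = as.integer(d$end))
  }), ids)
  annotation_bundle(dlist[ids], slist[ids], ivlist)
}

#' Write annotation tracks of a bundle to tabular files
#'
#' @param annotations an \code{annotation_bundle}.
#' @param disorder_path,ss_path,domain_path output paths.
#' @return invisibly, NULL.
#' @export
write_annotations <- function(annotations, disorder_path, ss_path,
                              domain_path) {
  ids <- names(annotations$disorder)
  dis <- do.call(rbind, lapply(ids, function(id)
    data.frame(sequence_id = id,
               residue_index = seq_along(annotations$disorder[[id]]) - 1L,
               score = annotations$disorder[[id]])))
  utils::write.table(dis, disorder_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ss <- data.frame(sequence_id = ids,
                   states = vapply(annotations$ss[ids], paste,
                                   character(1), collapse = ""))
  utils::write.table(ss, ss_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  dom <- do.call(rbind, lapply(ids, function(id) {
    ivs <- annotations$domains[[id]]
    if (nrow(ivs) == 0L) return(NULL)
    data.frame(sequence_id = id, start = ivs$start, end = ivs$end,
               domain_name = sprintf("%s_dom%d", id, seq_len(nrow(ivs))))
  }))
  if (is.null(dom))
    dom <- data.frame(sequence_id = character(0), start = integer(0),
                      end = integer(0), domain_name = character(0))
  utils::write.table(dom, domain_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}
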