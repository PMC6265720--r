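# End-to-end orchestration: per-family QC -> tree -> rate inference ->
# labeling -> joined per-site table, then the pooled statistical battery and
# a dataset summary. Synthetic mode consumes family_truth objects; real-data
# mode consumes (alignment, tree, annotations) bundles read from files.

#' Pipeline configuration
#'
#' All thresholds of the workflow with their standard defaults: linkage
#' identity 0.40 and coverage 0.90, cluster size bounds [10, 300], the five
#' alignment filters (0.30 / 0.50 / 0.90 / 4), disorder cutoff 0.4, 16
#' gamma categories, and significance level 0.05.
#'
#' @param min_identity,min_coverage linkage thresholds for clustering.
#' @param cluster_size inclusive cluster-size bounds.
#' @param qc_identity,qc_coverage,qc_conserved,qc_unique alignment filters.
#' @param disorder_cutoff disorder propensity cutoff.
#' @param n_categories discrete-gamma categories.
#' @param alpha_test significance level for post-hoc comparisons.
#' @param use_true_tree in synthetic mode, use the generating tree instead
#'   of rebuilding one by neighbor joining (default FALSE: the tree is
#'   re-estimated, as in a real run).
#' @param loess_span,loess_min_families disorder-content regression settings.
#' @return list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(min_identity = 0.40, min_coverage = 0.90,
                            cluster_size = c(10, 300),
                            qc_identity = 0.30, qc_coverage = 0.50,
                            qc_conserved = 0.90, qc_unique = 4L,
                            disorder_cutoff = 0.4, n_categories = 16L,
                            alpha_test = 0.05, use_true_tree = FALSE,
                            loess_span = 0.75, loess_min_families = 10L) {
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 cluster_size = cluster_size, qc_identity = qc_identity,
                 qc_coverage = qc_coverage, qc_conserved = qc_conserved,
                 qc_unique = qc_unique, disorder_cutoff = disorder_cutoff,
                 n_categories = n_categories, alpha_test = alpha_test,
                 use_true_tree = use_true_tree, loess_span = loess_span,
                 loess_min_families = loess_min_families),
            class = "pipeline_config")
}

#' Process one family: QC, tree, site rates, labels, joined table
#'
#' @param alignment an \code{msa}.
#' @param annotations an \code{annotation_bundle} for its rows.
#' @param tree optional \code{ape} \code{"phylo"}; if NULL a neighbor-joining
#'   tree is built from the alignment p-distances.
#' @param config a \code{pipeline_config}.
#' @return list of class \code{"family_result"}: \code{family_id}, \code{qc}
#'   (a \code{qc_report}), and — when QC passes — \code{profile}
#'   (a \code{site_rate_profile}), \code{labels} (a
#'   \code{site_label_table}), and \code{sites}, the per-site data.frame
#'   joining labels with raw and z-normalized rates.
#' @export
process_family <- function(alignment, annotations, tree = NULL,
                           config = pipeline_config()) {
  qc <- qc_filter(alignment, min_identity = config$qc_identity,
                  min_coverage = config$qc_coverage,
                  max_conserved = config$qc_conserved,
                  min_unique = config$qc_unique)
  out <- list(family_id = alignment$family_id, qc = qc)
  class(out) <- "family_result"
  if (!qc$pass) return(out)
  if (is.null(tree)) tree <- build_nj_tree(alignment)
  out$tree <- tree
  out$profile <- site_rate_profile(alignment, tree,
                                   n_categories = config$n_categories)
  out$labels <- build_label_table(alignment, annotations,
                                  cutoff = config$disorder_cutoff)
  sites <- out$labels$table
  sites$raw_rate <- out$profile$raw_rates
  sites$z_rate <- out$profile$z_rates
  out$sites <- sites
  out
}

#' Run the pipeline over a set of families
#'
#' Processes each family independently (a failing family is logged, skipped
#' and reported in the manifest), pools the per-site tables of QC-passing
#' families, runs the statistical battery on the pool, and fits the
#' disorder-content regression over families that carry
#' disordered-structured sites.
#'
#' @param families either a list of \code{family_truth} objects (synthetic
#'   mode) or a list of lists with elements \code{alignment},
#'   \code{annotations} and optional \code{tree}.
#' @param config a \code{pipeline_config}.
#' @param verbose print one status line per family and stage.
#' @return list of class \code{"pipeline_result"}: \code{families} (list of
#'   \code{family_result}), \code{sites} (pooled per-site data.frame),
#'   \code{stats} (a \code{stats_report}, NULL if no tri-factor sites),
#'   \code{loess} (NULL if too few families), \code{manifest} (counts),
#'   \code{config}.
#' @export
run_pipeline <- function(families, config = pipeline_config(),
                         verbose = FALSE) {
  results <- vector("list", length(families))
  failed <- character(0)
  for (i in seq_along(families)) {
    fam <- families[[i]]
    is_truth <- inherits(fam, "family_truth")
    aln <- fam$alignment
    ann <- fam$annotations
    tree <- if (is_truth) {
      if (config$use_true_tree) fam$tree else NULL
    } else fam$tree
    res <- tryCatch(
      process_family(aln, ann, tree, config),
      error = function(e) {
        structure(list(family_id = aln$family_id, error = conditionMessage(e)),
                  class = "family_result")
      })
    if (verbose) {
      status <- if (!is.null(res$error)) paste("ERROR:", res$error)
      else if (!res$qc$pass) "qc-fail"
      else sprintf("ok (%d sites, alpha %.2f)", nrow(res$sites),
                   res$profile$alpha)
      message(sprintf("[%s] %s", aln$family_id, status))
    }
    if (!is.null(res$error)) failed <- c(failed, aln$family_id)
    results[[i]] <- res
  }
  names(results) <- vapply(results, `[[`, character(1), "family_id")

  passed <- Filter(function(r) is.null(r$error) && r$qc$pass, results)
  sites <- if (length(passed) > 0L) {
    do.call(rbind, c(lapply(passed, `[[`, "sites"),
                     list(make.row.names = FALSE)))
  } else NULL
  stats <- NULL
  loess_fit <- NULL
  family_stats <- NULL
  if (!is.null(sites) && nrow(sites) > 0L) {
    labeled <- sites[sites$gap_free, , drop = FALSE]
    if (any(labeled$tri_factor_complete))
      stats <- stats_battery(labeled, alpha = config$alpha_test)
    family_stats <- do.call(rbind, lapply(passed, function(r) {
      tab <- r$sites
      gf <- tab[tab$gap_free, , drop = FALSE]
      ds <- gf$disorder_label == "disordered" & gf$ss_label == "structured"
      data.frame(
        family_id = r$family_id,
        disorder_content = if (nrow(gf) > 0L)
          mean(gf$disorder_label == "disordered") else NA_real_,
        mean_ds_z_rate = if (any(ds)) mean(gf$z_rate[ds]) else NA_real_,
        stringsAsFactors = FALSE)
    }))
    n_ds <- sum(complete.cases(family_stats))
    if (n_ds >= config$loess_min_families)
      loess_fit <- loess_disorder_content(family_stats,
                                          span = config$loess_span,
                                          min_families =
                                            config$loess_min_families)
  }

  manifest <- list(
    n_families = length(families),
    n_failed = length(failed),
    failed = failed,
    seed = vapply(families, function(f)
      if (inherits(f, "family_truth")) f$config$seed else NA_integer_,
      integer(1)),
    n_qc_passed = length(passed),
    total_sites = if (is.null(sites)) 0L else nrow(sites),
    gap_free_sites = if (is.null(sites)) 0L else sum(sites$gap_free),
    tri_factor_sites = if (is.null(sites)) 0L
      else sum(sites$tri_factor_complete))
  structure(list(families = results, sites = sites, stats = stats,
                 loess = loess_fit, family_stats = family_stats,
                 manifest = manifest, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "pipeline_result: %d families (%d passed QC, %d failed), %d sites (%d gap-free, %d tri-factor)\n",
    m$n_families, m$n_qc_passed, m$n_failed, m$total_sites,
    m$gap_free_sites, m$tri_factor_sites))
  if (!is.null(x$stats)) print(x$stats)
  invisible(x)
}

#' Dataset summary table
#'
#' One-row bookkeeping summary of a pipeline run: family, sequence and site
#' counts, per-category labeled-site counts, and per-category median
#' z-rates. Empty categories are reported as NA, not 0.
#'
#' @param result a \code{pipeline_result}.
#' @return one-row data.frame.
#' @export
summarize_run <- function(result) {
  passed <- Filter(function(r) is.null(r$error) && r$qc$pass,
                   result$families)
  n_seqs <- sum(vapply(passed, function(r) length(r$tree$tip.label),
                       integer(1)))
  sites <- result$sites
  if (is.null(sites))
    sites <- data.frame(disorder_label = character(0),
                        ss_label = character(0),
                        domain_label = character(0), z_rate = numeric(0))
  med <- function(sel) if (!any(sel)) NA_real_ else median(sites$z_rate[sel])
  cnt <- function(sel) sum(sel)
  data.frame(
    families = result$manifest$n_qc_passed,
    sequences = n_seqs,
    total_sites = result$manifest$total_sites,
    gap_free_sites = result$manifest$gap_free_sites,
    ordered_sites = cnt(sites$disorder_label == "ordered"),
    disordered_sites = cnt(sites$disorder_label == "disordered"),
    structured_sites = cnt(sites$ss_label == "structured"),
    coil_sites = cnt(sites$ss_label == "coil"),
    domain_sites = cnt(sites$domain_label == "domain"),
    linker_sites = cnt(sites$domain_label == "linker"),
    median_order_rate = med(sites$disorder_label == "ordered"),
    median_disorder_rate = med(sites$disorder_label == "disordered"),
    median_structure_rate = med(sites$ss_label == "structured"),
    median_coil_rate = med(sites$ss_label == "coil"),
    median_domain_rate = med(sites$domain_label == "domain"),
    median_linker_rate = med(sites$domain_label == "linker"))
}

#' Write the pooled per-site table of a run
#'
#' @param result a \code{pipeline_result}.
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
write_sites_tsv <- function(result, path) {
  utils::write.table(result$sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
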