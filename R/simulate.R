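# Synthetic protein-family generator: known tree, known site architecture
# (disorder / secondary structure / domain), class-dependent rate multipliers
# with gamma residual variation, post-hoc indels, and noisy annotation tracks.
# Every downstream stage can be tested against the ground truth it emits.

SS_STATES <- c("H", "E", "C")

#' Default per-track segment-length parameters for site architecture
#'
#' Mean segment lengths (residues) for the three annotation tracks, chosen to
#' mimic typical protein architecture: functional domains of a few dozen to a
#' few hundred residues separated by shorter linkers, secondary-structure
#' elements of order ten residues, and intrinsically disordered regions of a
#' few dozen residues embedded in mostly ordered sequence.
#'
#' @param domain_mean,linker_mean mean lengths of domain / linker segments.
#' @param ss_mean named mean lengths for helix (H), strand (E), coil (C).
#' @param ss_prob named segment-type frequencies for the three SS states in
#'   ordered sequence.
#' @param ss_prob_disordered segment-type frequencies inside disordered
#'   regions; the coil-heavy default reflects that intrinsically disordered
#'   regions carry only occasional (transient) secondary-structure
#'   elements, so disordered-structured sites are rare.
#' @param disorder_mean,order_mean mean lengths of disordered / ordered runs.
#' @return list of architecture parameters.
#' @export
architecture_params <- function(domain_mean = 60, linker_mean = 30,
                                ss_mean = c(H = 10, E = 6, C = 8),
                                ss_prob = c(H = 0.3, E = 0.2, C = 0.5),
                                ss_prob_disordered =
                                  c(H = 0.10, E = 0.05, C = 0.85),
                                disorder_mean = 25, order_mean = 75) {
  stopifnot(domain_mean > 0, linker_mean > 0, all(ss_mean > 0),
            all(ss_prob >= 0), all(ss_prob_disordered >= 0),
            disorder_mean >= 0, order_mean > 0)
  list(domain_mean = domain_mean, linker_mean = linker_mean,
       ss_mean = ss_mean[SS_STATES],
       ss_prob = ss_prob[SS_STATES] / sum(ss_prob),
       ss_prob_disordered =
         ss_prob_disordered[SS_STATES] / sum(ss_prob_disordered),
       disorder_mean = disorder_mean, order_mean = order_mean)
}

#' Default class-dependent rate multipliers
#'
#' Builds the full mapping from site-class triples (disorder in {0,1}, SS in
#' {H,E,C}, domain in {0,1}) to positive rate multipliers from four
#' interpretable effects: coil sites evolve faster than
#' secondary-structure sites, linker sites faster than domain sites, and
#' the disorder effect depends on secondary structure — disordered coil
#' sites are accelerated (\code{disorder}), while sites that are
#' simultaneously disordered and in secondary structure are decelerated
#' (\code{disordered_structured}), the interaction that reverses the
#' marginal disorder effect within structured sites.
#'
#' @param disorder multiplier for disordered sites in random coil.
#' @param coil multiplier applied when SS = C.
#' @param linker multiplier applied when domain = 0.
#' @param disordered_structured multiplier for disordered sites in a helix
#'   or strand (replaces \code{disorder} there).
#' @return named numeric vector keyed by \code{"d:ss:dom"} triples.
#' @export
default_class_multipliers <- function(disorder = 2.0, coil = 1.3,
                                      linker = 1.5,
                                      disordered_structured = 0.5) {
  stopifnot(disorder > 0, coil > 0, linker > 0, disordered_structured > 0)
  grid <- expand.grid(d = 0:1, ss = SS_STATES, dom = 0:1,
                      stringsAsFactors = FALSE)
  dis_eff <- ifelse(grid$d == 0, 1,
                    ifelse(grid$ss == "C", disorder, disordered_structured))
  mult <- dis_eff *
    ifelse(grid$ss == "C", coil, 1) *
    ifelse(grid$dom == 0, linker, 1)
  setNames(mult, class_key(grid$d, grid$ss, grid$dom))
}

class_key <- function(d, ss, dom) paste(d, ss, dom, sep = ":")

#' Simulation configuration
#'
#' Bundles all knobs of the synthetic-family generator with validation.
#' Defaults describe the study conditions used throughout the package's own
#' analyses: families of 16 taxa, 300 sites, unit gamma shape for residual
#' rate variation, 5\% annotation noise, an indel level leaving roughly two
#' thirds of columns gap-free, and a tree height of 0.6 substitutions/site
#' — shallow enough that generated families retain the minimum pairwise
#' identity (30\%) that the alignment filters demand of real input
#' families, which all pass 40\%-identity linkage upstream.
#'
#' @param n_taxa number of sequences (>= 4, the downstream uniqueness floor).
#' @param n_sites number of sites before indels.
#' @param gamma_shape shape of the mean-one gamma residual rate distribution.
#' @param class_multipliers named vector from \code{default_class_multipliers}.
#' @param architecture architecture parameters from \code{architecture_params}.
#' @param annotation_noise per-residue, per-track discordance probability,
#'   in [0, 0.5).
#' @param indel_rate target fraction of columns containing at least one gap,
#'   in [0, 1).
#' @param tree_height expected root-to-tip path length (substitutions/site).
#' @param seed integer seed for all randomness in the family.
#' @return list of class \code{"simulation_config"}.
#' @export
simulation_config <- function(n_taxa = 16L, n_sites = 300L, gamma_shape = 1.0,
                              class_multipliers = default_class_multipliers(),
                              architecture = architecture_params(),
                              annotation_noise = 0.05, indel_rate = 0.34,
                              tree_height = 0.6, seed = 1L) {
  if (n_taxa < 4L) stop("n_taxa must be at least 4")
  if (n_sites < 1L) stop("n_sites must be at least 1")
  if (gamma_shape <= 0) stop("gamma_shape must be positive")
  if (any(class_multipliers <= 0)) stop("all class multipliers must be positive")
  if (annotation_noise < 0 || annotation_noise >= 0.5)
    stop("annotation_noise must lie in [0, 0.5)")
  if (indel_rate < 0 || indel_rate >= 1) stop("indel_rate must lie in [0, 1)")
  if (tree_height <= 0) stop("tree_height must be positive")
  structure(list(n_taxa = as.integer(n_taxa), n_sites = as.integer(n_sites),
                 gamma_shape = gamma_shape,
                 class_multipliers = class_multipliers,
                 architecture = architecture,
                 annotation_noise = annotation_noise,
                 indel_rate = indel_rate, tree_height = tree_height,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# geometric segment length with mean L (support >= 1)
rseglen <- function(L) rgeom(1L, prob = 1 / L) + 1L

#' Sample a random tree with a target expected depth
#'
#' Pure-birth (Yule) topology: starting from a two-taxon cherry, a uniformly
#' chosen extant tip is repeatedly split until \code{n_taxa} tips exist.
#' Branch lengths are i.i.d. exponential, then rescaled so the mean
#' root-to-tip path length of the realized tree equals \code{tree_height}.
#'
#' @param n_taxa number of tips (>= 2).
#' @param tree_height target mean root-to-tip path length.
#' @param seed optional integer seed.
#' @return a rooted binary \code{ape} \code{"phylo"} tree with tip labels
#'   \code{t1..tN}.
#' @export
sample_tree <- function(n_taxa, tree_height = 1.0, seed = NULL) {
  if (n_taxa < 2L) stop("n_taxa must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  parent <- c(NA_integer_, 1L, 1L)
  tips <- c(2L, 3L)
  while (length(tips) < n_taxa) {
    i <- sample.int(length(tips), 1L)
    v <- tips[i]
    id1 <- length(parent) + 1L
    id2 <- id1 + 1L
    parent <- c(parent, v, v)
    tips <- c(tips[-i], id1, id2)
  }
  n_nodes <- length(parent)
  blen <- c(NA_real_, rexp(n_nodes - 1L))
  children <- split(seq_len(n_nodes)[-1L], parent[-1L])
  depth <- numeric(n_nodes)
  ord <- seq_len(n_nodes)  # construction order is already top-down
  for (v in ord[-1L]) depth[v] <- depth[parent[v]] + blen[v]
  scale <- tree_height / mean(depth[tips])
  blen <- blen * scale
  tip_no <- 0L
  newick <- function(v) {
    kids <- children[[as.character(v)]]
    lab <- if (is.null(kids)) {
      tip_no <<- tip_no + 1L
      paste0("t", tip_no)
    } else {
      paste0("(", paste(vapply(kids, newick, character(1)), collapse = ","), ")")
    }
    if (is.na(parent[v])) paste0(lab, ";")
    else paste0(lab, ":", format(blen[v], digits = 17))
  }
  ape::read.tree(text = newick(1L))
}

#' Sample a per-site class architecture
#'
#' Lays down three independent segmental tracks over \code{n_sites} sites:
#' alternating domain/linker segments, secondary-structure elements (H/E/C,
#' no immediate repeats), and alternating disordered/ordered runs. Segment
#' lengths are geometric with the track's mean; each track starts in a state
#' drawn from its stationary occupancy. Because disorder is laid down
#' independently of secondary structure, disordered-structured sites occur.
#'
#' @param n_sites number of sites.
#' @param params architecture parameters from \code{architecture_params}.
#' @param seed optional integer seed.
#' @return data.frame with columns \code{disorder} (0/1), \code{ss}
#'   ("H"/"E"/"C"), \code{domain} (0/1), one row per site.
#' @export
sample_architecture <- function(n_sites, params = architecture_params(),
                                seed = NULL) {
  if (n_sites < 1L) stop("n_sites must be at least 1")
  if (!is.null(seed)) set.seed(seed)

  alternating_track <- function(mean_on, mean_off) {
    out <- integer(0)
    state <- runif(1L) < mean_on / (mean_on + mean_off)
    while (length(out) < n_sites) {
      len <- rseglen(if (state) mean_on else mean_off)
      out <- c(out, rep(as.integer(state), len))
      state <- !state
    }
    out[seq_len(n_sites)]
  }

  domain <- alternating_track(params$domain_mean, params$linker_mean)
  disorder <- if (params$disorder_mean == 0) {
    integer(n_sites)
  } else {
    alternating_track(params$disorder_mean, params$order_mean)
  }

  # SS segments; type frequencies depend on whether the segment starts in a
  # disordered region (transient elements only) or ordered sequence.
  # Adjacent same-type segments simply merge into longer elements.
  ss <- character(0)
  while (length(ss) < n_sites) {
    at <- length(ss) + 1L
    prob <- if (disorder[at] == 1L) params$ss_prob_disordered
            else params$ss_prob
    state <- sample(SS_STATES, 1L, prob = prob)
    ss <- c(ss, rep(state, rseglen(params$ss_mean[[state]])))
  }
  ss <- ss[seq_len(n_sites)]

  data.frame(disorder = disorder, ss = ss, domain = domain,
             stringsAsFactors = FALSE)
}

# probability that a site stays in its current state after time t under the
# 20-state equal-exchange process at unit rate
jc20_p_same <- function(t) 1 / 20 + (19 / 20) * exp(-(20 / 19) * t)

#' Evolve a family along a tree with class-dependent site rates
#'
#' The root sequence is drawn uniformly over the 20 amino acids. Each site i
#' evolves independently along the tree under the 20-state
#' equal-exchangeability process at rate
#' \code{multiplier(class_i) * gamma_i}, where \code{gamma_i} is a mean-one
#' gamma draw; site rates are rescaled to mean exactly 1 (rates are relative).
#'
#' @param tree an \code{ape} \code{"phylo"} tree with branch lengths.
#' @param site_classes data.frame from \code{sample_architecture}.
#' @param class_multipliers named vector from \code{default_class_multipliers}.
#' @param gamma_shape shape of the residual gamma; \code{Inf} disables the
#'   residual (all draws 1).
#' @param seed optional integer seed.
#' @return list with \code{alignment} (ungapped \code{msa}, rows in tip-label
#'   order) and \code{site_rates} (mean-one positive vector).
#' @export
evolve_family <- function(tree, site_classes, class_multipliers =
                            default_class_multipliers(),
                          gamma_shape = 1.0, seed = NULL) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape phylo object")
  if (!is.null(seed)) set.seed(seed)
  n_sites <- nrow(site_classes)
  keys <- class_key(site_classes$disorder, site_classes$ss, site_classes$domain)
  missing <- setdiff(unique(keys), names(class_multipliers))
  if (length(missing) > 0L)
    stop("no multiplier defined for occurring site class(es): ",
         paste(missing, collapse = ", "))
  mult <- unname(class_multipliers[keys])
  resid <- if (is.finite(gamma_shape)) {
    rgamma(n_sites, shape = gamma_shape, rate = gamma_shape)
  } else rep(1, n_sites)
  rates <- mult * resid
  rates <- rates / mean(rates)

  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  seqs <- matrix(NA_integer_, n_node, n_sites)
  root <- n_tip + 1L
  seqs[root, ] <- sample.int(20L, n_sites, replace = TRUE)
  tree <- stats::reorder(tree, "cladewise")  # parents precede children
  edge <- tree$edge
  for (k in seq_len(nrow(edge))) {
    par <- edge[k, 1L]; chi <- edge[k, 2L]
    t_eff <- tree$edge.length[k] * rates
    p_same <- jc20_p_same(t_eff)
    stay <- runif(n_sites) < p_same
    child <- seqs[par, ]
    if (any(!stay)) {
      shift <- sample.int(19L, sum(!stay), replace = TRUE)
      child[!stay] <- (child[!stay] + shift - 1L) %% 20L + 1L
    }
    seqs[chi, ] <- child
  }
  aln <- vapply(seq_len(n_tip),
                function(i) paste(AA20[seqs[i, ]], collapse = ""), character(1))
  names(aln) <- tree$tip.label
  list(alignment = msa(aln), site_rates = rates)
}

#' Insert gap runs into an alignment
#'
#' Models lineage-specific deletions after the fact: geometric-length runs of
#' residues in randomly chosen rows are replaced by gap characters until the
#' fraction of columns containing at least one gap reaches
#' \code{indel_rate}. Runs that would reduce a row below 60\% residues or
#' create an all-gap column are skipped. Because gaps replace residues in
#' place, the column count is unchanged and each column keeps its source
#' site's true rate and class.
#'
#' @param alignment an \code{msa}.
#' @param indel_rate target gapped-column fraction, in [0, 1).
#' @param seed optional integer seed.
#' @param mean_run mean deletion run length (residues).
#' @return an \code{msa} with gap characters inserted.
#' @export
add_indels <- function(alignment, indel_rate, seed = NULL, mean_run = 6) {
  if (indel_rate < 0 || indel_rate >= 1) stop("indel_rate must lie in [0, 1)")
  if (indel_rate == 0) return(alignment)
  if (!is.null(seed)) set.seed(seed)
  m <- msa_matrix(alignment)
  nr <- nrow(m); nc <- ncol(m)
  target <- round(indel_rate * nc)
  tries <- 0L
  while (sum(colSums(m == "-") > 0L) < target && tries < 100L * nr) {
    tries <- tries + 1L
    i <- sample.int(nr, 1L)
    len <- min(rseglen(mean_run), nc)
    s <- sample.int(nc - len + 1L, 1L)
    cols <- s:(s + len - 1L)
    # trim the run so the gapped-column count stops at the target
    gap_cols <- colSums(m == "-") > 0L
    needed <- target - sum(gap_cols)
    newly <- cumsum(!gap_cols[cols])
    keep <- newly <= needed
    if (!any(keep)) next
    cols <- cols[keep]
    prop <- m[i, ]
    prop[cols] <- "-"
    if (sum(prop != "-") < 0.6 * nc) next
    blocked <- colSums(m[-i, cols, drop = FALSE] == "-") == nr - 1L
    if (any(blocked)) next
    m[i, ] <- prop
  }
  seqs <- apply(m, 1L, paste, collapse = "")
  msa(setNames(seqs, rownames(m)), family_id = alignment$family_id)
}

#' Emit noisy per-residue annotation tracks
#'
#' The surrogate for sequence-based structural predictors. For every residue
#' of every row (gap cells carry no annotation) the true class of its source
#' column is emitted with noise: disorder propensity scores are Beta(2,2)
#' draws scaled onto the correct side of the 0.4 cutoff and flipped across it
#' with probability \code{annotation_noise}; the secondary-structure state is
#' the true state with probability 1 - noise, else one of the two other
#' states uniformly; domain intervals are the true residue intervals with
#' small geometric boundary jitter.
#'
#' @param site_classes data.frame of true per-column classes.
#' @param alignment the (possibly gapped) \code{msa}; column count must equal
#'   \code{nrow(site_classes)}.
#' @param annotation_noise per-residue discordance probability in [0, 0.5).
#' @param seed optional integer seed.
#' @return an \code{annotation_bundle}: lists \code{disorder} (numeric
#'   scores), \code{ss} (state vectors), \code{domains} (data.frames with
#'   0-based half-open \code{start}, \code{end}), each keyed by sequence id.
#' @export
emit_annotations <- function(site_classes, alignment, annotation_noise = 0.05,
                             seed = NULL) {
  if (annotation_noise < 0 || annotation_noise >= 0.5)
    stop("annotation_noise must lie in [0, 0.5)")
  if (nrow(site_classes) != msa_ncol(alignment))
    stop("site_classes must cover every alignment column")
  if (!is.null(seed)) set.seed(seed)
  m <- msa_matrix(alignment)
  ids <- rownames(m)
  disorder <- ss <- domains <- setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    res_cols <- which(m[id, ] != "-")
    n_res <- length(res_cols)
    true_dis <- site_classes$disorder[res_cols] == 1L
    flip <- runif(n_res) < annotation_noise
    side <- xor(true_dis, flip)
    draw <- rbeta(n_res, 2, 2)
    disorder[[id]] <- ifelse(side, 0.4 + 0.6 * draw, 0.4 * draw)

    true_ss <- site_classes$ss[res_cols]
    wrong <- runif(n_res) < annotation_noise
    emitted <- true_ss
    if (any(wrong)) {
      emitted[wrong] <- vapply(true_ss[wrong], function(s)
        sample(setdiff(SS_STATES, s), 1L), character(1))
    }
    ss[[id]] <- emitted

    dom_res <- which(site_classes$domain[res_cols] == 1L)
    ivs <- runs_to_intervals(dom_res)
    if (nrow(ivs) > 0L && annotation_noise > 0) {
      jit <- function(k) ifelse(runif(k) < annotation_noise,
                                sample(c(-2L, -1L, 1L, 2L), k, replace = TRUE),
                                0L)
      ivs$start <- pmax(0L, pmin(n_res, ivs$start + jit(nrow(ivs))))
      ivs$end <- pmax(0L, pmin(n_res, ivs$end + jit(nrow(ivs))))
      ivs <- ivs[ivs$end > ivs$start, , drop = FALSE]
      ivs <- merge_intervals(ivs)
    }
    domains[[id]] <- ivs
  }
  structure(list(disorder = disorder, ss = ss, domains = domains),
            class = "annotation_bundle")
}

# 1-based positions of a 0/1 run -> 0-based half-open intervals
runs_to_intervals <- function(pos) {
  if (length(pos) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  brk <- c(0L, which(diff(pos) > 1L), length(pos))
  starts <- pos[brk[-length(brk)] + 1L] - 1L
  ends <- pos[brk[-1L]]
  data.frame(start = starts, end = ends)
}

merge_intervals <- function(ivs) {
  if (nrow(ivs) <= 1L) return(ivs)
  ivs <- ivs[order(ivs$start), , drop = FALSE]
  out <- ivs[1L, , drop = FALSE]
  for (k in seq(2L, nrow(ivs))) {
    last <- nrow(out)
    if (ivs$start[k] <= out$end[last]) {
      out$end[last] <- max(out$end[last], ivs$end[k])
    } else {
      out <- rbind(out, ivs[k, ])
    }
  }
  rownames(out) <- NULL
  out
}

#' Simulate one complete synthetic family with ground truth
#'
#' Runs tree sampling, architecture sampling, sequence evolution, indel
#' placement, and annotation emission under one configuration and seed.
#'
#' @param config a \code{simulation_config}.
#' @param family_id family identifier.
#' @return a \code{family_truth}: \code{tree}, \code{site_classes},
#'   \code{site_rates}, \code{alignment} (gapped \code{msa}),
#'   \code{annotations}, and the \code{config}.
#' @export
simulate_family <- function(config = simulation_config(),
                            family_id = "fam1") {
  set.seed(config$seed)
  tree <- sample_tree(config$n_taxa, config$tree_height)
  classes <- sample_architecture(config$n_sites, config$architecture)
  ev <- evolve_family(tree, classes, config$class_multipliers,
                      config$gamma_shape)
  aln <- add_indels(ev$alignment, config$indel_rate)
  aln$family_id <- family_id
  ann <- emit_annotations(classes, aln, config$annotation_noise)
  structure(list(family_id = family_id, tree = tree, site_classes = classes,
                 site_rates = ev$site_rates, alignment = aln,
                 annotations = ann, config = config),
            class = "family_truth")
}

#' Simulate a dataset of synthetic families
#'
#' @param n_families number of families.
#' @param config base \code{simulation_config}; each family re-draws
#'   \code{n_taxa} uniformly between \code{config$n_taxa/2} and
#'   \code{2*config$n_taxa} (clamped to [4, 300]) and uses seed
#'   \code{config$seed + i}.
#' @param vary_taxa logical; if FALSE all families use \code{config$n_taxa}.
#' @return named list of \code{family_truth} objects.
#' @export
simulate_dataset <- function(n_families, config = simulation_config(),
                             vary_taxa = TRUE) {
  fams <- vector("list", n_families)
  for (i in seq_len(n_families)) {
    cfg <- config
    cfg$seed <- config$seed + i
    if (vary_taxa) {
      set.seed(cfg$seed * 2L + 1L)
      cfg$n_taxa <- as.integer(min(300L, max(4L,
        sample(seq(max(4L, config$n_taxa %/% 2L), 2L * config$n_taxa), 1L))))
    }
    fams[[i]] <- simulate_family(cfg, family_id = sprintf("fam%03d", i))
  }
  setNames(fams, vapply(fams, `[[`, character(1), "family_id"))
}

#' Write the truth table of a synthetic family
#'
#' @param truth a \code{family_truth}.
#' @param path output TSV path (columns: family_id, column_index 0-based,
#'   true_rate, disorder, ss, domain).
#' @return invisibly, the path.
#' @export
write_truth_tsv <- function(truth, path) {
  df <- data.frame(family_id = truth$family_id,
                   column_index = seq_len(nrow(truth$site_classes)) - 1L,
                   true_rate = truth$site_rates,
                   truth$site_classes)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
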