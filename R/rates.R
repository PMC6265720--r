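# Empirical-Bayes site-rate inference on a fixed tree: 20-state
# equal-exchangeability substitution model (the amino-acid generalization of
# the Jukes-Cantor equal-probability matrix), discrete-gamma rate variation
# with equal-probability categories, Felsenstein pruning in linear space
# with per-node scaling, posterior-mean site rates, and per-family z-score
# normalization.

#' Transition probability matrix of the 20-state equal-exchange model
#'
#' All exchangeabilities equal, uniform equilibrium frequencies (1/20), time
#' scaled so that t is the expected number of substitutions per site:
#' \deqn{p_{same}(t) = 1/20 + (19/20) e^{-(20/19) t}}
#' \deqn{p_{diff}(t) = 1/20 - (1/20) e^{-(20/19) t}}
#'
#' @param t non-negative branch length (substitutions/site, already
#'   multiplied by any site rate).
#' @return 20 x 20 row-stochastic matrix.
#' @export
transition_prob <- function(t) {
  if (t < 0) stop("branch length must be non-negative")
  e <- exp(-(20 / 19) * t)
  p_diff <- (1 - e) / 20
  p_same <- 1 / 20 + (19 / 20) * e
  m <- matrix(p_diff, 20L, 20L, dimnames = list(AA20, AA20))
  diag(m) <- p_same
  m
}

# internal: encode msa columns as integer matrix (tips x sites), NA for gaps
encode_alignment <- function(x) {
  m <- msa_matrix(x)
  enc <- matrix(match(m, AA20), nrow(m), ncol(m))
  rownames(enc) <- rownames(m)
  enc  # NA where gap (or unknown char)
}

# internal: prepare a tree for repeated pruning passes
prune_plan <- function(tree, tip_ids) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape phylo object")
  if (is.null(tree$edge.length)) stop("tree must carry branch lengths")
  missing <- setdiff(tip_ids, tree$tip.label)
  if (length(missing) > 0L)
    stop("alignment rows without a matching leaf: ",
         paste(missing, collapse = ", "))
  tree <- stats::reorder(tree, "postorder")
  list(edge = tree$edge, edge_length = tree$edge.length,
       n_tip = length(tree$tip.label), tip_label = tree$tip.label,
       root = length(tree$tip.label) + 1L)
}

# internal: pruning over all sites at one rate; returns per-site
# log-likelihood vector. enc: tips x sites integer matrix aligned to
# plan$tip_label order.
prune_loglik <- function(plan, enc, rate) {
  n_tip <- plan$n_tip
  n_node <- max(plan$edge)
  n_sites <- ncol(enc)
  partial <- vector("list", n_node)
  # tip partials: indicator vectors; gaps = all ones (missing data)
  tip_partial <- function(i) {
    p <- matrix(0, 20L, n_sites)
    obs <- enc[i, ]
    na <- is.na(obs)
    if (any(!na)) p[cbind(obs[!na], which(!na))] <- 1
    if (any(na)) p[, na] <- 1
    p
  }
  scale_log <- numeric(n_sites)
  for (k in seq_len(nrow(plan$edge))) {
    par <- plan$edge[k, 1L]; chi <- plan$edge[k, 2L]
    t_eff <- plan$edge_length[k] * rate
    e <- exp(-(20 / 19) * t_eff)
    p_diff <- (1 - e) / 20
    child <- if (chi <= n_tip) tip_partial(chi) else partial[[chi]]
    s <- colSums(child)
    # contribution_a = sum_b P(a->b) L_b = p_diff * s + (p_same - p_diff) L_a
    contrib <- sweep(child * e, 2L, p_diff * s, "+")
    if (is.null(partial[[par]])) {
      partial[[par]] <- contrib
    } else {
      partial[[par]] <- partial[[par]] * contrib
      mx <- apply(partial[[par]], 2L, max)
      mx[mx == 0] <- 1  # zero column: leave as is, caught later
      partial[[par]] <- sweep(partial[[par]], 2L, mx, "/")
      scale_log <- scale_log + log(mx)
    }
    if (chi > n_tip) partial[chi] <- list(NULL)  # free, keep indices stable
  }
  rootp <- partial[[plan$root]]
  lik <- colSums(rootp) / 20
  if (any(lik <= 0) || any(!is.finite(lik)))
    stop("numerical underflow in site likelihood")
  log(lik) + scale_log
}

#' Likelihood of one alignment column at a given rate
#'
#' Felsenstein pruning over the tree with branch lengths scaled by
#' \code{rate}, uniform (1/20) root frequencies, gaps treated as missing
#' data (partial vector of ones).
#'
#' @param x an \code{msa}.
#' @param tree an \code{ape} \code{"phylo"} with branch lengths; leaf labels
#'   must cover all alignment rows.
#' @param column 1-based column index.
#' @param rate positive rate multiplier.
#' @return the column likelihood (probability).
#' @export
site_likelihood <- function(x, tree, column, rate = 1) {
  if (rate <= 0) stop("rate must be positive")
  enc <- encode_alignment(x)[, column, drop = FALSE]
  plan <- prune_plan(tree, rownames(enc))
  enc <- enc[plan$tip_label, , drop = FALSE]
  exp(prune_loglik(plan, enc, rate))
}

#' Discrete-gamma rate categories (equal-probability bins, bin-mean rates)
#'
#' Discretizes a mean-one gamma distribution with shape \code{alpha} into
#' \code{n_categories} equal-probability categories whose representative
#' rates are the conditional means within each quantile bin, then rescales
#' so the category rates average to exactly 1.
#'
#' @param alpha positive gamma shape.
#' @param n_categories number of categories (default 16).
#' @return list of class \code{"gamma_model"}: \code{alpha}, \code{n_categories},
#'   \code{rates} (increasing, mean 1), \code{probs} (all equal).
#' @export
discrete_gamma <- function(alpha, n_categories = 16L) {
  if (alpha <= 0) stop("alpha must be positive")
  k <- as.integer(n_categories)
  q <- qgamma(seq(0, 1, length.out = k + 1L), shape = alpha, rate = alpha)
  # E[X | q_i < X <= q_{i+1}] * P(bin) = pgamma(q_{i+1}, a+1) - pgamma(q_i, a+1)
  cum <- pgamma(q, shape = alpha + 1, rate = alpha)
  rates <- (cum[-1L] - cum[-(k + 1L)]) * k
  rates <- rates / mean(rates)
  structure(list(alpha = alpha, n_categories = k, rates = rates,
                 probs = rep(1 / k, k)), class = "gamma_model")
}

# internal: sites x categories log-likelihood matrix
category_logliks <- function(plan, enc, gm) {
  vapply(gm$rates, function(r) prune_loglik(plan, enc, r),
         numeric(ncol(enc)))
}

# internal: total log-likelihood from the per-category matrix
total_loglik <- function(ll_mat, gm) {
  mx <- apply(ll_mat, 1L, max)
  sum(mx + log(rowMeans(exp(ll_mat - mx))))
}

#' Fit the gamma shape of among-site rate variation by maximum likelihood
#'
#' Maximizes the discrete-gamma mixture likelihood
#' \eqn{\sum_s \log \sum_c (1/K) L(s | r_c(\alpha))} over
#' \eqn{\alpha \in [0.05, 50]} by Brent search (tolerance 1e-4) on the fixed
#' tree. A fitted shape within 2\% of either bound triggers a warning: the
#' data carry no usable rate-variation signal (e.g. all-invariant columns).
#'
#' @param x an \code{msa}.
#' @param tree an \code{ape} \code{"phylo"} with branch lengths.
#' @param n_categories number of gamma categories (default 16).
#' @param interval search interval for alpha.
#' @return list: \code{model} (a \code{gamma_model}), \code{loglik}.
#' @export
fit_alpha <- function(x, tree, n_categories = 16L,
                      interval = c(0.05, 50)) {
  enc <- encode_alignment(x)
  plan <- prune_plan(tree, rownames(enc))
  enc <- enc[plan$tip_label, , drop = FALSE]
  obj <- function(a) {
    gm <- discrete_gamma(a, n_categories)
    -total_loglik(category_logliks(plan, enc, gm), gm)
  }
  opt <- optimize(obj, interval = interval, tol = 1e-4)
  a_hat <- opt$minimum
  if (a_hat < interval[1L] * 1.02 || a_hat > interval[2L] * 0.98)
    warning("fitted gamma shape pinned at search bound (",
            format(a_hat, digits = 4),
            "): no usable among-site rate-variation signal")
  list(model = discrete_gamma(a_hat, n_categories), loglik = -opt$objective)
}

#' Posterior-mean site rates under a discrete-gamma model
#'
#' Empirical-Bayes point estimate per column: category rates weighted by the
#' (equal-prior) category likelihoods of the column,
#' \eqn{\hat r_s = \sum_c r_c L(s|r_c) / \sum_c L(s|r_c)}.
#'
#' @param x an \code{msa}.
#' @param tree an \code{ape} \code{"phylo"} with branch lengths.
#' @param gamma_model a \code{gamma_model} from \code{discrete_gamma} or
#'   \code{fit_alpha}.
#' @return numeric vector of raw posterior-mean rates, one per column, each
#'   within [min(rates), max(rates)].
#' @export
posterior_mean_rates <- function(x, tree, gamma_model) {
  enc <- encode_alignment(x)
  plan <- prune_plan(tree, rownames(enc))
  enc <- enc[plan$tip_label, , drop = FALSE]
  ll <- category_logliks(plan, enc, gamma_model)
  mx <- apply(ll, 1L, max)
  w <- exp(ll - mx)
  tot <- rowSums(w)
  if (any(tot <= 0) || any(!is.finite(tot)))
    stop("numerical underflow: zero total likelihood at a site")
  as.numeric(w %*% gamma_model$rates / tot)
}

#' z-score normalization of site rates
#'
#' Centers and scales with the population standard deviation so that within
#' a family the mean is 0 and the spread 1; positive scores mark
#' faster-than-average sites. A zero-variance input (degenerate family)
#' returns all zeros with a warning.
#'
#' @param rates numeric vector of raw site rates (length >= 2).
#' @return z-scored rates.
#' @export
z_normalize <- function(rates) {
  if (length(rates) < 2L) stop("need at least 2 columns to normalize")
  mu <- mean(rates)
  sigma <- sqrt(mean((rates - mu)^2))
  if (sigma == 0) {
    warning("zero rate variance: degenerate family, all z-scores set to 0")
    return(rep(0, length(rates)))
  }
  (rates - mu) / sigma
}

#' Full site-rate profile for one family
#'
#' Fits the gamma shape, computes posterior-mean rates and their z-scores.
#'
#' @param x an \code{msa}.
#' @param tree an \code{ape} \code{"phylo"} with branch lengths.
#' @param n_categories gamma categories (default 16).
#' @return list of class \code{"site_rate_profile"}: \code{family_id},
#'   \code{raw_rates}, \code{z_rates}, \code{alpha}, \code{loglik},
#'   \code{n_categories}.
#' @export
site_rate_profile <- function(x, tree, n_categories = 16L) {
  fit <- fit_alpha(x, tree, n_categories)
  raw <- posterior_mean_rates(x, tree, fit$model)
  structure(list(family_id = x$family_id, raw_rates = raw,
                 z_rates = z_normalize(raw), alpha = fit$model$alpha,
                 loglik = fit$loglik, n_categories = n_categories),
            class = "site_rate_profile")
}

#' @export
print.site_rate_profile <- function(x, ...) {
  cat(sprintf(
    "site_rate_profile '%s': %d sites, alpha = %.3f, logL = %.2f\n",
    x$family_id, length(x$raw_rates), x$alpha, x$loglik))
  invisible(x)
}

#' Neighbor-joining tree from alignment p-distances
#'
#' Convenience tree builder for families lacking an input tree: NJ on the
#' pairwise p-distance matrix, with any negative branch lengths clamped
#' to 0. Distances are uncorrected, so branch lengths underestimate
#' substitutions/site at high divergence; relative site rates are
#' insensitive to this compression.
#'
#' @param x an \code{msa}.
#' @return an unrooted \code{ape} \code{"phylo"} tree.
#' @export
build_nj_tree <- function(x) {
  d <- p_distance_matrix(x)
  tr <- ape::nj(as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}
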