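# The downstream statistical battery over pooled labeled sites: Mann-Whitney
# two-group contrasts (exact enumeration for tiny groups, tie-corrected
# normal approximation otherwise), Kruskal-Wallis over the eight factor-level
# cells, mean-rank multiple pairwise comparisons with a Bonferroni-adjusted
# normal critical difference, type-III factorial ANOVA with zero-sum
# contrasts, cell/margin means, and tricube local-linear regression.

#' Mann-Whitney rank-sum test with median difference
#'
#' U is the number of (a, b) pairs where b precedes a (ties count half),
#' i.e. the statistic of the first group. When both groups have at most
#' \code{exact_max} observations the two-sided p-value is computed by
#' exhaustive enumeration of all rank assignments (valid under ties);
#' otherwise a tie-corrected normal approximation without continuity
#' correction is used. The reported median difference is
#' \code{median(b) - median(a)}.
#'
#' @param a,b numeric vectors (both non-empty).
#' @param exact_max maximum per-group size for exact enumeration (default 8).
#' @return list: \code{U}, \code{p}, \code{delta_median}, \code{method}.
#' @export
mann_whitney <- function(a, b, exact_max = 8L) {
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    # enumerate all choices of which pooled ranks belong to group a
    sets <- combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[sets], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    n <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * (n + 1 - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal approximation"
  }
  list(U = u, p = min(1, p), delta_median = median(b) - median(a),
       method = method)
}

#' Kruskal-Wallis test over a list of groups
#'
#' Tie-corrected H with a chi-square p-value on k - 1 degrees of freedom
#' (base R's implementation). All-identical data return H = 0, p = 1.
#'
#' @param groups named list of numeric vectors (>= 2 non-empty).
#' @return list: \code{H}, \code{df}, \code{p}.
#' @export
kruskal_wallis <- function(groups) {
  groups <- groups[lengths(groups) > 0L]
  if (length(groups) < 2L) stop("need at least 2 non-empty groups")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1L)
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  kt <- kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Mean-rank multiple pairwise comparisons after Kruskal-Wallis
#'
#' For k groups with pooled-sample mean ranks, a pair (i, j) is called
#' significant iff
#' \deqn{|\bar R_i - \bar R_j| \ge z_{1-\alpha/(k(k-1))}
#'       \sqrt{\frac{N(N+1)}{12}\left(\frac1{n_i}+\frac1{n_j}\right)}}
#' the published critical-difference rule for post-hoc comparisons on mean
#' ranks with a Bonferroni-style adjustment over the k(k-1)/2 two-sided
#' pairs.
#'
#' @param groups named list of numeric vectors.
#' @param alpha family significance level (default 0.05).
#' @return data.frame (group_a, group_b, obs_diff, critical_diff,
#'   significant); pairs with an empty group carry NA verdicts.
#' @export
pairwise_rank_comparisons <- function(groups, alpha = 0.05) {
  k <- length(groups)
  if (k < 2L) stop("need at least 2 groups")
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_len(k))
  sizes <- lengths(groups)
  x <- unlist(groups, use.names = FALSE)
  r <- rank(x)
  grp <- rep(seq_len(k), sizes)
  mean_rank <- vapply(seq_len(k), function(i)
    if (sizes[i] > 0L) mean(r[grp == i]) else NA_real_, numeric(1))
  N <- length(x)
  zcrit <- qnorm(1 - alpha / (k * (k - 1)))
  pairs <- combn(k, 2L)
  out <- data.frame(
    group_a = nm[pairs[1L, ]], group_b = nm[pairs[2L, ]],
    obs_diff = NA_real_, critical_diff = NA_real_, significant = NA,
    stringsAsFactors = FALSE)
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    if (sizes[i] == 0L || sizes[j] == 0L) next
    cd <- zcrit * sqrt(N * (N + 1) / 12 * (1 / sizes[i] + 1 / sizes[j]))
    out$obs_diff[p] <- abs(mean_rank[i] - mean_rank[j])
    out$critical_diff[p] <- cd
    out$significant[p] <- out$obs_diff[p] >= cd
  }
  out
}

#' Type-III factorial ANOVA with zero-sum contrasts
#'
#' Fits the full 2x2x2 factorial \code{z_rate ~ disorder * ss * domain}
#' with effects (sum-to-zero) coding and reports marginal (type-III) sums
#' of squares per term via \code{car::Anova}, plus the adjusted R-squared.
#' Requires observations in all eight cells; missing cells raise an error
#' naming them.
#'
#' @param records data.frame with columns \code{z_rate} and factors
#'   \code{disorder}, \code{ss}, \code{domain} (two levels each).
#' @return list: \code{table} (data.frame term, sum_sq, df, f, p),
#'   \code{adj_r_squared}, \code{fit} (the lm object).
#' @export
anova_type3 <- function(records) {
  req <- c("z_rate", "disorder", "ss", "domain")
  if (!all(req %in% names(records)))
    stop("records must have columns ", paste(req, collapse = ", "))
  d <- records
  for (f in c("disorder", "ss", "domain")) {
    d[[f]] <- factor(d[[f]])
    if (nlevels(d[[f]]) != 2L)
      stop("inestimable terms: factor '", f, "' has ",
           nlevels(d[[f]]), " observed level(s), need 2")
  }
  cells <- with(d, table(disorder, ss, domain))
  if (any(cells == 0L)) {
    idx <- which(cells == 0L, arr.ind = TRUE)
    miss <- apply(idx, 1L, function(r)
      paste(dimnames(cells)[[1L]][r[1L]], dimnames(cells)[[2L]][r[2L]],
            dimnames(cells)[[3L]][r[3L]], sep = "/"))
    stop("inestimable terms: empty cell(s) ", paste(miss, collapse = ", "))
  }
  fit <- lm(z_rate ~ disorder * ss * domain, data = d,
            contrasts = list(disorder = "contr.sum", ss = "contr.sum",
                             domain = "contr.sum"))
  a3 <- car::Anova(fit, type = 3)
  keep <- !rownames(a3) %in% c("(Intercept)", "Residuals")
  tab <- data.frame(term = rownames(a3)[keep],
                    sum_sq = a3$`Sum Sq`[keep], df = a3$Df[keep],
                    f = a3$`F value`[keep], p = a3$`Pr(>F)`[keep],
                    stringsAsFactors = FALSE)
  list(table = tab, adj_r_squared = summary(fit)$adj.r.squared, fit = fit)
}

#' Cell and margin means of the eight factor-level combinations
#'
#' @param records data.frame as in \code{anova_type3}; empty cells are
#'   reported as NA.
#' @return list: \code{cells} (data.frame disorder, ss, domain, n, mean),
#'   \code{margins} (list of three 2x2 data.frames, one per factor pair,
#'   averaging over the third factor).
#' @export
cell_means <- function(records) {
  d <- records
  for (f in c("disorder", "ss", "domain"))
    d[[f]] <- as.character(d[[f]])
  grid <- expand.grid(disorder = unique(d$disorder), ss = unique(d$ss),
                      domain = unique(d$domain), stringsAsFactors = FALSE)
  grid$n <- 0L
  grid$mean <- NA_real_
  for (i in seq_len(nrow(grid))) {
    sel <- d$disorder == grid$disorder[i] & d$ss == grid$ss[i] &
      d$domain == grid$domain[i]
    grid$n[i] <- sum(sel)
    if (any(sel)) grid$mean[i] <- mean(d$z_rate[sel])
  }
  margin <- function(f1, f2) {
    ag <- aggregate(d$z_rate, by = list(d[[f1]], d[[f2]]), FUN = mean)
    names(ag) <- c(f1, f2, "mean")
    ag$n <- aggregate(d$z_rate, by = list(d[[f1]], d[[f2]]),
                      FUN = length)$x
    ag
  }
  list(cells = grid,
       margins = list(disorder_ss = margin("disorder", "ss"),
                      disorder_domain = margin("disorder", "domain"),
                      ss_domain = margin("ss", "domain")))
}

#' Tricube weight function
#'
#' \eqn{w(u) = (1 - |u|^3)^3} for |u| < 1, else 0; equals 1 at distance 0
#' and falls to 0 at the window edge.
#'
#' @param u normalized distances.
#' @return weights in [0, 1].
#' @export
tricube <- function(u) {
  w <- (1 - pmin(1, abs(u))^3)^3
  w
}

#' Local-linear (loess-style) regression with tricube weights
#'
#' At each evaluation point the \code{ceiling(span * n)} nearest
#' observations receive tricube weights scaled by the distance to the
#' farthest neighbor in the window, and a weighted least-squares line is
#' fitted and evaluated at the point.
#'
#' @param x,y observations.
#' @param span fraction of observations in each local window (default 0.75).
#' @param grid evaluation points (default: 50 points spanning x).
#' @return data.frame (x, fitted).
#' @export
local_linear_fit <- function(x, y, span = 0.75,
                             grid = seq(min(x), max(x), length.out = 50L)) {
  n <- length(x)
  if (n != length(y)) stop("x and y lengths differ")
  q <- ceiling(span * n)
  if (q < 3L) stop("window of ", q, " points is too small; ",
                   "increase span or supply more observations")
  fitted <- vapply(grid, function(x0) {
    d <- abs(x - x0)
    h <- sort(d, partial = q)[q]
    if (h == 0) return(mean(y[d == 0]))
    w <- tricube(d / h)
    use <- w > 0
    X <- cbind(1, x[use] - x0)
    W <- w[use]
    beta <- solve(crossprod(X, X * W), crossprod(X, y[use] * W))
    beta[1L]
  }, numeric(1))
  data.frame(x = grid, fitted = fitted)
}

#' Loess-style curve of disorder content vs disordered-structured rates
#'
#' One point per family: x = the family's disorder content (disordered
#' columns / gap-free columns), y = the family's mean z-rate over
#' disordered-structured sites. The curve is the tricube local-linear fit
#' through those points.
#'
#' @param family_stats data.frame with columns \code{disorder_content} and
#'   \code{mean_ds_z_rate}, one row per family with >= 1
#'   disordered-structured site.
#' @param span local window fraction (default 0.75).
#' @param min_families minimum number of families required (default 10).
#' @return list: \code{points} (the input), \code{curve} (data.frame x,
#'   fitted), \code{span}.
#' @export
loess_disorder_content <- function(family_stats, span = 0.75,
                                   min_families = 10L) {
  fs <- family_stats[complete.cases(family_stats[,
    c("disorder_content", "mean_ds_z_rate")]), , drop = FALSE]
  if (nrow(fs) < min_families)
    stop("need at least ", min_families,
         " families with disordered-structured sites, got ", nrow(fs))
  curve <- local_linear_fit(fs$disorder_content, fs$mean_ds_z_rate,
                            span = span)
  list(points = fs, curve = curve, span = span)
}

#' Run the full statistical battery over pooled labeled sites
#'
#' Sites are pooled across families and treated as independent
#' observations. The three two-group contrasts use each factor's labeled
#' sites independently; the Kruskal-Wallis test, the 28 pairwise
#' comparisons, the type-III ANOVA and the cell means use only
#' tri-factor-complete sites.
#'
#' @param site_table data.frame with columns \code{z_rate},
#'   \code{disorder_label}, \code{ss_label}, \code{domain_label},
#'   \code{tri_factor_complete} (one row per gap-free labeled site; rows
#'   with all labels "unlabeled" are allowed and ignored).
#' @param alpha significance level for the pairwise comparisons.
#' @return list of class \code{"stats_report"}: \code{mann_whitney} (list of
#'   three contrasts, each median difference signed as faster-category minus
#'   slower-category reference: disordered - ordered, coil - structured,
#'   linker - domain), \code{kruskal_wallis}, \code{pairwise},
#'   \code{anova}, \code{cell_means}, \code{n_tri_factor}.
#' @export
stats_battery <- function(site_table, alpha = 0.05) {
  mw_contrast <- function(label_col, ref, alt) {
    lab <- site_table[[label_col]]
    a <- site_table$z_rate[lab == ref]
    b <- site_table$z_rate[lab == alt]
    c(mann_whitney(a, b), list(reference = ref, alternative = alt))
  }
  mw <- list(
    disorder = mw_contrast("disorder_label", "ordered", "disordered"),
    ss = mw_contrast("ss_label", "structured", "coil"),
    domain = mw_contrast("domain_label", "domain", "linker"))

  tri <- site_table[site_table$tri_factor_complete, , drop = FALSE]
  cell_id <- paste(tri$disorder_label, tri$ss_label, tri$domain_label,
                   sep = "/")
  groups <- split(tri$z_rate, cell_id)
  kw <- tryCatch(kruskal_wallis(groups),
                 error = function(e) list(error = conditionMessage(e)))
  pw <- tryCatch(pairwise_rank_comparisons(groups, alpha = alpha),
                 error = function(e) NULL)
  rec <- data.frame(z_rate = tri$z_rate, disorder = tri$disorder_label,
                    ss = tri$ss_label, domain = tri$domain_label,
                    stringsAsFactors = FALSE)
  # the factorial model needs all 8 cells; small or degenerate datasets
  # still get the rank-based results
  an <- tryCatch(anova_type3(rec)[c("table", "adj_r_squared")],
                 error = function(e) list(error = conditionMessage(e)))
  cm <- cell_means(rec)
  structure(list(mann_whitney = mw, kruskal_wallis = kw, pairwise = pw,
                 anova = an, cell_means = cm,
                 n_tri_factor = nrow(tri), alpha = alpha),
            class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat("stats_report\n")
  for (nm in names(x$mann_whitney)) {
    m <- x$mann_whitney[[nm]]
    cat(sprintf("  MW %-8s (%s vs %s): delta_median = %+.4f, p = %.3g\n",
                nm, m$alternative, m$reference, m$delta_median, m$p))
  }
  if (is.null(x$kruskal_wallis$error))
    cat(sprintf("  Kruskal-Wallis: H = %.2f (df %d), p = %.3g\n",
                x$kruskal_wallis$H, x$kruskal_wallis$df, x$kruskal_wallis$p))
  if (!is.null(x$pairwise))
    cat(sprintf("  pairwise comparisons: %d significant of %d\n",
                sum(x$pairwise$significant, na.rm = TRUE), nrow(x$pairwise)))
  if (is.null(x$anova$error)) {
    cat(sprintf("  ANOVA adjusted R^2 = %.4f over %d tri-factor sites\n",
                x$anova$adj_r_squared, x$n_tri_factor))
  } else {
    cat(sprintf("  ANOVA not estimable: %s\n", x$anova$error))
  }
  invisible(x)
}
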