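# Statistical battery: Mann-Whitney (exact + approximate), Kruskal-Wallis,
# mean-rank pairwise comparisons, type-III ANOVA against a model-comparison
# oracle, cell means, and the tricube local-linear smoother.

test_that("mann_whitney handles separation, identity, and signs", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$delta_median, 3)

  same <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$delta_median, 0)
  expect_gt(same$p, 0.9)

  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("exact Mann-Whitney p equals the null distribution of U", {
  # tie-free case: the exact enumeration must reproduce the classical
  # Wilcoxon null distribution
  set.seed(8)
  for (rep in 1:5) {
    n1 <- sample(3:7, 1); n2 <- sample(3:7, 1)
    x <- sample(100, n1 + n2)  # distinct values, no ties
    a <- x[seq_len(n1)]; b <- x[-seq_len(n1)]
    got <- mann_whitney(a, b)
    expect_identical(got$method, "exact enumeration")
    u <- got$U
    mu <- n1 * n2 / 2
    lo <- min(u, n1 * n2 - u)
    want <- stats::pwilcox(lo, n1, n2) +
      (1 - stats::pwilcox(n1 * n2 - lo - 1L, n1, n2))
    expect_equal(got$p, min(1, want), tolerance = 1e-12)
  }

  # tied case: compare against an independently coded permutation sweep
  a <- c(1, 2, 2, 3); b <- c(2, 3, 3, 4)
  got <- mann_whitney(a, b)
  pooled <- c(a, b)
  r <- rank(pooled)
  obs_u <- sum(r[1:4]) - 4 * 5 / 2
  mu <- length(a) * length(b) / 2
  sets <- utils::combn(8, 4)
  u_all <- apply(sets, 2, function(s) sum(r[s]) - 10)
  want <- mean(abs(u_all - mu) >= abs(obs_u - mu) - 1e-12)
  expect_equal(got$p, want, tolerance = 1e-12)
})

test_that("large-sample Mann-Whitney matches the tie-corrected z test", {
  set.seed(9)
  a <- round(rnorm(40), 1)  # rounding induces ties
  b <- round(rnorm(50, 0.4), 1)
  got <- mann_whitney(a, b)
  expect_identical(got$method, "normal approximation")
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  expect_equal(got$U, unname(ref$statistic))
})

test_that("kruskal_wallis reduces to the squared two-group z statistic", {
  set.seed(10)
  a <- rnorm(15); b <- rnorm(20, 0.5)
  kw <- kruskal_wallis(list(a = a, b = b))
  mw <- mann_whitney(a, b, exact_max = 0L)
  z <- stats::qnorm(mw$p / 2)  # two-sided p back to |z|
  expect_equal(kw$H, z^2, tolerance = 1e-9)

  expect_equal(kruskal_wallis(list(a = rep(1, 5), b = rep(1, 5)))$H, 0)
  expect_error(kruskal_wallis(list(a = 1:3)), "at least 2")
})

test_that("pairwise mean-rank comparisons apply the critical difference", {
  # identical groups: never significant
  same <- pairwise_rank_comparisons(list(a = 1:10, b = 1:10))
  expect_false(any(same$significant))

  # 8 groups, one shifted far: exactly its 7 pairs significant
  set.seed(11)
  groups <- lapply(1:8, function(i) rnorm(30))
  names(groups) <- paste0("g", 1:8)
  groups$g8 <- groups$g8 + 100
  pw <- pairwise_rank_comparisons(groups)
  expect_equal(nrow(pw), 28L)
  sig <- pw$significant
  hits8 <- pw$group_a == "g8" | pw$group_b == "g8"
  expect_true(all(sig[hits8]))
  expect_false(any(sig[!hits8]))

  # 3-group toy against a by-hand critical difference
  g <- list(a = c(1, 2, 3, 4, 5), b = c(2, 3, 4, 5, 6),
            c = c(20, 21, 22, 23, 24))
  pw <- pairwise_rank_comparisons(g, alpha = 0.05)
  x <- unlist(g)
  r <- rank(x)
  mr <- c(mean(r[1:5]), mean(r[6:10]), mean(r[11:15]))
  cd <- stats::qnorm(1 - 0.05 / (3 * 2)) *
    sqrt(15 * 16 / 12 * (1 / 5 + 1 / 5))
  expect_equal(pw$critical_diff, rep(cd, 3), tolerance = 1e-12)
  expect_equal(pw$obs_diff,
               c(abs(mr[1] - mr[2]), abs(mr[1] - mr[3]), abs(mr[2] - mr[3])),
               tolerance = 1e-12)
  # |mean-rank difference| of lo-vs-mid (1.7) and mid-vs-hi (6.6) fall
  # below the critical difference (6.77); only lo-vs-hi (8.3) exceeds it
  expect_identical(pw$significant, c(FALSE, TRUE, FALSE))
})

test_that("type-III sums of squares match the model-comparison oracle", {
  # 16-row unbalanced fixture, printed in full
  d <- data.frame(
    z_rate = c(0.5, 1.2, -0.3, 0.8, -1.1, 0.4, 1.5, -0.2,
               0.9, -0.7, 0.1, 1.3, -0.5, 0.2, -1.4, 0.6),
    disorder = c("o", "o", "o", "o", "o", "d", "d", "d",
                 "o", "o", "d", "d", "o", "d", "d", "d"),
    ss = c("s", "s", "c", "c", "s", "s", "c", "c",
           "s", "c", "s", "c", "s", "s", "c", "c"),
    domain = c("D", "L", "D", "L", "D", "L", "D", "L",
               "D", "D", "L", "L", "L", "D", "D", "L"),
    stringsAsFactors = FALSE)
  got <- anova_type3(d)
  want <- type3_oracle(d)
  expect_equal(setNames(got$table$sum_sq, got$table$term), want,
               tolerance = 1e-9)
  expect_true(all(got$table$sum_sq >= 0))
  # 7 model terms of 1 df each; with the residual they partition N - 1
  expect_equal(sum(got$table$df), 7)
  expect_equal(got$fit$df.residual, nrow(d) - 8)

  # balanced design: type-III equals sequential type-I
  set.seed(12)
  bal <- expand.grid(disorder = c("o", "d"), ss = c("s", "c"),
                     domain = c("D", "L"), rep = 1:4,
                     stringsAsFactors = FALSE)
  bal$z_rate <- rnorm(nrow(bal))
  g3 <- anova_type3(bal)
  fit1 <- lm(z_rate ~ factor(disorder) * factor(ss) * factor(domain),
             data = bal)
  t1 <- anova(fit1)
  expect_equal(g3$table$sum_sq, t1$`Sum Sq`[seq_len(7)], tolerance = 1e-9)

  # missing cell raises an inestimability error naming the cell
  miss <- d[!(d$disorder == "d" & d$ss == "c" & d$domain == "L"), ]
  expect_error(anova_type3(miss), "empty cell")
})

test_that("cell means and margins are consistent", {
  d <- expand.grid(disorder = c("o", "d"), ss = c("s", "c"),
                   domain = c("D", "L"), stringsAsFactors = FALSE)
  d$z_rate <- 1:8
  cm <- cell_means(d)
  expect_equal(sort(cm$cells$mean), 1:8)
  expect_true(all(cm$cells$n == 1L))

  set.seed(13)
  d2 <- d[sample(8, 40, replace = TRUE), ]
  d2$z_rate <- rnorm(40)
  cm2 <- cell_means(d2)
  # margins recompute from cells weighted by counts
  m <- cm2$margins$disorder_ss
  for (k in seq_len(nrow(m))) {
    sel <- cm2$cells$disorder == m$disorder[k] & cm2$cells$ss == m$ss[k]
    expect_equal(m$mean[k],
                 sum(cm2$cells$mean[sel] * cm2$cells$n[sel]) /
                   sum(cm2$cells$n[sel]), tolerance = 1e-12)
  }

  allsame <- d
  allsame$z_rate <- 2
  expect_true(all(cell_means(allsame)$cells$mean == 2))
})

test_that("the tricube smoother is exact on lines and matches WLS by hand", {
  expect_equal(tricube(0), 1)
  expect_equal(tricube(1), 0)
  expect_equal(tricube(0.5), (1 - 0.125)^3)

  set.seed(14)
  x <- sort(runif(40))
  y <- 2 + 3 * x
  fit <- local_linear_fit(x, y, span = 0.5)
  expect_equal(fit$fitted, 2 + 3 * fit$x, tolerance = 1e-8)

  # one focal point against directly solved weighted least squares
  y2 <- sin(4 * x)
  x0 <- x[20]
  n <- length(x)
  q <- ceiling(0.75 * n)
  d <- abs(x - x0)
  h <- sort(d)[q]
  w <- tricube(d / h)
  use <- w > 0
  X <- cbind(1, x[use] - x0)
  beta <- solve(t(X) %*% (w[use] * X), t(X) %*% (w[use] * y2[use]))
  fit2 <- local_linear_fit(x, y2, span = 0.75, grid = x0)
  expect_equal(fit2$fitted, beta[1], tolerance = 1e-10)

  expect_error(local_linear_fit(1:3, 1:3, span = 0.5), "too small")
})

test_that("rank tests ignore monotone transforms; ANOVA F is affine-stable", {
  set.seed(15)
  a <- rnorm(25); b <- rnorm(30, 0.6)
  p1 <- mann_whitney(a, b)$p
  p2 <- mann_whitney(exp(a), exp(b))$p
  expect_equal(p1, p2, tolerance = 1e-12)
  k1 <- kruskal_wallis(list(a, b))$H
  k2 <- kruskal_wallis(list(exp(a), exp(b)))$H
  expect_equal(k1, k2, tolerance = 1e-12)

  d <- expand.grid(disorder = c("o", "d"), ss = c("s", "c"),
                   domain = c("D", "L"), rep = 1:5,
                   stringsAsFactors = FALSE)
  d$z_rate <- rnorm(nrow(d))
  f1 <- anova_type3(d)$table$f
  d$z_rate <- 3 * d$z_rate - 7
  f2 <- anova_type3(d)$table$f
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("loess_disorder_content requires enough families", {
  fs <- data.frame(disorder_content = runif(5), mean_ds_z_rate = rnorm(5))
  expect_error(loess_disorder_content(fs), "at least 10")
  set.seed(16)
  fs <- data.frame(disorder_content = runif(30),
                   mean_ds_z_rate = rnorm(30))
  out <- loess_disorder_content(fs)
  expect_equal(nrow(out$curve), 50L)
  expect_true(all(is.finite(out$curve$fitted)))
})
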