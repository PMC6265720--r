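# Independent oracles and small fixture builders used across the suite.
# Each oracle re-derives its quantity by brute force or closed form, never
# through the code path it checks.

toy_msa <- function(..., family_id = "toy") {
  seqs <- c(...)
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
  msa(seqs, family_id = family_id)
}

# --- likelihood enumeration oracle -----------------------------------------
# Sums over all joint internal-node state assignments; a gap tip contributes
# a factor of 1 (rows of P sum to one), so its pendant edge is dropped.
enum_site_likelihood <- function(x, tree, column, rate = 1) {
  m <- msa_matrix(x)
  obs <- match(m[, column], siterates::AA20)
  names(obs) <- rownames(m)
  n_tip <- length(tree$tip.label)
  internals <- sort(unique(tree$edge[, 1L]))
  pmats <- lapply(tree$edge.length * rate, transition_prob)
  grid <- as.matrix(expand.grid(rep(list(1:20), length(internals))))
  colnames(grid) <- as.character(internals)
  prob <- rep(1, nrow(grid))
  for (k in seq_len(nrow(tree$edge))) {
    par <- as.character(tree$edge[k, 1L])
    chi <- tree$edge[k, 2L]
    pstate <- grid[, par]
    if (chi <= n_tip) {
      cstate <- obs[tree$tip.label[chi]]
      if (is.na(cstate)) next  # gap: marginalizes to 1
      prob <- prob * pmats[[k]][cbind(pstate, cstate)]
    } else {
      cstate <- grid[, as.character(chi)]
      prob <- prob * pmats[[k]][cbind(pstate, cstate)]
    }
  }
  sum(prob) / 20  # uniform prior over the enumerated root state
}

# --- local alignment oracle -------------------------------------------------
# Exhaustive best local alignment: max over all substring pairs of the
# global affine-gap alignment score (gap of length L costs open + L * ext).
gotoh_global <- function(a, b, S, open, ext) {
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)  # gap in b (deletion from a)
  Y <- matrix(NEG, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  for (i in seq_len(n)) X[i + 1L, 1L] <- -(open + ext * i)
  for (j in seq_len(m)) Y[1L, j + 1L] <- -(open + ext * j)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- S[a[i], b[j]]
    M[i + 1L, j + 1L] <- max(M[i, j], X[i, j], Y[i, j]) + s
    X[i + 1L, j + 1L] <- max(M[i, j + 1L] - open - ext, X[i, j + 1L] - ext)
    Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - open - ext, Y[i + 1L, j] - ext)
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

sw_oracle_score <- function(a, b, open = 11, ext = 1) {
  S <- blosum62_matrix()
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  best <- 0
  for (i1 in seq_along(av)) for (i2 in i1:length(av))
    for (j1 in seq_along(bv)) for (j2 in j1:length(bv)) {
      sc <- gotoh_global(av[i1:i2], bv[j1:j2], S, open, ext)
      if (sc > best) best <- sc
    }
  best
}

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# --- graph components oracle ------------------------------------------------
brute_components <- function(ids, edges) {
  adj <- setNames(vector("list", length(ids)), ids)
  if (nrow(edges) > 0L) for (k in seq_len(nrow(edges))) {
    adj[[edges$id_a[k]]] <- c(adj[[edges$id_a[k]]], edges$id_b[k])
    adj[[edges$id_b[k]]] <- c(adj[[edges$id_b[k]]], edges$id_a[k])
  }
  seen <- setNames(rep(FALSE, length(ids)), ids)
  comps <- list()
  for (v in ids) {
    if (seen[v]) next
    stack <- v
    comp <- character(0)
    while (length(stack) > 0L) {
      u <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (seen[u]) next
      seen[u] <- TRUE
      comp <- c(comp, u)
      stack <- c(stack, adj[[u]])
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# canonical form of a partition for comparison
canon_partition <- function(clusters) {
  cl <- lapply(clusters, sort)
  cl[order(vapply(cl, `[`, character(1), 1L))]
}

# --- type-III ANOVA oracle --------------------------------------------------
# explicit full-vs-reduced residual-SS differences under effects coding
type3_oracle <- function(d) {
  for (f in c("disorder", "ss", "domain")) d[[f]] <- factor(d[[f]])
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  full <- stats::model.matrix(~ disorder * ss * domain, d)
  rss <- function(X) sum(stats::lm.fit(X, d$z_rate)$residuals^2)
  full_rss <- rss(full)
  assign_idx <- attr(full, "assign")
  labs <- attr(stats::terms(~ disorder * ss * domain), "term.labels")
  ss_out <- setNames(numeric(length(labs)), labs)
  for (k in seq_along(labs))
    ss_out[k] <- rss(full[, assign_idx != k, drop = FALSE]) - full_rss
  ss_out
}

# --- misc -------------------------------------------------------------------
random_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(siterates::AA20, n, replace = TRUE), collapse = "")
}

# tiny tree literals used in several tests
tree3 <- function() ape::read.tree(text = "((t1:0.2,t2:0.3):0.1,t3:0.4);")
tree4 <- function()
  ape::read.tree(text = "((t1:0.2,t2:0.3):0.15,(t3:0.25,t4:0.1):0.05);")
tree4_caterpillar <- function()
  ape::read.tree(text = "(((t1:0.1,t2:0.2):0.1,t3:0.3):0.1,t4:0.4);")
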