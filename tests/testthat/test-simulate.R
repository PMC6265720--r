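# Synthetic-family generator: tree sampler, architecture sampler, sequence
# evolution, indels, annotation emission, and the generator-wide invariants.

test_that("sample_tree produces binary trees of the requested depth", {
  expect_error(sample_tree(1L), "at least 2")

  cherry <- sample_tree(2L, tree_height = 0.5, seed = 1)
  expect_s3_class(cherry, "phylo")
  expect_equal(length(cherry$tip.label), 2L)
  expect_equal(nrow(cherry$edge), 2L)

  t1 <- sample_tree(16L, tree_height = 1.0, seed = 42)
  t2 <- sample_tree(16L, tree_height = 1.0, seed = 42)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_equal(length(t1$tip.label), 16L)
  expect_true(all(t1$edge.length > 0))
  expect_equal(anyDuplicated(t1$tip.label), 0L)

  # mean root-to-tip depth across replicates stays within 10% of the target
  depths <- vapply(1:200, function(s) {
    tr <- sample_tree(16L, tree_height = 0.8, seed = 1000 + s)
    mean(ape::node.depth.edgelength(tr)[seq_len(16L)])
  }, numeric(1))
  expect_lt(abs(mean(depths) - 0.8), 0.08)
})

test_that("sample_architecture lays down complete segmental class triples", {
  expect_error(sample_architecture(0L), "at least 1")

  cls <- sample_architecture(500L, seed = 7)
  expect_equal(nrow(cls), 500L)
  expect_true(all(cls$disorder %in% 0:1))
  expect_true(all(cls$ss %in% c("H", "E", "C")))
  expect_true(all(cls$domain %in% 0:1))

  cls2 <- sample_architecture(500L, seed = 7)
  expect_identical(cls, cls2)

  # degenerate parameter: no disorder anywhere
  none <- sample_architecture(
    300L, architecture_params(disorder_mean = 0), seed = 3)
  expect_true(all(none$disorder == 0L))

  # mean domain-segment length tracks the geometric expectation
  big <- sample_architecture(
    10000L, architecture_params(domain_mean = 50, linker_mean = 50), seed = 9)
  r <- rle(big$domain)
  lens <- r$lengths[r$values == 1L]
  lens <- lens[-c(1L, length(lens))]  # edge segments are truncated
  expect_lt(abs(mean(lens) - 50) / 50, 0.15)
})

test_that("evolve_family follows the equal-exchange process at class rates", {
  cls <- data.frame(disorder = 0L, ss = "C", domain = 1L)[rep(1, 50), ]
  flat <- ape::read.tree(text = "((t1:0,t2:0):0,(t3:0,t4:0):0);")
  ev <- evolve_family(flat, cls, gamma_shape = Inf, seed = 2)
  m <- msa_matrix(ev$alignment)
  expect_true(all(m == matrix(m[1, ], 4, 50, byrow = TRUE)))

  # one branch of length t: closed-form expected mismatch fraction
  n <- 10000L
  cls <- data.frame(disorder = 0L, ss = "C", domain = 1L)[rep(1, n), ]
  mult1 <- setNames(1, "0:C:1")
  two <- ape::read.tree(text = "(t1:0.6,t2:0);")
  ev <- evolve_family(two, cls, mult1, gamma_shape = Inf, seed = 5)
  p_hat <- p_distance(ev$alignment$seqs[["t1"]], ev$alignment$seqs[["t2"]])
  p_exp <- (19 / 20) * (1 - exp(-(20 / 19) * 0.6))
  expect_lt(abs(p_hat - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n))

  # rates are relative: doubling all multipliers changes nothing
  cls <- sample_architecture(200L, seed = 8)
  tr <- sample_tree(6L, 0.5, seed = 8)
  e1 <- evolve_family(tr, cls, default_class_multipliers(), seed = 13)
  e2 <- evolve_family(tr, cls, 2 * default_class_multipliers(), seed = 13)
  expect_identical(e1$alignment$seqs, e2$alignment$seqs)
  expect_equal(e1$site_rates, e2$site_rates)

  # missing multiplier for an occurring class is a configuration error
  expect_error(
    evolve_family(tr, cls, mult1, seed = 1),
    "no multiplier")
})

test_that("class multipliers accelerate the classes they target", {
  # disordered sites at twice the ordered rate, everything else equal
  n <- 1000L
  cls <- data.frame(disorder = rep(0:1, each = n / 2),
                    ss = "C", domain = 1L, stringsAsFactors = FALSE)
  mult <- setNames(c(1, 2), c("0:C:1", "1:C:1"))
  tr <- sample_tree(8L, 0.5, seed = 21)
  ev <- evolve_family(tr, cls, mult, gamma_shape = Inf, seed = 22)
  m <- msa_matrix(ev$alignment)
  mean_pdist <- function(cols) {
    sub <- m[, cols, drop = FALSE]
    mean(utils::combn(nrow(sub), 2, function(ij)
      mean(sub[ij[1], ] != sub[ij[2], ])))
  }
  expect_gt(mean_pdist(which(cls$disorder == 1L)),
            mean_pdist(which(cls$disorder == 0L)))
})

test_that("add_indels hits the target gapped fraction and conserves residues", {
  fam <- quick_family(seed = 31, indel_rate = 0)
  aln <- fam$alignment
  expect_identical(add_indels(aln, 0), aln)

  gapped <- add_indels(aln, 0.34, seed = 32)
  m0 <- msa_matrix(aln)
  m1 <- msa_matrix(gapped)
  expect_equal(dim(m0), dim(m1))
  # gaps only replace residues in place; degapping recovers a subsequence
  expect_true(all(m1 == m0 | m1 == "-"))
  frac <- mean(colSums(m1 == "-") > 0)
  expect_equal(frac, round(0.34 * ncol(m1)) / ncol(m1), tolerance = 1e-12)
  expect_error(add_indels(aln, 1.0), "indel_rate")
})

test_that("emit_annotations encodes true classes with the stated noise model", {
  expect_error(
    emit_annotations(data.frame(disorder = 0L, ss = "C", domain = 0L),
                     toy_msa(s1 = "A"), annotation_noise = 0.5),
    "annotation_noise")

  # noiseless: every residue's annotation reflects its column's true class
  fam <- quick_family(seed = 41, noise = 0)
  ann <- fam$annotations
  cmap <- msa_coordinate_map(fam$alignment)
  ids <- names(fam$alignment$seqs)
  for (i in seq_along(ids)) {
    idx <- cmap[[i]]
    res <- !is.na(idx)
    truth <- fam$site_classes[res, ]
    scores <- ann$disorder[[ids[i]]][idx[res] + 1L]
    expect_true(all((scores > 0.4) == (truth$disorder == 1L)))
    expect_identical(unname(ann$ss[[ids[i]]][idx[res] + 1L]), truth$ss)
    in_dom <- rep(FALSE, length(ann$disorder[[ids[i]]]))
    ivs <- ann$domains[[ids[i]]]
    if (nrow(ivs) > 0) for (k in seq_len(nrow(ivs)))
      in_dom[(ivs$start[k] + 1):ivs$end[k]] <- TRUE
    expect_identical(in_dom[idx[res] + 1L], truth$domain == 1L)
  }

  # noise 0.1, 10 sequences: a fully-disordered column keeps its conserved
  # label only if no score flips; loss fraction ~ 1 - 0.9^10
  n_sites <- 1500L
  cls <- data.frame(disorder = 1L, ss = "C", domain = 1L)[rep(1, n_sites), ]
  tr <- sample_tree(10L, 0.3, seed = 51)
  ev <- evolve_family(tr, cls, setNames(1, "1:C:1"), seed = 52)
  ann <- emit_annotations(cls, ev$alignment, annotation_noise = 0.1, seed = 53)
  scores <- do.call(rbind, ann$disorder)
  lost <- mean(colSums(scores < 0.4) > 0)
  p <- 1 - 0.9^10
  expect_lt(abs(lost - p), 3 * sqrt(p * (1 - p) / n_sites))
})

test_that("simulate_family is seed-deterministic with mean-one site rates", {
  f1 <- simulate_family(simulation_config(seed = 61))
  f2 <- simulate_family(simulation_config(seed = 61))
  expect_identical(f1$alignment$seqs, f2$alignment$seqs)
  expect_identical(ape::write.tree(f1$tree), ape::write.tree(f2$tree))
  expect_identical(f1$annotations, f2$annotations)
  expect_identical(f1$site_rates, f2$site_rates)

  expect_equal(mean(f1$site_rates), 1, tolerance = 1e-9)
  expect_equal(length(f1$site_rates), msa_ncol(f1$alignment))
  expect_true(all(f1$site_rates > 0))

  expect_error(simulation_config(n_taxa = 3L), "at least 4")
  expect_error(simulation_config(annotation_noise = 0.5), "annotation_noise")
})

test_that("truth tables round-trip through TSV", {
  fam <- quick_family(seed = 71, n_taxa = 6L, n_sites = 40L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth_tsv(fam, path)
  back <- utils::read.delim(path)
  expect_equal(nrow(back), 40L)
  expect_equal(back$true_rate, fam$site_rates, tolerance = 1e-12)
  expect_identical(back$ss, fam$site_classes$ss)
  expect_identical(back$column_index, 0:39)
})
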