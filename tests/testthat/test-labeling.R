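# Annotation-to-column mapping, the three unanimity label rules with gap
# exclusion, and the label-table bookkeeping.

test_that("map_to_columns respects the coordinate map", {
  # ungapped single row: identity mapping
  x <- toy_msa(s1 = "ACDE")
  ann <- annotation_bundle(
    disorder = list(s1 = c(0.1, 0.2, 0.3, 0.9)),
    ss = list(s1 = c("H", "H", "C", "C")),
    domains = list(s1 = data.frame(start = 0L, end = 2L)))
  mp <- map_to_columns(x, ann)
  expect_equal(mp$disorder[1, ], c(0.1, 0.2, 0.3, 0.9))
  expect_equal(mp$ss[1, ], c("H", "H", "C", "C"))
  expect_equal(mp$in_domain[1, ], c(TRUE, TRUE, FALSE, FALSE))

  # gapped row: column 2 is null, columns 1,3,4 map to residues 1,2,3
  x <- toy_msa(s1 = "A-CD")
  ann <- annotation_bundle(
    disorder = list(s1 = c(0.5, 0.6, 0.7)),
    ss = list(s1 = c("C", "E", "E")),
    domains = list(s1 = data.frame(start = integer(0), end = integer(0))))
  mp <- map_to_columns(x, ann)
  expect_equal(mp$disorder[1, ], c(0.5, NA, 0.6, 0.7))
  expect_equal(mp$ss[1, ], c("C", NA, "E", "E"))

  expect_error(map_to_columns(
    x, annotation_bundle(disorder = list(s1 = c(0.5, 0.6)),
                         ss = list(s1 = c("C", "E")),
                         domains = list(s1 = data.frame(start = integer(0),
                                                        end = integer(0))))),
    "track length")
})

test_that("column-residue mapping round-trips on random gapped alignments", {
  set.seed(7)
  for (rep in 1:5) {
    fam <- quick_family(seed = 100 + rep, n_taxa = 6L, n_sites = 60L,
                        indel_rate = 0.4)
    cmap <- msa_coordinate_map(fam$alignment)
    m <- msa_matrix(fam$alignment)
    for (i in seq_along(cmap)) {
      idx <- cmap[[i]]
      res_cols <- which(!is.na(idx))
      # residue indices are consecutive 0..k-1 in column order
      expect_identical(idx[res_cols], seq_along(res_cols) - 1L)
      expect_identical(m[i, res_cols],
                       strsplit(msa_ungap(fam$alignment)[[i]], "")[[1]])
    }
  }
})

test_that("the three unanimity rules label exactly as stated", {
  expect_equal(label_disorder(c(0.6, 0.7, 0.5)), "disordered")
  expect_equal(label_disorder(c(0.3, 0.6)), "unlabeled")
  expect_equal(label_disorder(c(0.1, 0.2)), "ordered")
  # a score exactly at the cutoff is neither above nor below
  expect_equal(label_disorder(c(0.4, 0.41)), "unlabeled")

  expect_equal(label_ss(c("H", "H", "H")), "structured")
  expect_equal(label_ss(c("E", "E")), "structured")
  expect_equal(label_ss(c("H", "E", "H")), "unlabeled")
  expect_equal(label_ss(c("C", "C", "C")), "coil")
  expect_equal(label_ss(c("C", "H")), "unlabeled")

  expect_equal(label_domain(c(TRUE, TRUE)), "domain")
  expect_equal(label_domain(c(FALSE, FALSE)), "linker")
  expect_equal(label_domain(c(TRUE, FALSE, FALSE)), "unlabeled")
})

test_that("build_label_table matches a hand-worked toy with gap exclusion", {
  # 3 sequences x 6 columns; columns 3 and 5 (1-based) contain gaps
  x <- toy_msa(s1 = "AC-DEF",
               s2 = "ACGD-F",
               s3 = "ACGDEF")
  ann <- annotation_bundle(
    disorder = list(s1 = c(0.8, 0.9, 0.7, 0.1, 0.2),
                    s2 = c(0.9, 0.6, 0.5, 0.6, 0.3),
                    s3 = c(0.7, 0.8, 0.9, 0.3, 0.3, 0.2)),
    ss = list(s1 = c("H", "H", "C", "C", "C"),
              s2 = c("H", "H", "E", "E", "C"),
              s3 = c("H", "H", "E", "C", "C", "C")),
    domains = list(s1 = data.frame(start = 0L, end = 2L),
                   s2 = data.frame(start = 0L, end = 4L),
                   s3 = data.frame(start = 0L, end = 2L)))
  lt <- build_label_table(x, ann)
  tab <- lt$table
  # hand-derived: col1 all residues, scores .8/.9/.7 -> disordered; H/H/H
  # structured; all in domain -> domain; tri-complete
  expect_identical(tab$gap_free, c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_identical(tab$disorder_label,
                   c("disordered", "disordered", "unlabeled", "unlabeled",
                     "unlabeled", "ordered"))
  expect_identical(tab$ss_label,
                   c("structured", "structured", "unlabeled", "unlabeled",
                     "unlabeled", "coil"))
  expect_identical(tab$domain_label,
                   c("domain", "domain", "unlabeled", "unlabeled",
                     "unlabeled", "linker"))
  expect_identical(tab$tri_factor_complete,
                   c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(unname(lt$summary[["gap_free_sites"]]), 4)
  expect_equal(unname(lt$summary[["tri_factor_sites"]]), 3)
})

test_that("labels recover truth on a noiseless family and ignore duplicates", {
  fam <- quick_family(seed = 111, noise = 0, indel_rate = 0.3)
  lt <- build_label_table(fam$alignment, fam$annotations)
  tab <- lt$table
  truth <- fam$site_classes
  gf <- tab$gap_free
  expect_identical(tab$disorder_label[gf],
                   ifelse(truth$disorder[gf] == 1, "disordered", "ordered"))
  expect_identical(tab$ss_label[gf],
                   ifelse(truth$ss[gf] == "C", "coil", "structured"))
  expect_identical(tab$domain_label[gf],
                   ifelse(truth$domain[gf] == 1, "domain", "linker"))
  # gapped columns carry no labels at all
  expect_true(all(tab$disorder_label[!gf] == "unlabeled"))
  expect_true(all(!tab$tri_factor_complete[!gf]))

  # duplicating a row leaves every label unchanged
  aln2 <- msa(c(fam$alignment$seqs,
                dup = unname(fam$alignment$seqs[1])), family_id = "dup")
  ann2 <- fam$annotations
  id1 <- names(fam$alignment$seqs)[1]
  ann2$disorder$dup <- ann2$disorder[[id1]]
  ann2$ss$dup <- ann2$ss[[id1]]
  ann2$domains$dup <- ann2$domains[[id1]]
  lt2 <- build_label_table(aln2, ann2)
  expect_identical(lt2$table$disorder_label, tab$disorder_label)
  expect_identical(lt2$table$ss_label, tab$ss_label)
  expect_identical(lt2$table$domain_label, tab$domain_label)
})

test_that("per-factor label counts partition the gap-free columns", {
  fam <- quick_family(seed = 121, noise = 0.1, indel_rate = 0.3)
  lt <- build_label_table(fam$alignment, fam$annotations)
  s <- lt$summary
  gf <- s[["gap_free_sites"]]
  tab <- lt$table
  for (col in c("disorder_label", "ss_label", "domain_label")) {
    labeled <- sum(tab$gap_free & tab[[col]] != "unlabeled")
    unlabeled <- sum(tab$gap_free & tab[[col]] == "unlabeled")
    expect_equal(labeled + unlabeled, gf)
  }
  expect_equal(s[["ordered_sites"]] + s[["disordered_sites"]] +
                 sum(tab$gap_free & tab$disorder_label == "unlabeled"),
               gf, ignore_attr = TRUE)
})

test_that("annotation bundles round-trip through their tabular formats", {
  fam <- quick_family(seed = 131, n_taxa = 5L, n_sites = 50L, noise = 0.1)
  d <- withr::local_tempfile(fileext = ".tsv")
  s <- withr::local_tempfile(fileext = ".tsv")
  dm <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(fam$annotations, d, s, dm)
  back <- read_annotations(d, s, dm)
  ids <- names(fam$annotations$disorder)
  for (id in ids) {
    expect_equal(back$disorder[[id]], unname(fam$annotations$disorder[[id]]),
                 tolerance = 1e-9)
    expect_identical(back$ss[[id]], unname(fam$annotations$ss[[id]]))
    expect_equal(back$domains[[id]]$start, fam$annotations$domains[[id]]$start)
    expect_equal(back$domains[[id]]$end, fam$annotations$domains[[id]]$end)
  }
})
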