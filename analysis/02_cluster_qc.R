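#!/usr/bin/env Rscript
# Stage 2: homolog clustering check and alignment suitability filters.
#
# Clustering demonstration: pool the ungapped members of three families
# with unrelated random sequences and confirm that single linkage under the
# 40% identity / 90% coverage criteria recovers exactly the families (and
# no cluster of unrelated sequences reaches the 10-member floor). Then run
# the five suitability filters on every simulated family alignment.

source("analysis/00_config.R")

ids <- list_family_ids()

## clustering on a manageable subset (all-vs-all local alignments)
subset_ids <- head(ids, 3)
seqs <- character(0)
for (fid in subset_ids) {
  aln <- read_msa(family_paths(fid)$alignment, family_id = fid)
  ug <- msa_ungap(aln)
  names(ug) <- paste(fid, names(ug), sep = ".")
  seqs <- c(seqs, ug)
}
set.seed(ANALYSIS_SEED)
randoms <- vapply(1:20, function(i)
  paste(sample(AA20, 250, replace = TRUE), collapse = ""), character(1))
names(randoms) <- paste0("random", 1:20)
seqs <- c(seqs, randoms)

cs <- cluster_sequences(seqs, size_range = pipe_config$cluster_size)
write_clusters_tsv(cs, file.path(RESULTS_DIR, "clusters.tsv"))
recovered <- vapply(cs$clusters, function(cl)
  length(unique(sub("\\..*$", "", cl))) == 1L, logical(1))
cat(sprintf("clustering: %d sequences (%d members of %d families + %d randoms) -> %d clusters within the size bounds [%g, %g], %s single-family, none random (families smaller than the floor are dropped)\n",
            length(seqs), length(seqs) - 20L, length(subset_ids), 20L,
            length(cs$clusters), pipe_config$cluster_size[1],
            pipe_config$cluster_size[2],
            if (all(recovered)) "all" else "NOT all"))

## suitability filters per family
qc_rows <- lapply(ids, function(fid) {
  aln <- read_msa(family_paths(fid)$alignment, family_id = fid)
  r <- qc_filter(aln, min_identity = pipe_config$qc_identity,
                 min_coverage = pipe_config$qc_coverage,
                 max_conserved = pipe_config$qc_conserved,
                 min_unique = pipe_config$qc_unique)
  data.frame(family_id = fid, pass = r$pass,
             min_pairwise_identity = r$values$min_pairwise_identity,
             min_length_fraction = r$values$min_length_fraction,
             conserved_fraction = r$values$conserved_fraction,
             n_unique = r$values$n_unique_sequences)
})
qc_tab <- do.call(rbind, qc_rows)
write_tsv(qc_tab, file.path(RESULTS_DIR, "qc_report.tsv"))
cat(sprintf("suitability filters: %d of %d families pass (min identity %.2f-%.2f)\n",
            sum(qc_tab$pass), nrow(qc_tab),
            min(qc_tab$min_pairwise_identity),
            max(qc_tab$min_pairwise_identity)))
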