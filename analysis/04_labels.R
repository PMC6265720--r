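#!/usr/bin/env Rscript
# Stage 4: conserved tri-factor site labeling.
#
# Map the noisy annotation tracks onto alignment columns, exclude every
# column containing a gap, assign the three unanimity labels
# (ordered/disordered, structured/coil, domain/linker), and join the labels
# with the z-normalized site rates into the pooled per-site table that the
# statistical battery consumes.

source("analysis/00_config.R")

rates <- utils::read.delim(file.path(RESULTS_DIR, "site_rates.tsv"))
ids <- unique(rates$family_id)

rows <- list()
for (fid in ids) {
  p <- family_paths(fid)
  aln <- read_msa(p$alignment, family_id = fid)
  ann <- read_annotations(p$disorder, p$ss, p$domains)
  lt <- build_label_table(aln, ann, cutoff = pipe_config$disorder_cutoff)
  tab <- lt$table
  r <- rates[rates$family_id == fid, ]
  tab$raw_rate <- r$raw_rate[match(tab$column_index, r$column_index)]
  tab$z_rate <- r$z_rate[match(tab$column_index, r$column_index)]
  rows[[fid]] <- tab
}
sites <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
write_tsv(sites, file.path(RESULTS_DIR, "sites.tsv"))

gf <- sites[sites$gap_free, ]
cat(sprintf("labeling: %d sites, %d gap-free (%.0f%%); ordered %d / disordered %d, structured %d / coil %d, domain %d / linker %d; %d tri-factor-complete\n",
            nrow(sites), nrow(gf), 100 * nrow(gf) / nrow(sites),
            sum(gf$disorder_label == "ordered"),
            sum(gf$disorder_label == "disordered"),
            sum(gf$ss_label == "structured"), sum(gf$ss_label == "coil"),
            sum(gf$domain_label == "domain"),
            sum(gf$domain_label == "linker"),
            sum(gf$tri_factor_complete)))
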