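# Shared settings for the analysis drivers. Source()d by every numbered
# script; all paths are relative to the repository root.

library(siterates)

ANALYSIS_SEED <- 101L
N_FAMILIES <- 20L

RESULTS_DIR <- "results"
FAMILY_DIR <- file.path(RESULTS_DIR, "families")

base_config <- simulation_config(seed = ANALYSIS_SEED)
pipe_config <- pipeline_config()

family_paths <- function(fam_id) {
  d <- file.path(FAMILY_DIR, fam_id)
  list(dir = d,
       alignment = file.path(d, "alignment.fasta"),
       tree = file.path(d, "tree.nwk"),
       disorder = file.path(d, "disorder.tsv"),
       ss = file.path(d, "ss.tsv"),
       domains = file.path(d, "domains.tsv"),
       truth = file.path(d, "truth.tsv"))
}

list_family_ids <- function() sort(list.dirs(FAMILY_DIR, recursive = FALSE,
                                             full.names = FALSE))

write_tsv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
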