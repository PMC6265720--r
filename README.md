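# siterates

Structural context shapes how fast individual protein sites evolve:
intrinsically disordered sites tend to accumulate amino acid replacements
faster than ordered sites, random-coil sites faster than sites in helices
or strands, inter-domain linkers faster than functional domains — and the
factors interact, most strikingly at sites that are *both* disordered and
involved in secondary structure, which are among the slowest-evolving of
all (a signature of transient, fold-upon-binding elements).

`siterates` is an R package plus analysis workflow for measuring these
effects on protein family alignments. It is aimed at molecular
evolutionists who have (or simulate) aligned homolog families with trees
and per-residue structural annotations, and want site-level rate estimates
joined to conserved structural labels with a defensible statistical
analysis on top.

## What it implements

* **Clustering** — graph-based single linkage over best local alignments
  (BLOSUM62, affine gaps 11/1): sequences link iff identity ≥ 40% over the
  alignment footprint and the footprint covers ≥ 90% of the longer
  sequence; components of 10–300 members become families.
* **Alignment QC** — five suitability filters: minimum pairwise identity
  (1 − p-distance) ≥ 30%, every row ≥ 50% of the alignment length, standard
  residues only, < 90% conserved columns, ≥ 4 unique sequences.
* **Site-rate inference** — empirical-Bayes posterior-mean rates on a fixed
  tree under the 20-state equal-exchangeability model
  (p<sub>same</sub>(t) = 1/20 + (19/20)e<sup>−(20/19)t</sup>) with a
  16-category discrete gamma whose shape α is fitted per family by maximum
  likelihood; Felsenstein pruning with per-node scaling; per-family
  z-normalization (mean 0, unit spread; positive = faster).
* **Site labeling** — per-residue disorder scores (cutoff 0.4),
  H/E/C secondary structure and domain intervals mapped onto columns;
  a column with any gap is excluded; labels require unanimity across all
  sequences (disordered/ordered, structured/coil, domain/linker).
* **Statistics** — Mann-Whitney contrasts (exact enumeration for tiny
  groups), Kruskal-Wallis over the eight factor-level cells with 28
  mean-rank pairwise comparisons at a Bonferroni-adjusted critical
  difference, type-III factorial ANOVA with zero-sum contrasts, cell and
  margin means, and a tricube local-linear regression of family disorder
  content against disordered-structured site rates.
* **Synthetic families** — a generator with known Yule tree, segmental
  site architecture, class-dependent rate multipliers (defaults: disordered
  coil ×2.0, coil ×1.3, linker ×1.5, disordered-structured ×0.5), gamma
  residual rate variation, post-hoc indels, and noisy annotation emission —
  so every stage is testable against ground truth.

See `vignettes/site-rate-drivers.Rmd` for the models, conventions and
design choices in detail.

## Worked example

Simulate one family and run it through QC, rate inference and labeling:

```r
library(siterates)
cfg <- simulation_config(n_taxa = 12, n_sites = 200, seed = 5)
fam <- simulate_family(cfg)
res <- process_family(fam$alignment, fam$annotations, tree = fam$tree)
print(res$qc)
print(res$profile)
print(res$labels)
cor(fam$site_rates, res$profile$raw_rates, method = "spearman")
```

```
qc_report 'fam1': PASS
  min_identity    ok
  min_coverage    ok
  standard_chars  ok
  not_conserved   ok
  unique_rows     ok
site_rate_profile 'fam1': 200 sites, alpha = 1.036, logL = -3367.71
site_label_table:
     total_sites   gap_free_sites    ordered_sites disordered_sites
             200              132               54                9
structured_sites       coil_sites     domain_sites     linker_sites
              32               32              109               21
tri_factor_sites
              33
Spearman(true rate, inferred rate) = 0.82
```

The family passes all five filters; the fitted gamma shape (1.04) recovers
the generating value (1.0); 132 of 200 columns are gap-free, of which 33
carry all three conserved labels; and the inferred posterior-mean rates
rank-correlate 0.82 with the true simulated rates.

The numbered scripts under `analysis/` run the same machinery as a
file-to-file workflow on a 20-family dataset — `01_simulate.R` writes the
families (FASTA/Newick/annotation TSVs), `02_cluster_qc.R` checks
clustering and the filters, `03_rates.R` fits rates on re-estimated NJ
trees, `04_labels.R` joins labels with rates, and `05_stats.R` produces
the Mann-Whitney, ANOVA, cell-mean, pairwise-comparison and
disorder-content regression tables under `results/`.

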