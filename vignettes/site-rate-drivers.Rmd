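---
title: "Site-specific evolutionary rates and conserved structural factors"
author: "siterates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Site-specific evolutionary rates and conserved structural factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question

Amino acid replacement rates vary strongly among the sites of a protein.
Part of that variation tracks structural context: sites in intrinsically
disordered regions (IDRs) tend to evolve faster than ordered sites, random
coil faster than helices and strands, and inter-domain linkers faster than
functional domains — yet the three factors interact, and sites that are
simultaneously disordered *and* involved in secondary structure are among
the slowest of all, a signature of transient structural elements that fold
upon binding. `siterates` implements the full analysis chain needed to
measure these effects on protein family alignments: homolog clustering,
alignment quality control, empirical-Bayes site-rate inference on a fixed
tree, conserved tri-factor site labeling, and the downstream statistical
battery, together with a synthetic-family generator that gives every stage
a ground truth to be tested against.

## Pipeline overview

For each protein family (an aligned set of homologs plus a tree and
per-sequence annotation tracks) the pipeline:

1. applies five suitability filters (`qc_filter`);
2. infers per-column relative rates under a 20-state
   equal-exchangeability substitution model with 16-category
   discrete-gamma rate variation, and z-normalizes them per family
   (`site_rate_profile`);
3. maps per-residue disorder scores, secondary-structure states and
   domain intervals onto alignment columns and assigns conserved binary
   labels with gap exclusion (`build_label_table`);
4. pools labeled sites across families and runs the statistical battery
   (`stats_battery`): Mann-Whitney contrasts, Kruskal-Wallis with
   mean-rank pairwise comparisons, type-III factorial ANOVA with zero-sum
   contrasts, cell means, and a tricube local regression of family
   disorder content against disordered-structured site rates.

`run_pipeline` orchestrates all stages; the numbered scripts under
`analysis/` run them file-to-file so every stage is independently
re-runnable.

## The substitution and rate model

Rates are scored under the amino-acid generalization of the
equal-probability (Jukes–Cantor-style) model: all exchangeabilities equal,
uniform equilibrium frequencies $\pi_a = 1/20$. With time measured in
expected substitutions per site its transition probabilities are closed
form,

$$p_\mathrm{same}(t) = \tfrac{1}{20} + \tfrac{19}{20}e^{-\frac{20}{19}t},
\qquad
p_\mathrm{diff}(t) = \tfrac{1}{20} - \tfrac{1}{20}e^{-\frac{20}{19}t},$$

which the test suite verifies against a numerical matrix exponential of
the generator. The equal-probability choice makes the inferred rates a
direct measure of replacement intensity rather than exchangeability
structure, which is why it is preferred here over empirical matrices.

Among-site rate variation is a discrete gamma: the mean-one gamma with
shape $\alpha$ is cut into $K = 16$ equal-probability bins whose
representative rates are the conditional bin means, rescaled to average
exactly 1. The shape is fitted per family by maximizing

$$\ell(\alpha) = \sum_s \log \sum_{c=1}^{K} \tfrac{1}{K}
  L(x_s \mid \text{tree}, r_c(\alpha))$$

with Brent search on $\alpha \in [0.05, 50]$ (tolerance $10^{-4}$). A fit
pinned at either bound triggers a warning — it means the data carry no
usable rate-variation signal (e.g. an all-invariant alignment).

Column likelihoods $L(x_s \mid r)$ come from Felsenstein pruning with
branch lengths scaled by $r$. Because the model has only two distinct
transition probabilities, each edge contributes
$p_\mathrm{diff}(t r)\,\mathbf{1}^\top L_c + e^{-\frac{20}{19}tr} L_c$ to
its parent's partial vector, which vectorizes across sites. Partials are
renormalized by their column maximum at every internal node, with the log
scale accumulated, so likelihoods do not underflow even on
hundreds-of-taxa families. A gap at a leaf is missing data (a partial
vector of ones); downstream statistics exclude gapped columns anyway, so
this choice affects only the fitted shape, mildly.

The empirical-Bayes point estimate per column is the posterior-mean rate

$$\hat r_s = \frac{\sum_c r_c\, L(x_s \mid r_c)}{\sum_c L(x_s \mid r_c)},$$

bounded by the extreme category rates. Within each family the raw rates
are z-normalized, $(\hat r_s - \bar r)/\sigma_r$ with the population
standard deviation, so scores are comparable across families and positive
values mark faster-than-average sites. The zero mean is the essential
convention; scaling to unit spread (population, not sample, standard
deviation) is this package's choice and is what makes pooled-site
analyses sensible. A zero-variance family yields all-zero scores with a
warning rather than an error.

`build_nj_tree` provides a convenience tree for families that lack one:
neighbor joining on uncorrected p-distances with negative branch lengths
clamped to zero. Uncorrected distances compress deep branches; relative
site rates, which are what the z-scores retain, are insensitive to that
compression, and in real use trees come from proper phylogenetic
inference upstream.

## Clustering and suitability filters

Homologs are grouped by graph-based single linkage: two sequences are
linked iff their best local alignment (BLOSUM62, affine gaps open 11 /
extend 1 — the conventional protein-search scoring) has identity
$\ge 40\%$ over its footprint *and* the footprint covers $\ge 90\%$ of the
longer sequence. Identity counts gap columns of the local alignment in the
denominator. Connected components of the link graph with 10–300 members
become families. A pair whose length ratio is below
$0.9 \times 0.4 = 0.36$ is skipped without aligning: matches cannot exceed
the shorter length, so footprint coverage and identity cannot both hold —
the prefilter provably never changes a verdict (asserted in the tests).

An aligned family enters rate inference only if (i) minimum pairwise
identity ($1 - p$-distance, pairwise gap deletion) is at least 30%;
(ii) every row covers at least 50% of the alignment length; (iii) only
the 20 standard residues and `-` occur; (iv) fewer than 90% of columns
are conserved; and (v) at least four distinct ungapped sequences are
present. Thresholds are inclusive exactly as "at least"/"less than"
dictate. A conserved column in (iv) must be gap-free and invariant;
counting gapped invariant columns as non-conserved is this package's
documented choice (`max_conserved` and the rest are configurable in
`qc_filter`), consistent with the downstream exclusion of gapped columns.

## Site labeling

Annotation tracks mirror standard predictor outputs: per-residue disorder
propensities in $[0,1]$, three-state secondary structure (H/E/C), and
domain intervals (0-based half-open internally; 1-based inclusive in
report files, stated in their headers). Labels are assigned per column,
only to columns without any gap character, and only when the prediction is
unanimous: *disordered* iff every score is strictly above 0.4, *ordered*
iff strictly below (a score exactly at the cutoff leaves the site
unlabeled); *structured* iff all sequences are in a helix or all in a
strand — the same element type — *coil* iff all are in coil; *domain* iff
every residue lies in some domain interval (intervals are merged first;
domain identity is not compared), *linker* iff none does. Sites with all
three labels are "tri-factor complete" and enter the eight-cell analyses.

## The statistical battery

Sites are pooled across families and treated as independent observations
(the conventional design for proteome-scale site analyses; a per-family
stratification would be a different estimand). Three Mann-Whitney contrasts compare
disordered vs ordered, coil vs structured, and linker vs domain sites,
reporting $U$, a two-sided $p$, and the median difference signed
faster-minus-slower. With both groups of size $\le 8$ the $p$-value is an
exhaustive enumeration over rank assignments (valid under ties);
otherwise a tie-corrected normal approximation without continuity
correction. No correction is applied across the three contrasts, which
are reported separately.

The eight factor-level cells are compared by a tie-corrected
Kruskal-Wallis test and $\binom{8}{2} = 28$ post-hoc comparisons on pooled
mean ranks: pair $(i,j)$ is significant iff

$$|\bar R_i - \bar R_j| \ge z_{1-\alpha/(k(k-1))}
  \sqrt{\frac{N(N+1)}{12}\Big(\frac{1}{n_i}+\frac{1}{n_j}\Big)},$$

the published critical-difference rule for this design. The factorial
model `z_rate ~ disorder * ss * domain` is fitted with sum-to-zero
contrasts and tested with type-III (full-vs-reduced) sums of squares,
which the tests verify against explicitly constructed design-matrix
comparisons; with balanced cells type III collapses to sequential type I,
also asserted. Datasets that do not populate all eight cells get the
rank-based results with the ANOVA flagged inestimable instead of a hard
failure.

The disorder-content regression takes one point per family — $x$ the
fraction of gap-free columns labeled disordered, $y$ the mean z-rate of
its disordered-structured sites — and fits a local-linear curve with
tricube weights over the `span` fraction (default 0.75, degree 1, at
least 10 families) of nearest neighbors. The smoother is implemented
directly so that its window and kernel conventions are exactly those
stated here and testable against a hand-computed weighted least squares.

## The synthetic-family generator

The generator is the package's ground-truth instrument; its defaults are
the study conditions used by the tests and the acceptance script.

* **Tree**: pure-birth (Yule) topology grown by uniform tip splitting,
  i.i.d. exponential branch lengths rescaled so the mean root-to-tip path
  equals `tree_height`. Default height 0.6 substitutions/site: deep
  enough for rate signal, shallow enough that generated families retain
  the $\ge 30\%$ minimum pairwise identity that real input families
  satisfy by construction (they pass 40%-identity linkage upstream).
* **Architecture**: three segmental tracks with geometric lengths —
  domains (mean 60) alternating with linkers (mean 30), disordered runs
  (mean 25) alternating with ordered runs (mean 75, i.e. ~25% disorder
  content), and secondary-structure elements (H mean 10, E mean 6, C mean
  8). Element-type frequencies differ inside disordered regions
  (H/E/C = 0.10/0.05/0.85 vs 0.30/0.20/0.50 in ordered sequence): IDRs
  are predominantly coil with occasional transient elements, which keeps
  disordered-structured sites the rare class they are in real proteomes
  while guaranteeing they exist.
* **Rates**: multiplicative — site rate = class multiplier × mean-one
  gamma residual (shape 1.0), rescaled to mean exactly 1. Default
  multipliers: coil ×1.3, linker ×1.5, and a disorder effect that depends
  on secondary structure — disordered coil sites ×2.0, disordered
  structured sites ×0.5. The effects being emulated are known by
  direction, not by generative magnitude, so these values are calibrated
  only to reproduce the signs: all three marginal accelerations
  positive, and the
  disorder effect reversing inside secondary structure (the
  disordered-structured deceleration must *replace*, not stack on, the
  coil-side acceleration — stacked, the reversal would cancel
  identically).
* **Evolution**: root drawn uniform over the 20 residues, each site
  evolved independently along the tree under the same equal-exchange
  process the inference assumes. This is deliberate: recovery tests
  measure the estimator, not model misspecification.
* **Indels**: placed post hoc as deletions — geometric runs (mean 6) of
  residues in random rows replaced by `-` until the target fraction of
  gapped columns (default 0.34, leaving about two thirds of columns
  gap-free — a realistic level for eukaryotic family alignments) is
  reached exactly, trimming the last
  run; runs that would drop a row below 60% residues or create an all-gap
  column are skipped. Deletions keep the column count equal to the
  simulated site count, so every gapped column still carries its true
  rate and class. Indels are not evolved on the tree: gapped columns are
  excluded downstream, so indel realism buys nothing here.
* **Annotation noise**: per residue and track, probability
  `annotation_noise` (default 0.05, required $< 0.5$) of a discordant
  emission — disorder scores are Beta(2,2) draws scaled onto the correct
  side of the 0.4 cutoff and flipped across it; secondary structure flips
  to a uniformly chosen other state; domain boundaries get small
  geometric jitter. Any distribution on the right side of the cutoff
  would do; Beta(2,2) keeps scores away from the boundary without
  touching it.

What the generator does **not** emulate: codon-level processes,
among-branch rate variation beyond branch lengths, heterotachy,
alignment error, correlated annotation errors across related sequences
(predictor errors in real data are phylogenetically correlated, which
inflates apparent conservation of wrong labels), and any dependence of
indel placement on structure. Passing tests therefore demonstrate that
the pipeline recovers what this generative model encodes — estimator
correctness and qualitative effect directions — not that real proteomes
satisfy the model.

## Problem sizes and numerical choices

The package's own analyses use 20 families of 8–32 taxa and 300 sites
(about 6,000 sites, two thirds gap-free), a size at which the full chain
— NJ trees, per-family shape fits, labeling, statistics — completes in a
few minutes on one core while leaving every cell of the factorial design
populated. Rate-recovery checks use a single 16-taxon, 500-site family at
tree height 1.0 and shape 1.0, where the posterior-mean rates achieve
Spearman correlation around 0.9 with truth and the fitted shape lands
within [0.7, 1.4].

Numerical conventions worth knowing: likelihoods are accumulated in
linear space with per-node column rescaling and log bookkeeping;
`optimize` performs the Brent search; ties in rank statistics use
midranks with the standard variance correction; exact Mann-Whitney
two-sidedness is "at least as far from the null mean"; z-normalization
uses the population (not sample) standard deviation; NJ branch lengths
are clamped at zero; all random draws flow from a single integer seed per
family, and identical configuration plus seed reproduces byte-identical
alignments, trees, annotations and downstream tables.

## Limitations

Pooling sites as independent observations ignores phylogenetic and
within-family correlation, so reported $p$-values are anti-conservative
for real data — an acknowledged property of pooled-site designs that this
package retains deliberately. The equal-exchangeability model
discards amino-acid chemistry; it is the right instrument for measuring
replacement intensity, not for reconstructing histories. The NJ
convenience trees are not substitutes for proper tree inference on
deeply diverged families. And the acceptance checks are run at desk
scale: they establish correctness of the machinery and the direction of
effects under known truth, not proteome-scale effect magnitudes.
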