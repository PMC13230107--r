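---
title: "Comparing phage lifestyles through codon usage and genomic distance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing phage lifestyles through codon usage and genomic distance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagecub)
```

## The scientific problem

Bacteriophages of *Staphylococcus aureus* follow different lifestyles:
virulent (strictly lytic) phages, temperate phages able to lysogenise, and
prophages resident in bacterial chromosomes. These lifestyles impose
different selective regimes, and two genome-scale signatures are expected to
record them: how heterogeneous the genomes of a lifestyle group are
(recombination networks versus episodic divergence) and how strongly genes
match the host's synonymous codon preferences (translational selection
versus compositional drift). `phagecub` implements the complete analytical
machinery for such a comparison — per-gene codon-usage metrics, a combined
genomic distance over pairwise similarity tables, and a nonparametric
statistical ledger — together with a synthetic-data generator so that every
stage can be exercised and validated without any sequence downloads.

## Per-gene metrics

For every CDS the package computes gene length (`nt`), overall and
position-specific GC content (`gc`, `gc1`, `gc2`, `gc3`), the Codon
Adaptation Index (CAI, Sharp & Li) and Wright's effective number of codons
(Nc).

**GC metrics.** `gcK` is the percentage of G or C at codon position `K`
over the codons counted. Three exclusion rules apply uniformly: the
terminal stop codon is dropped (the dominant convention; a sensitivity
switch `include_terminal_stop` restores it), codons containing `N` are
excluded from numerator and denominator, and internal stop codons are
treated the same way as ambiguity codons. Without exclusions,
`gc = (gc1 + gc2 + gc3)/3` exactly; this identity is property-tested.

**CAI.** Relative adaptiveness weights are `w = f / f_max` within each
synonymous family on the reference counts; CAI is the geometric mean of
`w` over a gene's codons, computed in the log domain for numerical
stability. Stop codons and the single-codon families ATG (Met) and TGG
(Trp) are excluded — they carry no synonymous information and would bias
CAI toward 1. Zero-count reference codons receive a 0.5 pseudo-count
before normalisation (a standard remedy that keeps CAI strictly positive).

**Nc.** Per synonymous family the homozygosity estimate is
`F = (n * sum(p^2) - 1)/(n - 1)`; class averages over families with
`n >= 2` and `F > 0` enter `Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6` (standard
code: 9 two-fold, 1 three-fold, 5 four-fold, 3 six-fold families). When
the single three-fold family (Ile) is unobserved, `F3` is imputed as the
harmonic mean of `F2` and `F4`; when a two-, four- or six-fold class
average is unavailable — typical for very short genes, where codon usage
is stochastic — Nc is reported as `NA` rather than an arbitrary number,
and such genes are excluded pairwise (never listwise) from downstream
statistics with a logged count. Estimates above the theoretical maximum,
which Wright's estimator can produce on small samples, are capped at 61.

The host reference is any Kazusa-dialect or three-column TSV codon-usage
table (`read_codon_usage_table()`); RNA and DNA alphabets are both
accepted. The genetic code is fixed to the standard (bacterial) table.

## Combined genomic distance

Pairwise genome similarity arrives as directional BLAST-style records of
percent identity and query coverage. Reciprocal directions are averaged
into one unordered pair; which BLAST column encodes coverage is a
reporting decision, so the reader takes column names as parameters rather
than guessing. The distance combines divergence and alignment breadth:

$$d = \sqrt{d_{id}^2 + d_{cov}^2}, \qquad
  d_{id} = 1 - \tfrac{\%ID}{100}, \quad d_{cov} = 1 - \tfrac{\%Cov}{100}.$$

Pairs with no detectable similarity (NSS) are informative absences, not
missing data: they are pinned at the metric's theoretical maximum
$\sqrt 2 \approx 1.414$. Two complementary summaries are produced per
lifestyle group: statistics over pairs with detectable similarity only,
and statistics over all $n(n-1)/2$ pairs with NSS at $\sqrt 2$. All
quartiles use linear interpolation between order statistics (type 7) and
SD uses the $n-1$ denominator; both conventions are fixed for
reproducibility.

## The statistical ledger

All tests are two-sided at $\alpha = 0.05$.

* **Omnibus**: Kruskal–Wallis with tie correction, augmented with the
  rank effect sizes $\eta^2 = (H-k+1)/(N-k)$ and
  $\varepsilon^2 = (H-k+1)/(N-1)$, labelled negligible/small/moderate/
  large at 0.01/0.08/0.26.
* **Post-hoc**: Dunn's mean-rank contrasts with the tie term
  $\sum T/(12(N-1))$ always applied (it vanishes without ties), Bonferroni
  and Holm corrections applied to unrounded p-values; Mann–Whitney U with
  exact enumeration when $n_1 n_2 \le 400$ and no ties, otherwise the
  tie-corrected normal approximation; Cliff's $\delta$ with thresholds
  0.147/0.33/0.474 and explicit direction strings.
* **Correlations**: Spearman's $\rho$ with BH-FDR within each lifestyle,
  percentile bootstrap CIs (1,000 pair resamples by default; degenerate
  constant resamples are redrawn and counted), and partial Spearman by
  rank residualisation — rank-transform, regress ranked variables on
  ranked covariates (GC3 and overall GC), correlate residuals — with
  degrees of freedom reduced by the number of covariates. A residual
  vector that the covariates explain perfectly has no remaining rank
  signal; its partial correlation is defined as 0.
* **Two-way ranks**: Scheirer–Ray–Hare via sequential sums of squares on
  global mid-ranks, each effect referred to $\chi^2$ at its df.
* **Multivariate**: PERMANOVA and PERMDISP on z-scored metric profiles
  with Euclidean distances, 999 label permutations and
  $p = (1 + \#\{F_\pi \ge F\})/(1 + n_\pi)$. Because the distance is
  Euclidean on standardised columns, the sums of squares are computed
  directly from the data matrix (deviations from grand and group
  centroids), which is algebraically identical to the Gower-centred
  distance-matrix formulation but costs $O(np)$ instead of $O(n^2)$ per
  permutation; the equality is verified in the test suite against both a
  brute-force distance-matrix oracle and `vegan::adonis2`. Groups are
  balanced before testing by one seeded subsample per contrast (default
  cap 1,953 genes per group). PERMDISP measures distances to the group
  centroid (not the spatial median), matching the Euclidean setting.

The functional-category analyses default to per-genome medians within
each category as the unit of observation — the conservative choice that
avoids pseudo-replication of genes within genomes — with
`category_unit = "gene"` available as a toggle.

## The synthetic generator: what it emulates

`sim_config()` fixes the study conditions: three balanced lifestyle
groups of 30 genomes. The defaults encode the regimes of the motivating
comparison and are not tuning knobs:

| condition | virulent | temperate | prophage |
|---|---|---|---|
| genome size model (bp) | 14:16 mixture of 17,500 ± 600 and 135,000 ± 7,000 | 43,297 ± 1,423 | 61,021 ± 15,655 |
| GC3 target (%) | 19.8 | 28.0 | 25.8 |
| host-mix $\alpha$ | 0.90 | 0.35 | 0.50 |
| NSS rate | 0.591 | 0 | 0.055 |
| mean %ID of valid pairs | 86.89 | 83.51 | 84.62 |
| tRNAs | only $\ge$ 120 kb genomes, p = 0.56 | none | none |

Per genome, gene lengths are log-normal in codons (median 130,
`sdlog = 0.93`, minimum 21) and genes are drawn until the summed CDS
length reaches 90% of the genome size, so gene counts scale with genome
size rather than being fixed. Each codon comes from the host reference
frequencies with probability $\alpha$ and otherwise from a synonymous
draw tilted toward G/C third bases by `gc3_target`; amino-acid
composition always follows the host table, so CAI and Nc interact
realistically. The GC3 tilt acts only at third positions — GC1/GC2
emerge from amino-acid composition alone, mirroring the empirical
finding that lifestyle signal concentrates at synonymous sites.

**The synthetic host table.** No real host usage table ships with the
package (they are external resources); `host_usage_table()` builds a
deterministic synthetic stand-in with typical bacterial amino-acid
composition and one dominant A/T-ending codon per family (weight 7
against minor weights 2.0/1.2/0.8 for A/T-, C- and G-ending codons).
The dominance strength was calibrated once against the per-lifestyle Nc
and GC3 regimes the generator is meant to emulate: at the default
$\alpha$ values, 250-gene batches give mean Nc near 37/46/43 and mean
GC3 near 20/27/24.5 for virulent/temperate/prophage.

**What the generator does not emulate.** Genes are drawn independently
from a single stationary codon model, so (i) absolute CAI levels sit
roughly 0.10–0.12 below what a real host table yields at the same bias —
independent sampling cannot make a gene set simultaneously highly
concentrated (low Nc) and high-CAI the way correlated real usage does —
while orderings, dominance directions and effect-size classes are
preserved, which is what the statistical ledger consumes; (ii) there is
no mosaicism, recombination or phylogenetic correlation between genomes;
(iii) similarity tables are drawn per pair rather than from alignments,
so transitivity of genome similarity is not enforced. Passing tests
therefore validate the analytical machinery and the qualitative lifestyle
structure, not any claim about real sequence data.

## Numerical choices and degenerate inputs

* Frame-broken genes raise errors that batch processing isolates per
  gene; a batch never fails wholesale.
* An all-identical Kruskal–Wallis input returns $H = 0$, $p = 1$ rather
  than the 0/0 tie correction.
* Mann–Whitney exact enumeration is unavailable under ties; the
  tie-corrected approximation is used there regardless of sample size.
* Collinear ranked covariates in the partial correlation raise a
  rank-deficiency error; perfectly confounded variables return 0.
* PERMANOVA/PERMDISP require at least one residual degree of freedom and
  refuse single-observation groups; constant metric columns are dropped
  from the z-scoring with a warning.
* All stochastic operations (generator, bootstrap, subsampling,
  permutations) take explicit seeds and are bit-reproducible; seeds are
  recorded in the results bundle.

## Problem sizes

The default configuration produces roughly 8,000–8,500 genes across 90
genomes; a full pipeline run (generation, metrics, distances, the entire
ledger with 999 permutations and 1,000 bootstrap iterations) completes in
about two minutes on one CPU. Unit tests run on scaled-down
configurations (6–12 genomes, lighter resampling) chosen to keep the
whole suite fast while the acceptance checks exercise the full default
conditions.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 42)
res <- run_all(cfg)

# lifestyle medians of the synonymous-site metrics
s <- res$metrics$summary
s[s$metric %in% c("gc3", "cai", "nc"), c("lifestyle", "metric", "p50")]

# omnibus effects and the largest pairwise contrasts
res$stats$metric_kw
head(res$stats$pairwise)

# genomic heterogeneity with and without NSS pairs
res$distance$summary

write_results_bundle(res, "phagecub-demo")
```
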