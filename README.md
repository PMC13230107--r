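# phagecub

Codon usage bias and genomic heterogeneity across bacteriophage lifestyles.

## What it is for

Bacteriophages of *Staphylococcus aureus* fall into three lifestyles —
virulent (strictly lytic) phages, temperate phages, and chromosomal
prophages — that impose different selective regimes on their genomes.
`phagecub` provides the complete analytical toolkit for comparing such
lifestyle groups from coding sequences and pairwise genome similarity:

* **Per-gene metrics**: gene length, overall and position-specific GC
  content (%GC1/2/3), the Codon Adaptation Index (CAI; geometric mean of
  relative adaptiveness weights `w = f / f_max` against a host reference
  usage table) and Wright's effective number of codons
  (`Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6` from synonymous-family
  homozygosities; 20 = maximal bias, 61 = uniform usage).
* **Combined genomic distance (CGD)** over BLAST-style similarity tables:
  `d = sqrt((1 - %ID/100)^2 + (1 - %Cov/100)^2)`, with genome pairs
  showing *no significant similarity* (NSS) treated as informative
  absences pinned at the theoretical maximum `sqrt(2) ~ 1.414`, and dual
  heterogeneity summaries (valid-pairs-only and all-pairs).
* **A nonparametric statistical ledger**: Kruskal–Wallis with rank-based
  effect sizes (η² = (H−k+1)/(N−k), ε² = (H−k+1)/(N−1)), Dunn post-hoc
  contrasts, Mann–Whitney with Cliff's δ, Holm and Benjamini–Hochberg
  corrections, bootstrap and partial Spearman correlations,
  Scheirer–Ray–Hare, and PERMANOVA/PERMDISP on z-scored metric profiles.
* **A synthetic lifestyle-structured generator** (genome-size mixtures,
  GC3- and host-adaptation-controlled CDS, functional categories, tRNA
  gating, similarity tables with tunable NSS fractions) so the whole
  pipeline is testable end to end without downloads.

Intended users are molecular-evolution and phage-genomics researchers who
want these analyses reproducible, seeded and unit-tested rather than
assembled ad hoc.

## A worked example

```r
library(phagecub)

cfg <- sim_config(seed = 42)      # 3 lifestyles x 30 genomes, study defaults
res <- run_all(cfg)               # simulate -> metrics -> distances -> stats

s <- res$metrics$summary
s[s$metric == "gc3", c("lifestyle", "p50")]
#>    lifestyle      p50
#> 5   virulent 20.00000
#> 12 temperate 26.51515
#> 19  prophage 24.00000

res$stats$metric_kw[res$stats$metric_kw$metric == "gc3", ]
#>   metric       H df p      eta2  epsilon2 effect    N
#> 5    gc3 2687.97  2 0 0.3137815 0.3137082  large 8563

pw <- res$stats$pairwise
pw[pw$metric == "nc" & pw$group_2 == "temperate",
   c("metric", "group_1", "group_2", "cliffs_delta", "magnitude", "direction")]
#>    metric  group_1   group_2 cliffs_delta magnitude            direction
#> 13     nc virulent temperate   -0.7576255     large temperate > virulent

res$distance$summary[res$distance$summary$scope == "all_pairs",
                     c("lifestyle", "n_total", "prop_nss", "d_mean", "d_median")]
#>   lifestyle n_total   prop_nss    d_mean  d_median
#> 2  virulent     435 0.58620690 1.1411793 1.4142136
#> 4 temperate     435 0.00000000 0.7726386 0.8133513
#> 6  prophage     435 0.05287356 0.8022066 0.8170594
```

Read: third-position GC is lowest in virulent phage genes and highest in
temperate ones, lifestyle explains a large share of its rank variance
(ε² ≈ 0.31), virulent genes are far more codon-biased than temperate ones
(large negative Cliff's δ on Nc), and the virulent group owes its
heterogeneity to majority-NSS divergence (59% of pairs at the distance
ceiling) while temperate genomes form a fully connected similarity
network. `write_results_bundle(res, dir)` emits the tables as TSV plus a
`results.json` ledger with all seeds and corrections recorded.

Real data enter through the same surface: `read_fasta_cds()`,
`read_codon_usage_table()` (Kazusa or TSV dialect; a synthetic host-style
table ships in `inst/extdata/` and via `host_usage_table()`),
`read_directional_hits()` (BLAST tabular) and `read_annotation_table()`.

## Package layout

* `R/io_formats.R` — FASTA / codon-usage / BLAST-tabular / annotation IO
* `R/codon_metrics.R`, `R/host_table.R` — GC, CAI, Nc, functional classes
* `R/genome_distance.R` — pair building, CGD, heterogeneity summaries
* `R/stats_suite.R`, `R/permanova.R` — the statistical ledger
* `R/synthetic_data.R` — the lifestyle-structured generator
* `R/pipeline.R` — `run_simulate()`, `run_metrics()`, `run_distance()`,
  `run_stats()`, `run_all()`, `write_results_bundle()`
* `vignettes/phage-lifestyle-codon-usage.Rmd` — models, conventions,
  design decisions and limitations
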