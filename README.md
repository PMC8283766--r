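# exonsig

Quantification of a cassette-exon-skipping oncogene isoform from RNA-seq
splice-junction reads, and evaluation of a dual-isoform median-split
prognostic signature — with the survival statistics implemented from first
principles and simulators that make the whole pipeline testable without any
external data.

## The problem

A cassette (internal) exon can be skipped during splicing, joining the
upstream flanking exon directly to the downstream one. For a three-exon
trio E3–E4–E5 this produces two transcript isoforms distinguishable by
their splice junctions: the inclusion ("wild-type", WT) isoform supported
by E3–E4 junction reads and the skipping isoform (ΔE4) supported by E3–E5
junction reads. In breast tumors, the expression of the two isoforms of an
oncogene is strongly correlated, and a two-marker classifier — patients
low for *both* isoforms versus high for *either* — can stratify
relapse-free survival (RFS) in the Luminal subclass better than either
marker alone.

`exonsig` implements that analysis end to end:

* **Junction quantification.** For a sample's spliced alignments
  (SAM/BAM), count reads whose intron gap (`N` CIGAR operator) matches a
  junction exactly, with a minimum anchor on both sides. The skipping
  fraction is

      skip_ratio = n_E3E5 / (n_E3E4 + n_E3E5)

  (the complement of PSI for the cassette exon), and normalized gene
  expression `G` is partitioned as `de4 = skip_ratio x G`,
  `wt = (1 - skip_ratio) x G`, with exon-level scaling
  `(exon3_reads / total_reads) x G` available and a positivity call at
  `de4 >= 1000` normalized units (inclusive).

* **RT-qPCR quantification.** Standard-curve fitting (Cq vs log10 input;
  efficiency `E = 10^(-1/slope) - 1`), efficiency-corrected relative
  expression `(1+E_t)^(-Cq_t) / (1+E_r)^(-Cq_r)`, absolute copy estimates,
  and plasmid-mixture primer-specificity validation.

* **Signature.** St Gallen-style subtypes from ER/PR/HER2; per-marker
  median dichotomization (ties low); the 3-group classification
  (1 = both low, 3 = both high, 2 = discordant) and the 2-group dual
  signature (low only in group 1).

* **Survival.** Kaplan–Meier product-limit curves, the k-group log-rank
  test, Cox proportional hazards by Newton–Raphson with Efron tie handling
  (Wald CIs; monotone-likelihood cells reported N/A with a reason),
  Pearson correlation and tie-corrected Kruskal–Wallis — all written
  from first principles and cross-validated against the `survival`
  package in the test suite.

* **Simulators.** Spliced-alignment SAM files with known junction counts;
  cohorts with bivariate log-normal isoform expression (configurable
  correlation, subtype shifts), exponential relapse times with a
  signature-dependent hazard ratio and administrative censoring; qPCR
  plates with known efficiencies and Cq noise.

## Worked example

```r
library(exonsig)

gm <- example_gene_model()
sam <- tempfile(fileext = ".sam")
simulate_alignments(gm, sam, depth = 2000, skip_fraction = 0.15, seed = 42)
n_incl <- count_junction_reads(sam, gm$junction_inclusion)  # 1713
n_skip <- count_junction_reads(sam, gm$junction_skip)       # 287
isoform_expression(skip_ratio(n_incl, n_skip), norm_expr = 8000)
#>   sample_id skip_ratio wt_expr de4_expr rel_level positive
#> 1      <NA>     0.1435    6852     1148 0.1675423     TRUE

sim <- simulate_cohort(seed = 42)   # 107 tumors, rho 0.85, signature HR 5
res <- run_clinical(sim$expression, sim$clinical)
subset(res$table1, marker == "dual" & stratum %in% c("all", "Luminal"))
#>       stratum n_low n_high events logrank_p   hr ci_low ci_high
#> high3     all    44     63     45   0.00466 2.58   1.31    5.10
#> high7 Luminal    23     43     24   0.03407 3.02   1.03    8.85
res$pearson$r                                    # 0.812
concordance_fraction(res$assignments$group3)     # 0.813
```

The 2000 junction reads split 1713/287, matching the simulator's ground
truth exactly; the estimated skipping fraction 0.1435 sits within binomial
noise of the true 0.15. In the simulated cohort the dual signature carries
a significant log-rank association with RFS in the whole cohort and the
Luminal stratum (hazard ratios with 95% CIs above), the two isoforms'
expressions correlate at r = 0.81, and 81% of samples have concordant
low/low or high/high labels — the behavior the signature's construction
predicts for strongly correlated markers.

## Command line

A thin CLI wraps the main stages:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/exonsig", package = "exonsig"))')
Rscript $CLI simulate --what cohort --n 107 --seed 1 --out out/
Rscript $CLI report --expr out/expression.tsv --clinical out/clinical.tsv --out out/
Rscript $CLI quantify --samples samples.tsv --gene-model gene.json --out out/
```

Exit codes: 0 success, 2 validation error, 3 statistical failure.

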