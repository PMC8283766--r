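---
title: "Methods: cassette-exon isoform quantification and the dual-isoform prognostic signature"
author: "exonsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cassette-exon isoform quantification and the dual-isoform prognostic signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exonsig)
```

# Scope and model

`exonsig` analyses a single cassette-exon skipping event in one target
gene. Three exons E3, E4, E5 define two splice junctions sharing the donor
at the end of E3: the inclusion junction E3–E4 (wild-type isoform, WT) and
the skipping junction E3–E5 (ΔE4 isoform). The package covers four stages —
junction-read quantification, RT-qPCR quantification, signature
construction, and survival statistics — plus simulators that generate every
input with known ground truth.

# Junction quantification

## Counting rule

A read supports a junction when its CIGAR contains an `N` (intron) gap
whose reference boundaries equal the junction **exactly**, in 0-based
half-open coordinates (donor = position after the last base of E3,
acceptor = first base of the downstream exon). Inexact gaps — off by even
one base — are never counted: a fuzzy match would conflate distinct splice
events, and aligners report junction boundaries deterministically.

Tunable parameters:

* `min_anchor` (bases, default 3): minimum aligned (`M`/`=`/`X`) reference
  length immediately flanking the gap on each side. Very short overhangs
  are dominated by spurious alignments of 1–3 terminal bases; 3 is a
  conservative floor, and the simulator writes reads with ≥ 6 so that a
  stricter setting remains satisfiable.
* Record filters: primary, mapped, non-duplicate, non-supplementary
  alignments only; both orientations count (library strandedness is not
  assumed, since junction identity is orientation-free once the gap
  coordinates match).

Reading is delegated to Rsamtools/GenomicAlignments (SAM is converted to
BAM on the fly); the test suite contains an independent text-level SAM
parser that re-derives gap coordinates record by record, and the two
routes are asserted equal on dozens of simulated files.

## From counts to isoform expression

With inclusion count $n_{34}$ and skipping count $n_{35}$,

$$\mathrm{skip\_ratio} = \frac{n_{35}}{n_{34} + n_{35}},$$

the complement of percent-spliced-in (PSI) for the cassette exon. When
both counts are zero the ratio is *undefined* (`NA`), deliberately
distinct from zero: "no evidence" is not "no skipping". The direction of
the ratio was a genuinely open reading of the source analysis description;
we fixed the skipping-fraction form because it lies in $[0,1]$ and
partitions normalized expression additively (below), which the downstream
isoform quantification requires.

Gene-level normalized expression $G$ (a DESeq-style size-factor-normalized
value, accepted as input — the package does not re-implement library-size
normalization) is partitioned as

$$\mathrm{de4} = \mathrm{skip\_ratio} \cdot G,\qquad
  \mathrm{wt} = (1 - \mathrm{skip\_ratio}) \cdot G,$$

so `wt + de4 = G` holds to a relative $10^{-9}$ by construction, and this
conservation is asserted for every simulated sample. An exon-level
normalization `exon3_deseq = (exon3_reads / total_reads) * G` is provided
for the case where the gene value must be rescaled to the constitutive
exon; `total_reads` means total mapped reads (a library-size proxy) and
may be supplied externally or counted from the file.

**Positivity cutoff.** A sample is called positive for the skipping
isoform when `de4 >= 1000` normalized units. The threshold's boundary is
applied *inclusively*: the source of the convention describes 1,000 as a
minimal expression, and "minimal" naturally includes its own value. The
cutoff is a parameter everywhere it is used.

# RT-qPCR quantification

Standard curves regress Cq on $\log_{10}(\text{input})$ by ordinary least
squares; efficiency is $E = 10^{-1/\text{slope}} - 1$, so perfect doubling
corresponds to slope $-1/\log_{10} 2 \approx -3.3219$ and $E = 1$. Curves
with non-negative slope are flagged invalid and refuse quantification.

Relative expression is efficiency-corrected by default,

$$\frac{(1+E_t)^{-Cq_t}}{(1+E_r)^{-Cq_r}},$$

reducing to $2^{-\Delta Cq}$ at 100 % efficiencies (`check_eff = FALSE`
disables the plausibility window $[0.8, 1.1]$). The choice of correcting
by default reflects that validated assays report their efficiencies; the
uncorrected model is one argument away. Replicates are aggregated by the
arithmetic mean of Cq before normalization, and wells with Cq ≥ 40 are
treated as non-detected (industry convention).

Mixture validation estimates, per plasmid mixture, WT copies (E3–E4
primers), ΔE4 copies (E3–E5 primers) and total copies (E3 primers) through
their standard curves, and reports estimated/expected recovery ratios with
a pass flag at ±20 % by default. A species absent from the design must
come back below 20 % of the mixture total.

# Signature construction

* **Subtypes** from receptor status: Luminal when ER+ and/or PR+;
  HER2-enriched when ER−/PR−/HER2+; triple negative when all three are
  negative. Samples with missing status are excluded from subtype
  analyses (not from whole-cohort analyses).
* **Median dichotomization**: `high` ⇔ strictly above the median. Ties at
  the median go to `low`, so that "high" always means "above the
  cohort's middle value" — the upstream analysis tool's tie behavior is
  unstated, and this rule is the one that keeps the two groups' meaning
  asymmetric-free. With all values identical everything is `low`, with a
  warning.
* **Scope**: medians are computed on the whole cohort by default, with a
  `scope = "stratum"` switch recomputing them within each molecular
  subtype. Which scope the original analysis used is not stated; the
  whole-cohort default is the conservative choice (labels do not change
  when a stratum is re-analysed), and every report records the scope used.
* **Groups**: group 1 = both markers low, group 3 = both high, group 2
  otherwise; the dual signature is `low` exactly for group 1. The
  concordance fraction (groups 1 ∪ 3) tends to 0.5 for independent
  markers and to 1 as the correlation approaches 1 — both limits are
  checked by simulation.

# Survival statistics

All statistics are implemented in the package (the `survival` package
serves only as an independent oracle in the tests):

* **Kaplan–Meier** product-limit estimator with risk/event/censor tables.
* **Log-rank**: observed-minus-expected events over pooled risk sets with
  the hypergeometric variance; $\chi^2$ with $k-1$ df. For $k = 2$ the
  statistic is the squared standardized $O-E$; it is invariant to
  time-unit rescaling.
* **Cox proportional hazards**: Newton–Raphson maximum partial likelihood
  with the **Efron** approximation for tied event times (more accurate
  than Breslow when ties are frequent, as with rounded follow-up months).
  Wald 95 % CIs $\exp(\hat\beta \pm 1.96\,\mathrm{SE})$ and Wald p-values.
  The score test at $\beta = 0$ is also reported; on tie-free two-group
  data it equals the log-rank $\chi^2$ exactly, an identity the tests
  assert at $10^{-6}$ relative tolerance.
* **Monotone likelihood**: when one group has no events the partial
  likelihood increases monotonically in $|\beta|$ and no maximum exists.
  The fitter detects coefficient divergence (|β| > 18) or exploding
  standard errors and returns an N/A result with a human-readable reason
  instead of an arbitrary number — the survival table renders such cells
  as N/A, which is exactly how an all-censored low-expression group must
  be reported.
* **Pearson** correlation (t-test p, $n-2$ df) and **Kruskal–Wallis**
  with tie correction.

The survival report (`table1_report`) crosses markers (E3, WT, ΔE4, dual
signature) with cohort strata (all, Luminal, HER2-enriched, triple
negative): two-group log-rank p and univariate Cox HR with 95 % CI per
cell, an NS flag at $\alpha = 0.05$ carrying the raw p, and per-cell skip
or N/A reasons. Log-rank p and Cox HR/CI are reported **side by side and
not reconciled**: published tables of this shape sometimes print HR/CI
pairs whose provenance cannot be reproduced from the p-values, and the
package deliberately does not attempt to force agreement. Follow-up is
administratively truncated at a configurable horizon (default 120 months:
events beyond it become censored at the horizon), implementing a 10-year
retrospective analysis; truncation can only reduce the number of events.
No multiple-testing correction is applied across cells by default, since
the table's convention is raw p-values.

The multivariate model (`cox_multivariate`) uses simultaneous entry of
the selected covariates — no stepwise selection.

# The simulators: what they emulate, and what they do not

**Alignments** (`simulate_alignments`): `Binomial(depth, skip_fraction)`
reads span E3–E5, the rest E3–E4; each read's gap matches its junction
exactly and its offset respects a minimum anchor of 6 bases. Output is a
coordinate-sorted SAM file, byte-identical under a fixed seed. There is no
sequence-level realism — no mismatches, no quality model, no reference
FASTA — because the counting operation consumes only positions and CIGARs.

**Cohorts** (`simulate_cohort`): log-expressions of the two isoforms are
bivariate normal with correlation ρ, then exponentiated — log-normal
marginals reproduce the right-skewed, zero-bounded expression histograms
seen in junction-level data ("bins of thousands"). Defaults state the
world the package targets: n = 107 tumors split ≈ 72/15/20 across
Luminal/HER2-enriched/triple-negative; ρ = 0.85 (observed isoform
correlations in the motivating analyses were ≈ 0.89 by RNA-seq and ≈ 0.81
by RT-qPCR); the ΔE4 log-mean sits log 7 below WT (the skipping isoform is
reported 6–8-fold weaker), giving a relative ΔE4/WT level mostly between
10 % and 30 %; subtype shifts (+0.3 / 0 / −0.4 on the log scale) induce
the subtype expression differences that a Kruskal–Wallis test detects;
relapse follows an exponential with baseline hazard 0.002 events/month and
a dual-signature hazard ratio of 5, censored administratively at 120
months, yielding ≈ 20 % events in the low group over 10 years. Receptor
status is derived deterministically from the simulated subtype so subtype
assignment is exactly invertible. The true dual label is defined against
the subtype-conditional true medians $e^{\mu}$, making hazard-ratio
recovery well-defined independent of the sample median split. Not
emulated: real copy-number-driven expression, non-proportional hazards,
informative censoring, missing data patterns — so a green end-to-end test
establishes the pipeline's correctness, not the clinical claim.

**qPCR plates** (`simulate_qpcr`): Cq = intercept + slope·log10(copies) +
N(0, noise_sd), slope from the assay efficiency, zero template reported at
the detection limit (Cq 40). Dilution series and mixture wells are run in
triplicate — the standard plate design; with a single-well curve, curve
error dominates recovery error. Note that a per-well Cq noise of
0.2 cycles leaves ~2 % of wells outside a ±20 % copy-recovery band even
after triplicate averaging; recovery assertions are therefore formulated
over the distribution of wells (≥ 90 % in band), not well-by-well.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; GFF3 (1-based inclusive)
  and BED12 (0-based, block-encoded) readers normalize on input.
* `skip_ratio(0, 0)` is `NA` (undefined), never 0.
* Newton–Raphson uses step-halving to keep the partial likelihood
  non-decreasing; convergence is declared on a relative log-likelihood
  change below $10^{-9}$, divergence on $|\beta| > 18$ (hazard ratios
  beyond $e^{18}$ are indistinguishable from separation at any realistic
  n).
* Zero-variance markers dichotomize to all-`low` with a warning rather
  than erroring, so degenerate simulations propagate visibly.
* All generators are deterministic under a fixed seed; alignment output
  is byte-identical, tables value-identical.

# Known limitations

* One cassette event, one gene at a time; no genome-wide junction
  discovery or annotation-free splicing analysis.
* `gene_deseq` normalized values are inputs; the package neither aligns
  reads nor normalizes libraries.
* No time-varying covariates, competing risks, or proportional-hazards
  diagnostics beyond convergence reporting.
* The qPCR module starts at Cq values; amplification-curve processing and
  primer design are out of scope.

```{r example}
sim <- simulate_cohort(seed = 1)
res <- run_clinical(sim$expression, sim$clinical)
subset(res$table1, marker == "dual", select = -c(marker, na_reason))
```
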