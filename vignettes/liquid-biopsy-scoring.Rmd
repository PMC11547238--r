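---
title: "Liquid-biopsy scoring: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Liquid-biopsy scoring: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melanoliq)
```

`melanoliq` scores tumor-derived material in blood along four channels —
chromosome-arm aneuploidy of cell-free DNA (cfDNA), cfDNA methylation,
droplet-digital-PCR (ddPCR) variant allele fractions, and circulating tumor
cell (CTC) enumeration — and ties them to clinical covariates with a small
cohort-statistics layer. This vignette explains each model, the tunable
parameters and why their defaults are what they are, what the synthetic
cohort generator does and does not emulate, and the places where the design
was genuinely open and a choice had to be made.

## Aneuploidy scoring

A sample arrives as per-arm read counts over the 39 autosomal chromosome
arms (the acrocentric p-arms 13p/14p/15p/21p/22p carry no usable signal and
are excluded). Counts are converted to fractions, and each arm is scored
against a healthy-blood-donor (HBD) reference panel:

$$z_a = \frac{f_a - \mu_a}{\sigma_a}$$

with $\mu_a, \sigma_a$ the panel mean and sample SD (divisor $n-1$) of the
arm fraction. The genome-wide statistic is $\sum_a z_a^2$.

**Score normalization.** The raw squared sum has null expectation roughly
equal to the number of arms (~39), so a positivity threshold of 3 cannot
apply to it directly. The reported aneuploidy score is therefore the raw
sum re-expressed as a z-score against the leave-one-out raw sums of the
panel members: for each donor, the donor is removed, scored against the
remaining panel, and its squared sum recorded; the sample's score is
`(raw_sum - mean(null sums)) / sd(null sums)`. Under the null this is
centred near 0 with roughly unit scale (verified by simulation in the test
suite), which is what makes `score >= 3` a meaningful operating point. Both
the raw sum and the normalized score are reported.

**Leave-one-out everywhere.** Whenever a sample is scored against a panel
that contains it, the panel statistics are recomputed without it. With
9-20 donors, including a sample in its own reference visibly deflates its
z-scores; the leave-one-out rule removes that bias at negligible cost.

Parameters: read-depth QC threshold 90,000 mapped reads (the assay's
validated minimum; inclusive); positivity threshold 3 (inclusive); at
least 5 usable arms required for a score; zero-SD arms are excluded and
logged, never imputed. Samples failing QC are "not evaluable", never
negative.

## Methylation scoring

Input is a region-by-sample count matrix from methylation-dependent
restriction-enzyme sequencing, restricted to autosomes. The stages:

1. **Digestion QC** (`lpnpi_qc`): a library fails when fewer than 20% of
   the first 2,000,000 inspected reads pass the enzyme filter — the
   signature of failed digestion.
2. **Completeness filter**: keep regions with a nonzero count in at least
   75% of all samples *and* in all HBD controls. The wording "at least
   75% of all samples and nine HBD controls" is ambiguous about the
   denominator; both conditions are applied jointly, and the HBD condition
   can be switched off (`require_all_hbds = FALSE`). "Data" means a
   nonzero read count: a region with no reads carries no signal in this
   assay.
3. **Normalization**: counts per million per sample, then `log2(x + 1)`.
   The upstream study does not state its normalization; CPM + log2 is the
   field default for count matrices of this kind, is isolated in a single
   function (`normalize_counts`), and every downstream result is defined
   on whatever matrix that function returns, so an alternative can be
   swapped in at one place.
4. **Per-region z-scores** against the HBD panel (leave-one-out for
   donors), and squared-sum scores: genome-wide over all retained regions,
   melanoma-specific over the DMR set.
5. **DMR discovery**: two-group moderated t between HBDs and "high-ctDNA"
   patients (aneuploidy score >= 3 — patients whose cfDNA demonstrably
   carries tumor signal, so the contrast is anchored on an independent
   channel). Region-wise pooled variances are shrunk toward a prior by
   empirical Bayes: the prior degrees of freedom and prior variance are
   estimated from the ensemble of log variances by moment matching
   (solving `trigamma(d0/2) = var(log s^2) - trigamma(df/2)` with a
   Newton inversion of the trigamma function). P-values use the t
   distribution with augmented df (capped at the pooled residual df) and
   are Benjamini-Hochberg adjusted; the DMR set is `q < 0.10`. The test
   suite cross-checks the whole computation against an independent
   established implementation of the same empirical-Bayes model. With
   zero within-group variance everywhere the moderation itself keeps the
   statistic finite; a fully degenerate variance ensemble falls back to
   the ordinary t-test with a warning.
6. **Donor cutoff**: a sample is "altered" when its melanoma-specific
   score strictly exceeds the upper limit of the 95% confidence interval
   of the mean HBD score, `mean + t_{0.975, n-1} sd / sqrt(n)`, computed
   on leave-one-out donor scores. A prediction interval
   (`mean + t sd sqrt(1 + 1/n)`) is the defensible alternative if the
   cutoff is meant to bound a *new* donor's score rather than the donor
   mean; it is available as `cutoff_mode = "prediction"`. The CI of the
   mean is the default because it matches the stated definition and the
   high altered rate observed in practice, at the cost of flagging a
   donor-sized score excursion more readily.
7. **PCA** on the 50% most variable regions (variance of normalized
   values across all samples), centered per region, via SVD.

A known circularity: the HBDs serve both as the DMR-discovery control
group and as the reference for the cutoff. This mirrors the analysis the
package reproduces and is documented rather than hidden; leave-one-out
scoring removes the worst of the optimism, and a user can split donors
between the two roles by passing disjoint id sets.

## ddPCR variant allele fractions

Molecules partition over ~20,000 droplets approximately as Poisson, so a
channel with fraction $f$ of positive droplets implies
$\lambda = -\ln(1-f)$ mean copies per droplet. The VAF is
$\lambda_{mut} / (\lambda_{mut} + \lambda_{wt})$, zero when both channels
are empty. All-positive channels are a saturation error (the estimate is
unbounded; the remedy is dilution, and the error message says so).
Replicate wells are pooled by summing positives and totals before
correction, which is the maximum-likelihood combination.

Detection requires at least 3 mutant-positive droplets. This threshold is
not printed in the study; it is the field-standard limit-of-detection
convention for uniplex assays and is exposed as `min_droplets`. The
dominant mutation per patient is the detected assay with maximal VAF; a
patient with no detected assay has dominant VAF 0, the convention under
which cohort VAF ranges start at 0.

## CTC enumeration and leukapheresis recovery

The expected CTC yield of a diagnostic leukapheresis (DLA) is the
peripheral-blood concentration (count per 7.5 mL) scaled to the processed
blood volume. The product is assayed as an aliquot; the measured product
total is the aliquot concentration extrapolated to the product volume, and
recovery is measured over expected, in percent. Recovery can exceed 100%
through counting noise. Patients with zero CTCs in peripheral blood have
an undefined denominator: they are reported as not evaluable and excluded
from recovery summaries, never coded as 0%.

## Cohort statistics

Spearman (average ranks for ties, exact p for n <= 9 without ties),
Mann-Whitney (exact enumeration when the product of group sizes is <= 400
and there are no ties), and the Fisher exact test (two-sided by the
probability-mass method) are thin wrappers over the standard R
implementations; the test suite verifies each against brute-force
enumeration oracles. The sample odds ratio is reported for 2x2 tables. No
multiplicity adjustment is applied across the descriptive correlation
panel — the analysis it reproduces applies none — and the report says so
by exposing raw p-values only.

**Simon two-stage designs** are found by exhaustive search over
$(r_1, n_1, r, n)$ with $n \le 60$ by default. Operating characteristics
are exact:
$$P(\text{promising} \mid p) = \sum_{x=r_1+1}^{n_1} \binom{n_1}{x} p^x
(1-p)^{n_1-x} \, P(X_2 > r - x)$$
with $X_2 \sim \mathrm{Bin}(n-n_1, p)$. For fixed $(n_1, r_1, n)$ both the
type-I error and the power decrease in $r$, so only the smallest $r$
meeting the alpha bound needs a power check — this prunes the search to
seconds. The optimal design minimizes $E[N \mid p_0]$; the minimax design
minimizes $n$, then $E[N \mid p_0]$; remaining ties go to smaller $n_1$.
Rejection bounds are inclusive ("stop if responses $\le r_1$", "not
promising if total responses $\le r$"), the original convention. At the
melanoma operating point ($p_0 = 0.4$, $p_1 = 0.7$, $\alpha = 0.05$,
$\beta = 0.2$) the search returns $r_1/n_1 = 3/7$, $r/n = 11/20$ with
exact $\alpha = 0.0450$ and power $0.812$.

## The synthetic cohort generator

The generator's defaults are the study conditions of a 20-patient
metastatic-melanoma cohort, and they are fixed once:

- **Tumor fraction**: point mass at 0 with probability 0.1 (2/20 patients
  had no detectable mutation) plus Beta(0.45, 6) otherwise — median 0.032
  (matching the printed median dominant VAF of 3.18%) with a 99.5%
  quantile near 0.48, so cohort maxima around 0.56 are attainable. VAF is
  equated to tumor fraction, i.e. a heterozygous clonal mutation in
  otherwise copy-neutral DNA; real VAFs are additionally modulated by
  local copy number, which is deliberately not modeled.
- **Coupling**: tumor fraction and log tumor volume share a Gaussian
  copula with correlation 0.7, so blood measures correlate with
  radiological burden, as observed. LDH is baseline 164 U/L (the low end
  of the printed cohort range) plus 0.8 U/L per cm^3 of tumor volume plus
  noise; tumor volumes are log-normal with median 107 cm^3 (the printed
  cohort median).
- **Arm counts**: multinomial draws of ~500,000 reads over arm-length
  baseline proportions (a bundled GRCh38 arm table — proportional-to-
  length is the simplest defensible baseline and avoids any download),
  perturbed by 2% donor-to-donor log-normal noise. A patient's arm
  proportions mix normal and tumor DNA:
  $w_a \propto \text{baseline}_a \,[(1-tf) + tf \cdot c_a/2]$ with copy
  numbers $c_a \in \{0..4\}$ on a random quarter of the arms.
- **Methylation**: negative-binomial counts (dispersion 0.05) around
  log-normal region means, ~100 reads per region, library sizes varying
  two-fold; 200 of 5,000 regions are true DMRs whose patient means scale
  by $(1-tf) + 3\,tf$.
- **ddPCR**: ~8,000 amplifiable copies over 20,000 droplets, channel
  positives binomial with the Poisson-partition probability.
- **CTC/DLA**: blood CTC concentration log-normal, increasing in
  log1p(volume) and calibrated so that roughly a third of patients have a
  detectable count in 7.5 mL; processed volumes uniform on 2.4-6.8 L and
  product volumes on 46-121 mL (printed ranges); the product's measured
  total is a binomial thinning by a Beta(2.9, 7.1) recovery (mean 29%,
  matching the observed median CTC recovery); the semi-automated platform
  counts a 2 mL aliquot with an additional 0.5 efficiency factor, so the
  flow-cytometry count dominates it in expectation. Mononuclear-cell
  recovery is Beta(7, 3) (mean 70%).

**What the generator does not emulate.** Real region universes (38,610
regions genome-wide) and the study's specific 118-region DMR list cannot
be reproduced without its undeposited data; the generator's regions are
synthetic placeholders with random coordinates. The flow-cytometry
measurement is modeled as counting the whole product, so its detection
rate saturates near 100% in simulated cohorts, higher than the 70%
observed in practice where only an aliquot is analyzed — the recovery
arithmetic is unaffected, but simulated per-platform detection gaps are
conservative for CellSearch-vs-FCM contrasts. Recovery percentages
computed from small peripheral-blood counts are noisy and biased low when
conditioning on count >= 1 (a 1-count patient's expected yield is
overstated whenever their true concentration is below 1 per 7.5 mL);
calibration properties of the recovery operation are therefore checked in
a high-concentration regime where counting statistics are adequate. No
read-level data (FASTQ/BAM) and no survival outcomes are simulated.

## Numerical choices and degenerate inputs

- SD uses divisor $n-1$ everywhere; zero-SD arms/regions are excluded and
  recorded, never imputed.
- The trigamma inversion iterates Newton steps to relative tolerance 1e-8
  (at most 50 iterations); for arguments above 1e7 the asymptote
  $1/\sqrt{y}$ is used.
- Fisher's probability-mass summation uses the conventional 1 + 1e-7
  relative tolerance when comparing table probabilities.
- Saturated ddPCR channels, all-zero arm profiles, constant matrices for
  PCA, empty high-ctDNA selections and sub-minimal panels all raise
  descriptive errors rather than returning numbers.
- BED intervals are 0-based half-open; a file whose smallest start is 1
  triggers a warning (it *looks* 1-based) but is never silently shifted.
- Missing methylation input marks that pipeline stage skipped (as happens
  in practice when libraries fail digestion QC); the remaining stages run.

## Problem sizes used by the test suite

Simulation-backed tests run at deliberately modest sizes chosen to give
stable pass/fail behavior: null calibration of the aneuploidy score uses
200 tumor-free patients against a 20-donor panel; parameter-recovery
checks use a 50-patient cohort with tumor fractions on a [0, 0.5] grid;
DMR recovery/FDR uses 5 replicate cohorts of 5,000 regions with 200
spiked DMRs and 7 patients at tumor fraction 0.3-0.5; ddPCR round-trips
use 100 replicate wells per VAF level. These sizes are the package's
definition of its calibration experiments and are stated here so they can
be scaled up by anyone wanting tighter Monte-Carlo error.

## Known limitations

- The melanoma-specific score inherits any instability of the DMR set:
  with few high-ctDNA patients the discovered set varies between runs of
  different seeds, and scores restricted to it vary accordingly.
- The donor cutoff is estimated from nine scores; its own sampling
  variability is substantial, which is one reason both cutoff modes are
  exposed.
- The Mann-Whitney wrapper's paired-data cousin (signed-rank) is not
  provided; paired designs should use `stats::wilcox.test(paired = TRUE)`
  directly.
- Sex chromosomes are out of scope for aneuploidy scoring; arm input
  begins at counts (no alignment or amplicon processing).
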