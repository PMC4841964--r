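---
title: "Methods: copy number quantification, genotype calling and association in cnvdrop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy number quantification, genotype calling and association in cnvdrop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvdrop)
```

cnvdrop implements the analysis chain behind a bi-allelic copy number
genetic test: absolute quantification of droplet digital PCR (ddPCR)
wells, relative quantification of qPCR replicates, discretisation into
allele-pair genotypes, pedigree consistency checks, and case/control
association statistics. This vignette documents the models, the tunable
parameters, the numerical choices, and what the simulators do and do not
emulate.

## The Poisson occupancy model for ddPCR

A ddPCR well partitions restriction-digested template across `N` oil
droplets (about 13,000 accepted droplets per well in the data this
package was designed around). If template molecules land in droplets at
random, the per-droplet copy count is Poisson with mean $\lambda$, and a
droplet amplifies (is "positive") unless it received zero copies:

$$\hat\lambda = -\ln\frac{N - N^+}{N},$$

where $N^+$ is the positive droplet count. `poisson_lambda()` is exactly
this inversion. A duplex well measures the target CNV (FAM channel) and
a diploid housekeeper (VIC channel, the C7orf28b assay) on the same
droplets, and the copy number per diploid genome is the occupancy ratio

$$\widehat{CN} = 2\,\hat\lambda_t / \hat\lambda_r.$$

Template concentration per volume is never needed for this ratio: the
droplet volume (default 0.91 nL, configurable) enters only
`copies_per_microlitre()`. Changing the assumed volume cannot change a
copy number call, and a test asserts this.

**Uncertainty.** The binomial sampling variance of the positive fraction
$p$ gives $\mathrm{var}(\hat\lambda) = p/((1-p)N)$; the 95% CI of the
ratio is formed by the delta method on $\ln(\lambda_t/\lambda_r)$ with
$z = 1.96$, treating the two channels as independent. The instrument
software that produced the original study's intervals does not document
its formula, so this is the package's own choice; simulation shows the
interval covers the truth at roughly the nominal rate at default droplet
counts.

**Degenerate wells.** A channel in which every droplet is positive
carries no information about $\lambda$ (the inversion diverges), so
saturation raises a classed error rather than returning infinity —
nothing downstream could use such a call. A reference channel with zero
positives likewise raises a reference-failure error. A well below the QC
floor of accepted droplets (default 8,000, against a typical ~13,000) is
flagged `low_droplets` but not rejected: the estimate is still unbiased,
just wider. A target channel with zero positives returns `cn = 0` with a
one-sided interval from the Poisson bound on a zero count.

**Duplicate assays.** Two assays interrogate the 16.1 kb locus; their
ddPCR results are interchangeable in practice, so `merge_assay_calls()`
pools them by inverse-variance weighting and flags pairs differing by
more than 1.0 copy (`assay_discordant`) — about two standard deviations
of the inter-assay ddPCR difference reported for the original data
(0.01 ± 0.52 copies).

## Relative quantification by delta-delta-Ct

qPCR estimates copy number relative to a calibrator individual of known
diploid copy number: $\Delta Ct$ is the mean target minus mean reference
Ct within an individual, $\Delta\Delta Ct$ subtracts the calibrator, and
$\widehat{CN} = 2 \cdot E^{-\Delta\Delta Ct}$ with efficiency $E = 2$
(perfect doubling; the standard assumption of the method, configurable
only in the simulator). Replicates (quadruplicates in the study design)
are aggregated by the arithmetic mean of Ct, the standard practice. The
result's error is a composite of four reactions — target and reference
for both individuals — so the CI combines the four standard errors of
the mean in quadrature on the $\Delta\Delta Ct$ scale. Calibrator error
is therefore propagated into every sample's interval; whether the
original analysis did the same is not documented, and this is the more
conservative choice. Replicate SDs above 0.5 cycles flag
`noisy_replicates`; a replicate set of size one leaves the CI
unavailable (`no_ci`).

## Genotype calling

Both loci behave as stable bi-allelic systems: 1 or 3 copies per
chromosome at CNV_14.3 (diploid totals 2/4/6) and 1 or 5 at CNV_16.1
(totals 2/6/10). A `locus_model()` stores the allele values and derives
the totals; because each total decomposes uniquely, a called total
implies an unordered allele pair, written with the larger allele first
("5|1").

`call_genotype()` assigns the nearest class, with three guards:

* **No-call ceiling** (default 1.5 copies): an estimate further than
  this from every class is a no-call. The smallest inter-class gap at
  CNV_16.1 is 4 copies, so the midpoint sits 2 copies from each centre;
  the 1.5 ceiling stops calls comfortably before that coin-flip region.
* **Midpoint ties** are no-calls, never forced: in 327 genotyped dogs no
  off-model total was observed, so genuine ambiguity is more plausibly a
  measurement problem and should surface.
* **Confidence** is the normalised Gaussian weight of the estimate over
  the class centres, using the call's CI-derived SD
  (`(ci_high - ci_low)/3.92`); a runner-up weight above 0.2 flags
  `ambiguous`. Weights are computed on the log scale so distant classes
  underflow to zero rather than producing 0/0.

`discover_clusters()` recovers the class structure without a model:
one-dimensional k-means with deterministic, evenly spaced initial
centres, choosing k in 2..5 by mean silhouette width
(`cluster::silhouette`). Centres within 0.35 of an integer are snapped;
otherwise raw centres are reported with a warning — a deliberately
conservative snap radius, small enough that qPCR-grade noise often
refuses to snap while ddPCR-grade precision always does. Degenerate
input (all values identical) returns a single-class model with a
warning rather than an error.

## Pedigree checks

`check_mendelian()` verifies, for each offspring with both parents
genotyped, that one allele per parent can reproduce the offspring pair;
trios with a missing genotype are skipped and counted, and half-trios
(one parent genotyped) are checked against the available parent only and
reported separately, because real extended pedigrees are incomplete.

`detect_two_locus_pairs()` screens for recombinant haplotypes. The two
loci overlap on one chromosome, so alleles travel as two-locus
haplotypes; the canonical phase couples 14.3-allele-1 with 16.1-allele-5
and 3 with 1, making (2,10), (4,6) and (6,2) the consistent diploid
total pairs. The phase is inferred from the data by default — of the two
possible phasings of two bi-allelic loci, the one explaining more
individuals wins, which is the co-segregation logic by which the phase
was established in the first place — with an explicit `haplotypes`
argument to pin it. Individuals inconsistent with both canonical
haplotypes (e.g. the pair (4,2)) are flagged as recombinant carriers.

## Association statistics

Allele-level case/control tables put risk-allele versus other-allele
counts (`a,b` cases; `c,d` controls). The three statistics are:

* odds ratio $ad/bc$ with the Woolf log-scale CI;
* risk ratio $\frac{a/(a+b)}{c/(c+d)}$ with the Katz CI. This is the
  allele-carriage-frequency orientation; it was confirmed by brute force
  over the four possible 2×2 orientations as the unique one whose point
  estimate and CI jointly reproduce the published reference values;
* the two-tailed Fisher exact test by full enumeration of the
  hypergeometric support, summing point probabilities
  $\le (1+10^{-7})$ times the observed one. The tolerance keeps exact
  mathematical ties included despite floating point; probabilities come
  from `lchoose` so the enumeration is independent of
  `stats::fisher.test`, which the test suite uses as a cross-check.

Zero cells trigger the Haldane–Anscombe +0.5 correction with a flag; a
zero risk-allele count in controls leaves the risk ratio undefined
(error). The packaged count fixture (genotype and allele counts for the
age-limited disease cohort, five sub-phenotypes and the control groups)
validates two identities at every load — column sums equal the cohort
sizes, and allele rows equal `2·hom + het` — so a corrupted fixture
cannot silently feed the statistics. The published SPAID-column summary
statistics are not consistent with the same publication's printed counts
(computed OR 4.30 vs printed 4.10); the package reports what the counts
give and documents the discrepancy rather than guessing which is
correct. Amyloidosis is compared against the histopathology-confirmed
control group (C3), not the age-restricted one (C1), because amyloid
status cannot be established clinically.

## What the simulators emulate

`sim_config()` holds every tunable. The defaults describe the study
conditions the pipeline targets:

| parameter | default | meaning |
|---|---|---|
| `n_droplets_mean/sd` | 13000 / 800 | accepted droplets per well |
| `lambda_ref_mean` | $-\ln(7/13) \approx 0.619$ | reference occupancy, so ~6,000 of ~13,000 droplets are reference-positive |
| `lambda_ref_cv` | 0.10 | between-well template-load variation (lognormal, mean-preserving) |
| `ct_noise_sd` | 0.15 cycles | per-replicate Ct noise |
| `qpcr_efficiency` | 2 | doubling per cycle |
| `hap_freq` | 0.803 / 0.197 | canonical haplotype frequencies; $0.803=\sqrt{0.645}$ so the modal pair fraction matches the observed 64.5% |
| `recombination_rate` | 0.01 | per-meiosis; a placeholder — the true rate between the overlapping duplications is unknown |
| `penetrance` | 0.045 / 0.15 / 0.43 | disease probability by risk-allele dosage |

The penetrance values were solved analytically (before any test was
written) so that the expected allele-level odds ratio under
Hardy–Weinberg proportions at these haplotype frequencies is ≈ 4, the
effect size the association stage must recover. The Ct noise default was
set so that simulated qPCR lands in the qualitative regime of the
original method comparison — a continuum of estimates that clusters
poorly — without attempting to reproduce its real-data r² values, which
depend on the 196 original dogs and are not recoverable from summaries.

Both channels of a simulated well share the well's template load, so
load variation cancels in the ratio exactly as it does on the
instrument. Positive counts are binomial draws with
$p = 1 - e^{-\lambda}$ per channel; channel–channel covariation from
droplet-size variation, rain (intermediate-amplitude droplets),
fluorescence compensation and restriction-digestion efficiency are all
out of scope — input is assumed to be classified counts, as produced by
instrument software. Consequently, passing tests show the statistical
pipeline is correct under the occupancy model, not that the wet-lab
classification upstream is.

Pedigrees are outbred (each generation mates with fresh founder
spouses), founders draw haplotypes from the population frequencies, and
gametes recombine at the configured rate; true haplotypes are recorded
for oracle testing. Cohort simulation draws individuals until the case
and control quotas fill, assigns clinical signs to cases at the observed
sign mix, gives controls ages above the 60-month floor, and records the
realised allele-level odds ratio of the sample so recovery can be tested
against the cohort actually drawn, not the asymptotic effect.

Randomness uses R's global RNG stream: `set.seed()` before any simulator
makes the full output deterministic, which is the package's
reproducibility contract.

## Problem sizes used in the test suite

The suite validates parameter recovery with 1,000 wells per true copy
number in {2, 4, 6, 10} (mean within ±0.1 of truth), paired
qPCR-vs-ddPCR comparisons over 200 replicate cohorts of 60 individuals
(dispersion and silhouette ordering in ≥ 95%), ten recombination-free
four-generation pedigrees (zero violations, zero recombinant flags, and
detection of an injected incompatible genotype in each), 1,000 random
tables for the Fisher cross-check (agreement to 1e-10), and one
end-to-end cohort of 155 cases / 34 controls through wells →
quantification → genotyping → association (≥ 99% genotype recovery).
These sizes give Monte-Carlo error comfortably below each asserted
margin while keeping the default run fast.

## Known limitations

* The delta-method CI assumes independent channels and moderate
  occupancy; it degrades near saturation (where the package errors out
  anyway).
* `discover_clusters()` assumes roughly equal within-class spread; with
  strongly copy-number-dependent noise the silhouette criterion can
  merge the rare lowest class in small, noisy cohorts.
* The two-locus consistency rule only detects recombinants whose diploid
  totals leave the canonical set; a recombinant whose genotype pair is
  still expressible with canonical haplotypes is invisible to it, so
  flagged carriers are a lower bound.
* The cohort simulator models one umbrella disease with conditional
  sign rates; it does not model age-dependent penetrance, relatedness
  within the cohort, or genotyping failure.
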