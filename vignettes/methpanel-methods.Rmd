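---
title: "Methods: differential methylation testing and panel validation in methpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential methylation testing and panel validation in methpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Colorectal tumors and their precancerous lesions (conventional adenomas,
cADN, and sessile serrated lesions, SSL) carry DNA regions that are
hypermethylated relative to the patient's normal colonic mucosa (NM).
A validated catalogue of such differentially methylated regions (DMRs) —
specifically ones whose methylation does not drift upwards with normal
mucosal aging — is the raw material for non-invasive screening assays.
`methpanel` implements the complete desk-side analysis for a targeted
bisulfite sequencing validation study of such a catalogue: from
per-cytosine read counts in a few hundred kilobases of captured targets to
a top-k marker panel and its classification performance.

The package ships a synthetic cohort generator with ground truth, so the
entire pipeline — and its statistical calibration — is testable without any
sequencing data.

# Data model

Counts are held per CpG cytosine and sample: a methylated read count and a
total read count. Internal coordinates are 0-based half-open (BED-native);
Bismark-style cytosine reports are 1-based and converted only at the I/O
boundary. Cytosines on the two strands are kept as separate sites; no
CpG-dinucleotide pooling is performed (the DMR definition below counts
cytosines, and pooling would halve the granularity of the run rules).

Sites covered by fewer than `min_reads = 7` reads in *any* sample are
removed before testing — the filter is a conjunction across samples, so
the retained site set is identical for everyone. The filter is applied
once, globally; per-region levels afterwards use all retained CpGs.

# The differential methylation test

Each sample contributes two observations per CpG: its methylated count and
its unmethylated count. The expanded design therefore has `2N` rows and

* one indicator column per sample (absorbing per-sample effects),
* an intercept, patient indicators, and the tested tumor-vs-NM indicator,
  all applied to the methylated rows only.

This is the standard two-level count parameterisation for methylation
data; the patient indicators make the test paired. Batch is *not* an
additional covariate: both samples of a patient are always measured in the
same batch, so the patient factor nests batch completely.

Counts are transformed to `log2CPM = log2((c + 0.5) / (L + 1) * 1e6)`.
For the two-level structure, both observation columns of a sample share
the sample's total library size `L` (methylated + unmethylated reads
summed over all CpGs). This matters: if each column were normalised by its
own sum, the genuinely hypermethylated regions would inflate the
methylated library of tumor samples and the resulting composition shift
would load onto the tissue coefficient at *every* region, destroying null
calibration at unaffected regions. With a shared per-sample library the
normalisation offset is absorbed exactly by the sample-indicator columns.

Per CpG, ordinary least squares gives the tissue coefficient (a log2
fold change of methylated signal), the residual variance `s²`, and the
residual degrees of freedom `d = 2N − (N + P + 1)`. Variances are then
moderated empirically across CpGs with the scaled-F hyperprior: writing
`e_g = log s²_g − ψ(d_g/2) + log(d_g/2)`, the prior degrees of freedom
`d₀` solve `ψ′(d₀/2) = var(e) − mean(ψ′(d_g/2))` by monotone inverse
trigamma iteration, and the prior variance is
`s₀² = exp(mean(e) + ψ(d₀/2) − log(d₀/2))`. When the right-hand side is
non-positive the prior is infinite and `s₀²` is the plain mean of the
variances (so that identical input variances are returned unchanged).
Posterior variances are the usual shrinkage
`s̃² = (d₀ s₀² + d s²)/(d₀ + d)`; moderated t statistics are referred to a
t distribution on `d₀ + d` degrees of freedom (normal when `d₀ = ∞`).
The "robustified" variant is exposed as an optional winsorization of the
log-variance residuals (`winsor` argument, default off); the standard
moment-matching fit is the default because no outlier model is part of
the simulated data.

Two-sided p-values are used even though candidate biomarkers are
hypermethylated; the sign travels separately through the coefficient, and
the direction requirement is enforced later by the inclusion criteria.

Per region, the member CpG p-values are combined with the Simes rule
`p_region = min_i (m · p_(i) / i)`, which is valid under the positive
dependence expected of neighbouring CpGs, and the region p-values are
corrected across regions by Benjamini–Hochberg.

# DMR definition and inclusion criteria

A candidate DMR is at least three consecutive differentially methylated
cytosines (BH-adjusted per-CpG p < 0.05) with identical direction of
change, each at most 50 bp from the next. The per-CpG threshold inside
the run rule is a package choice (the region-level q threshold is defined
by the study design, the per-CpG one is not); 0.05 on the adjusted scale
keeps the run definition aligned with the region-level error rate. The
gap is measured between successive DM cytosines, not between all probed
cytosines.

A call (or, in validation mode, a predefined target region) passes the
formal inclusion criteria iff it

1. overlaps a CpG island by at least 1 bp,
2. spans at least 80 bp,
3. is hypermethylated with a tumor−NM level difference ≥ 0.5
   (coverage-weighted pooled levels, inclusive threshold), and
4. has q < 0.05 (strict).

All four flags are reported for failing calls too.

# Panel selection and validation

Patients are split into training and test sides by *whole measurement
batches*, which prevents any within-batch leakage and automatically keeps
the two samples of a patient together. Among all batch subsets whose
training patient fraction is within ±0.1 of the target, the one whose
training cADN:SSL composition is closest to the cohort's is chosen (ties
broken by a seeded draw; if the tolerance is infeasible, the closest
achievable fraction wins). Enumeration is exhaustive up to 20 batches and
randomised beyond.

The panel is the `k = 30` eligible regions with the smallest training
q-values (ties: smaller Simes p, then lexicographic region id). Each
sample's panel score is the unweighted mean of its per-region methylation
levels over the panel; regions with no coverage in a sample are dropped
from that sample's mean and counted.

The classification cutoff is trained by maximising F1 (tumor = positive)
over candidate cutoffs placed at midpoints of consecutive distinct scores,
plus the minimum score itself as a sentinel — with the inclusive decision
rule (tumor iff score ≥ cutoff) the sentinel labels every sample a tumor,
so the candidate set covers all achievable labellings. Ties prefer the
smallest cutoff (sensitivity). Youden's J and Cohen's Kappa are available
as alternative metrics; on well-separated data all three agree. A
false-negative-weighted variant was deliberately not implemented as a
default: on small training sets it degenerates (the optimum runs off to
"call everything positive"), which is exactly the known failure mode of
such weighting.

ROC curves sweep the distinct scores in descending order; the trapezoidal
AUC equals the Mann–Whitney concordance probability with ties counted
one-half, and the implementation is tested against that pair-count oracle
exactly. A baseline distribution is obtained from `n_random_sets = 100`
random panels of the same size drawn from the eligible pool.

MDS plots use arcsine-square-root transformed per-region levels
(`asin(sqrt(x))`, the variance stabiliser for proportions — the
conventional reading of "asin transformation" for levels in [0, 1]). The
distance between two samples is the root-mean-square of their `top_n =
100` largest absolute per-region differences (the region subset is chosen
per pair, so locally informative regions dominate), followed by classical
Torgerson scaling; each dimension's sign is fixed so its first nonzero
loading is positive, making plots reproducible across runs.

# The synthetic cohort generator

The generator emulates the validated study design, and its defaults *are*
the study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_patients` | 59 | one NM + one tumor sample each (118 samples) |
| `lesion_ratio` | 41/59 | fraction of tumors that are cADN |
| region classes | 990 / 17 / 22 / 47 / 20 | biomarker / cADN-only / SSL-only / negative-control / aging-specific |
| `cpgs_per_region` | 5–25 | uniform |
| `cpg_spacing` | 5–50 bp | uniform, so the ≤ 50 bp chaining rule is exercised |
| `mean_coverage`, `coverage_size` | 100×, NB size 4 | CV ≈ 0.5; deep targeted capture |
| `nm_baseline_mean` | 0.05 | NM methylation at effect regions (beta, precision 30, capped at 0.2) |
| `delta_range` | 0.5–0.75 | tumor−NM difference at biomarkers, per region |
| `lesion_delta_range` | 0.3–0.6 | cADN-only / SSL-only effect, matching lesion only |
| `negative_control_mean` | 0.7 | methylated in tumor *and* NM |
| `aging_slope` | 0.004/yr | both tissues, ages 40–80 |
| `rho` | 0.05 | beta-binomial overdispersion |
| `batch_sd` | 0.1 | per-batch logit shift |

Counts are beta-binomial over negative-binomial coverage — the standard
overdispersed model for bisulfite counts; the assay itself specifies
neither, so these are stated modelling assumptions, not measured ones.
Batch effects are mild logit shifts: strong enough that batch-aware
splitting is meaningful, weak enough not to dominate the tissue signal.
One integer seed drives every draw; the pipeline forks per-stage seeds
from it by fixed offsets, so e.g. changing the number of random panels
does not perturb the simulated cohort.

What the generator does *not* emulate: read-level artifacts (incomplete
bisulfite conversion, mapping bias), spatial correlation of methylation
beyond the shared region-level mean, copy-number effects, and
between-patient heterogeneity of effect sizes at a region. Passing tests
on this cohort therefore demonstrate the correctness and calibration of
the analysis code under its stated assumptions — not assay-level
performance on tissue.

# Numerical and degenerate-input choices

* Residual variances of exactly zero are excluded from the hyperprior
  moment fit but still shrunk; an all-zero variance vector is an error.
* `trigamma_inverse` uses the monotone Newton iteration with closed-form
  guards for arguments below 1e-6 and above 1e7.
* Regions containing no probed CpGs get missing levels and are excluded
  from region-level testing (reported once); samples missing every panel
  region are an error, named.
* Empty coverage-filter results and empty DMR call sets are legal and
  return typed empty objects.
* Region sets must be non-overlapping — panel scores average per-region
  levels and overlap would double-count reads.

# Problem sizes used by the test suite

The suite exercises the full default cohort (59 patients, 1096 regions,
~16,000 CpGs) twice — once for the end-to-end recovery checks, once to
verify byte-identical reproduction under the same seed — plus a 20-patient,
200-region null cohort for calibration (Kolmogorov–Smirnov uniformity of
per-CpG p-values, and the fraction of null regions reaching q < 0.05),
and 5,000 scaled-F simulated variances for prior-df recovery. Unit
fixtures are small handmade matrices with enumerated truth tables. The
combining and ranking primitives (Simes, BH, AUC) are checked exactly
against brute-force oracles over all permutations of 5-element vectors
and 1000 random tied score vectors.

# Known limitations

* The expanded-design OLS treats a sample's methylated and unmethylated
  observations as conditionally independent given the sample effect; true
  read-level dependence is only approximated, which is the usual trade-off
  of the two-level parameterisation.
* The aging-specific truth class is a simulation label only; the pipeline
  does not attempt to detect aging-associated regions (that requires
  tumor-free donors across an age span, a different design).
* Lesion type is not part of the tested contrast; the tissue (tumor vs
  NM) effect is tested across both lesion types, with lesion-specific
  questions left to subsetting the sample sheet.
* Discovery-mode DMR calling chains CpGs genome-wide and is intended for
  targeted panels (tens of thousands of CpGs), not whole-genome scans.
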