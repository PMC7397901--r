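---
title: "Statistical methods for spatiotemporal nucleolar proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for spatiotemporal nucleolar proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleoscope)
```

`nucleoscope` bundles the statistics needed to analyze an imaging-based map
of the nucleolar proteome: which proteins line the nucleolar rim, which are
recruited to the perichromosomal layer in mitosis, how disordered they are,
whether they are essential or prognostic, and how their localization
collapses when the MKI67 scaffold is knocked out. This vignette documents
the models behind each stage, the parameters that matter, what the
synthetic-data generators do and do not emulate, and the numerical choices
made where the procedures are conventionally underspecified.

## Disorder statistics

A disorder profile is one probability per residue in [0, 1]. The package
treats a residue as disordered iff its score is **strictly** above the
threshold (default 0.5): a score exactly at the threshold counts as
ordered. The disorder fraction divides the disordered-residue count by the
protein length. A *long disordered domain* is a maximal run of consecutive
disordered residues of length **strictly greater** than `min_len`
(default 30, so 31 residues qualify and 30 do not) — the conventional
length scale for a functional disordered domain.

Group comparisons use a Kruskal–Wallis omnibus test on the per-protein
disorder fractions followed by Dunn's (1964) pairwise z tests on mean
ranks, with the tie correction $\sum_t (t^3 - t) / (12(N-1))$ subtracted
from $N(N+1)/12$ in the variance, and Bonferroni multiplication by the
number of pairs (capped at 1). No installed package provides Dunn's test,
so it is implemented directly and verified in the test suite against
hand-computed rank tables with and without ties. The group partition is
taken exactly as passed by the caller; in the motivating analysis the
mitotic-chromosome proteins are removed from the nucleolar group first to
avoid redundancy, and proteins lacking a score profile are dropped by the
caller rather than imputed.

## Enrichment tests

`binom_test()` computes exact binomial tails through `pbinom` (accurate far
into the extreme tails) and the minimum-likelihood ("small-p") two-sided
construction, matching `stats::binom.test`, which the suite uses as an
independent cross-check together with direct summation.

`chisq_2x2()` is the Pearson statistic with **no Yates continuity
correction**. This choice is deliberate and validated: the chi-squared
p-values printed for the essentiality and prognosis contrasts
(5.3×10⁻¹⁰, 5.4×10⁻⁴, 3.0×10⁻⁸) are reproduced exactly only without the
correction. Likewise the whole-genome background tables are formed as two
independent groups (focal set vs full background, not background minus
focal); the subtractive alternative fails to reproduce the printed
3.0×10⁻⁸.

`recruitment_enrichment()` encodes the study-specific null for mitotic
recruitment: if rim and non-rim proteins of the stained target set were
equally likely to relocate to mitotic chromosomes, the rim count among the
recruited proteins would be Binomial(n recruited, rim fraction of stained).
The observed excess is tested one-tailed. Note a structural property,
surfaced by the test suite: when the recruited set is drawn *without
replacement* from the stained set, the rim count is hypergeometric, with
smaller variance than the binomial null assumes — the test is therefore
valid but conservative under that null, and its null p-values are not
uniform. The same applies to the embedding test below.

`proportion_pct()` rounds half away from zero, matching how percentages
are conventionally printed (73/150 → 49%).

## Embedding separation test

To ask whether the rim proteins form a distinct cluster in the 2D
image-feature embedding, one image is chosen uniformly at random to
represent each gene, each focal-class representative's single nearest
neighbor (Euclidean metric, self excluded) is found, and the number of
focal representatives with a focal neighbor is counted. The randomization
is repeated `n_reps = 10` times and the mean count, rounded to the nearest
integer (a binomial test needs an integer; R's `round` is used), enters an
exact two-sided binomial test against
$p_0 = (n_{focal}-1)/(n_{total}-1)$ — the probability that a uniformly
chosen *other* gene is focal-class, the self-excluded reading of "expected
from the population size". The alternative $n_{focal}/n_{total}$ is
selectable (`null = "population"`). `k = 1` neighbor is the default; ties
in distance are broken deterministically by lowest gene id, which also
makes the degenerate all-coincident configuration reproducible.

The result is invariant to translation, rotation, and uniform scaling of
the coordinates (tested). Two calibration facts matter for interpretation:
(i) with well-separated clusters at the study's sizes (27 focal of 235)
the test has essentially full power; (ii) under a label-permutation null
the p-values are **conservative, not uniform** — the count's true variance
is below binomial (labels fixed in number; neighbor indicators dependent),
and at an expected count of ~3 the two-sided exact p cannot fall below
~0.1 for any count the null plausibly reaches. The package documents this
rather than repairing it, since the procedure is fixed by convention; a
significant result is therefore trustworthy, but the test's p-values
should not be treated as uniformly distributed under the null.

## Colocalization

Segmentation of the DNA (DAPI) channel: Gaussian smoothing (`sigma`, in
pixels, default 2) → global Otsu threshold (or a fixed value) → hole
filling → removal of components below `min_area` (default 64 px) →
8-connected labeling. EBImage's labeling is 4-connective, so
diagonal-adjacent components are merged through a small graph union. A
blank image yields zero objects with a warning. "Manual selection of
mitotic nuclei" in the motivating workflow is approximated by the area
filter; no solidity or shape filter proved necessary on the synthetic
images.

Per object, the measurement region is the object mask dilated by
`dilate_radius` (default 8 px) so that perichromosomal signal adjacent to
the DNA mass is captured; radius 0 reproduces a strict nuclear-area
reading. Two metrics are computed over the region, with no intensity
thresholding: the overlap coefficient
$\sum I_1 I_2 / \sqrt{\sum I_1^2 \sum I_2^2}$ (the normalized
cross-product; Manders' M1/M2 are out of scope), defined as 0 if either
channel is all-zero in the region, and the sample Pearson correlation,
`NA` when a channel is constant. The overlap coefficient is invariant to
positive scaling of either channel; the Pearson correlation to any
positive affine rescaling. One geometric property deserves emphasis:
*growing* the measurement region dilutes the overlap coefficient (the
denominator gains protein-only rim pixels), so the coefficient is maximal
at radius 0 and non-increasing in the dilation radius — the test suite
asserts this direction. The larger default radius is kept not to maximize
overlap but to give the Pearson correlation background context on both
sides of the boundary, which is what separates the WT (positive) from the
KO (negative) phenotype.

Condition comparison uses two-sided Mann–Whitney tests per metric on
per-cell values and requires at least 3 cells per condition.

## Censored abundance and rank machinery

Copies-per-cell tokens are capped before testing: `"> 2e7"` becomes 5×10⁷
and `"< 5e2"` becomes 100 (the conventional point estimates for those
censored classes); numeric literals pass through; anything else is an
error naming the token. Proteins missing from the abundance table are
dropped, not imputed.

`mann_whitney()` uses the exact permutation distribution when
n₁ + n₂ ≤ 12 and the samples are tie-free (small enough for the suite to
verify against full enumeration of all $\binom{n_1+n_2}{n_1}$
assignments), and otherwise the normal approximation with tie correction
and, by default, continuity correction (both toggleable). At the branch
boundary the two methods agree within 0.02 absolute (the exhaustive
maximum gap at n₁ = n₂ = 6 is 0.0155); under the null the approximate
branch's p-values are uniform.

## Prognostic scan

Survival is estimated by the Kaplan–Meier product-limit estimator (via
the survival package) and two groups are compared with the standard
observed-minus-expected log-rank test with hypergeometric variance,
implemented directly so the scan can reuse a vectorized core and report
per-group observed/expected counts; it is verified against
`survival::survdiff` on random cohorts.

`scan_best_cutoff()` implements maximally separated Kaplan–Meier analysis:
candidate cutoffs are the distinct expression values at which both groups
retain at least `min_frac` (default 10%) of the cohort — unrestricted
scans produce degenerate groups — with "high" defined as expression
**strictly greater** than the cutoff, so membership is unambiguous at
observed values. The gene is prognostic when the minimum log-rank p falls
below 0.001, and unfavorable when the high group's observed events exceed
expectation at the best cutoff. Ties in p resolve to the smallest cutoff.
Genes with median expression below 1 FPKM are excluded; a constant
expression vector yields direction "none" with an `NA` p-value.

The reported minimum is **deliberately unadjusted** for the multiplicity
of the scan, as in the Pathology Atlas convention the procedure follows.
The test suite demonstrates the consequence: under a null hazard ratio of
1, far more than 0.1% of cohorts yield min p < 0.001-level signals at
conventional thresholds. Users should treat the scan as a screening
statistic, not a calibrated test.

## The synthetic-data module

Every input modality has a seeded generator, configured through
`synthetic_config()`. A single master seed fans out to per-stream
sub-seeds by fixed offsets, so all streams are jointly reproducible and
bit-identical under reruns; `gen_mitotic_image_pair()` takes an explicit
per-image seed for building cohorts. Defaults are the study conditions:
73 rim / 77 non-rim stained proteins with recruitment probabilities 49/73
and 16/77 (late fraction 19/65); planted disorder medians 0.14 (cytosol),
0.20 (nucleoli), 0.31 (rim), 0.36 (mitotic); 27 rim vs 208 nucleoli
embedding genes with unit-covariance clusters 8 units apart; a hazard
ratio of 3 above an expression cutoff of 4.5 FPKM with 30% uniform
censoring; and a +0.5 natural-log shift of rim copies per cell with
censor thresholds 2×10⁷ / 5×10².

Disorder profiles draw a per-protein target fraction from a Beta
distribution whose *median* equals the group target (the shape is solved
numerically for a fixed concentration), then realize residue states with
a two-state Markov chain with stationary disorder probability equal to
the target and mean disordered run length `disorder_run_mean`
(default 20 residues), so >30-residue domains occur at realistic rates
rather than degenerating as they would under i.i.d. residues. Disordered
residues receive scores uniform on (0.5, 1), ordered residues uniform on
(0, 0.5); a score of exactly 0.5 never occurs, keeping the strict
threshold rule unambiguous. Two dispersion choices are calibrated to the
estimation problem the module exists to exercise: protein lengths are
uniform on 300–2500 residues and the Beta concentration defaults to 80,
which together keep the per-protein fraction s.d. near 0.09. That is the
level at which a group median is estimable to ±0.03 at the smallest group
size used (n = 65: the median's standard error is ≈ 1.25·sd/√n ≈ 0.014,
so ±0.03 is a ≥2σ band). Real disorder-fraction distributions are
considerably wider; the generator trades that realism for a sharp
parameter-recovery surface, and conclusions about real data should not
lean on the dispersion.

Mitotic images are built on a mask of 1–4 random ellipses (a condensed
metaphase-plate stand-in) at intensity 1. The WT protein channel is a
perichromosomal band along the mask boundary — full intensity on the
inner part (within `rim_erosion` = 5 px inside), 0.4 on the outer part
(within `rim_band_width` = 5 px outside). The asymmetry is a projection
argument: a 3D shell around the chromosome mass projects signal over the
chromosome area, so the in-mask part of the band dominates; it is also
what makes the WT phenotype quantitatively sensible (overlap > 0.6,
positive Pearson at zero noise), which a symmetric binary band cannot
achieve. The KO channel places Gaussian aggregates centered just outside
but adjacent to the mask — each aggregate center is off the DNA mass, so
KO overlap is low and the in-region correlation negative. Poisson-like
shot noise (photon count `shot_scale`) and Gaussian read noise are
applied when `noise_sd > 0`; zero disables all noise and yields the clean
geometric constructions the unit tests verify. The generator does not
simulate a microscope PSF, 3D stacks, cell-to-cell intensity variation,
or interphase/apoptotic bystander cells.

Survival cohorts use log-normal expression and exponential event times
with hazard $h_0 \cdot HR^{\mathbf{1}[x > c^*]}$; censoring times are
uniform on $(0, \tau)$ with $\tau$ solved numerically so the expected
censored fraction matches the configuration. Embedding clusters are
Gaussian with per-class means and covariances (singular covariances are
rejected), and each gene owns $1 + \mathrm{Poisson}(\lambda)$ images.

## What the tests do and do not show

The suite verifies three kinds of claims: exact reproduction of printed
enrichment statistics from the study's counts; agreement of every core
statistic with an independent oracle (per-residue scans, full permutation
enumeration, direct summation, hand-computed rank and risk-set tables,
`survdiff`, `chisq.test`, `binom.test`); and end-to-end recovery of every
planted effect at the study's sample sizes (disorder medians within
±0.03 with all reported contrasts significant, full power of the
embedding test, the WT/KO colocalization signature, and recovery of the
planted prognostic cutoff and direction, each across 100 seeds). Passing
these establishes that the implementations compute what they claim and
can detect effects of the planted size at the study's n — not that the
study's raw data would reproduce its numbers, which requires the original
images, sequences, and cohorts. Known honest gaps: the nearest-neighbor
binomial and the recruitment binomial are conservative under their
respective resampling nulls (see above), and the maximal-selection scan
inflates the null rate by construction.
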