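---
title: "Methods: the splicing-response pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the splicing-response pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliosplice)
```

`gliosplice` implements the computational stages that connect splicing
disruption by PRMT5 inhibitors to drug response in glioblastoma stem cell
(GSC) lines: filtering and consolidating alternative splicing events
(ASEs), PSI quantification from RT-PCR amplicons, dose–response scoring,
a baseline splicing signature of responder status, proteome depletion
enrichment, and single-hit limiting-dilution analysis. This vignette
records the models behind each stage, the parameters that matter, the
numerical choices made where the method description left room, and what
the synthetic-data generators do and do not emulate.

## ASE filtering and consolidation

An event is significant when all five clauses hold, each inclusive:
p ≤ `p_max` (0.05), inclusion reads ≥ 1, exclusion reads ≥ 1, total reads
≥ 10, and |ΔPSI| ≥ 0.10 with ΔPSI = PSI(treated) − PSI(control). The ΔPSI
clause is applied to the *absolute* value: both preferential-inclusion
(ΔPSI > 0) and preferential-exclusion (ΔPSI < 0) events are biology the
downstream analysis needs (the direction-vs-disruption test and the
included/excluded proteome gene sets both depend on keeping the two
signs), so a signed-only filter would silently discard half of it.

Events from different samples are the *same* event when they lie on the
same chromosome and strand, have the same event class, and their
0-based half-open intervals overlap reciprocally by at least
`min_reciprocal_overlap` (0.95) — the `bedtools intersect -f 0.95 -r -s`
convention. Class identity is required on top of coordinates because a
cassette exon and a retained intron sharing an interval are distinct
biology. Consolidation keeps events matched in *all* samples; the
representative record comes from the first table in input order (a
documented, deterministic choice), with each sample's ΔPSI and matched
event id carried alongside. When several candidates qualify, the pair
with the largest minimum reciprocal fraction wins, ties broken by event
id. Whether cross-sample identity should additionally demand an equal
ΔPSI sign is not specified by the filtering rules; we do not require it,
and the per-sample ΔPSI columns leave the question auditable.

Protein impact is predicted from transcript models by
complete-inclusion/complete-exclusion mapping: a retained intron maps
when some transcript carries the segment entirely within one exon; a
cassette exon maps when some transcript excludes it completely (no exon
overlap, inside the transcript span) while a canonical transcript
carries it inside an exon. Mapped events with length ≢ 0 (mod 3) are
frameshifts; in-frame segments are scanned for stop codons in the frame
fixed by the mapping transcript's coding start (the only well-defined
frame available); unmapped events are `unknown`. The
direction-vs-disruption association uses a two-sided Fisher test by
default — the sidedness of the reported test is not stated, so the
conservative choice is the default and one-sided is an argument. A 2×2
table with a zero margin has no defined association; we return p = 1
with a warning rather than an error, since degenerate tables arise
legitimately in small synthetic cohorts.

## RT-PCR PSI

For each assay (primer pair), the long and short isoforms are the two
amplicon sizes with the largest concentration totals *summed over all
samples of that assay*, not per sample: a sample in which one isoform
vanishes must still report PSI 0 or 1 rather than promote a noise peak.
Ties between candidate sizes prefer the larger amplicon (deterministic,
documented). PSI = L/(L+S) on the fraction scale; percentages are
presentation only. A sample with zero total isoform concentration yields
a missing PSI and affects nothing else; `compute_psi` itself treats L+S=0
as an error so silent 0/0s cannot propagate.

## Dose–response scoring

Readout time is the 95th percentile (nearest-rank) of the times DMSO
control wells take to reach 100% confluence, snapped to the nearest
observed timepoint at or before — late enough for full drug effect,
early enough to avoid saturation. The quantile definition is
nearest-rank because the source procedure does not specify one;
nearest-rank always returns an observed time. Responses are normalized
to the DMSO mean and clipped to [0, 1] (clipping flagged), which keeps
the AAC on its printed 0–1 scale when wells outgrow the control.

AAC is the trapezoidal integral of (1 − response) over log10 dose on the
observed points, divided by the tested log-range. The upstream tooling
delegates AAC to a pharmacogenomics package without printing a formula;
observed-point trapezoid over the normalized log range is the standard
normalized-AAC construction and is what the package contracts to. It is
exact on the reference shapes: 0 for a flat-at-control curve, 1 for
complete kill, 0.5 for a log-linear decline.

EC50 comes from least-squares fits of
`response = e_inf + (1 − e_inf) / (1 + (dose/ec50)^hill)` with the top
fixed at 1 (responses are control-normalized; freeing the top is not
identifiable from nine doses). Bounds: `e_inf` ∈ [0, 1], `hill` ∈
[0.1, 10], EC50 within [d_min/10, d_max·10] fitted on the log10 scale.
The optimizer is Levenberg–Marquardt (`minpack.lm::nls.lm`) with a
multi-start over candidate EC50s at every observed dose plus the dose
nearest half-maximal response, keeping the lowest-RSS fit — single
starts near the dose-ladder edge can present a singular Jacobian. An
EC50 is reported undefined when the curve is flat (response range
< 0.1), when the fit pins at the upper dose bound (censored, not
estimated), or on optimizer failure. Sensitivity is EC50 < 250 nM
(configurable). The good/poor responder split defaults to the
per-compound cohort median AAC: the cutoff behind the reported
19-good/12-poor split is unstated, so the threshold is an argument, and
with all AACs equal the ≥-median rule labels everyone good (documented
degenerate case).

## The baseline splicing signature

Three criteria select signature events from a baseline PSI matrix with
good/poor labels: quantifiability (non-missing PSI) in ≥ 75% of samples
*overall* — whether the original 75% was per group or overall is
unstated, and overall is the stricter reading under unbalanced groups;
intra-group variation smaller than inter-group variation, both as
standard deviations; and |mean difference| ≥ 0.20 on the fraction scale.
The variance comparison needed an estimator choice: intra is the root of
the average within-group variance and inter is the sd of the two group
means (= |Δmean|/√2 for two groups); both quantities are columns of the
output so the criterion is auditable against any alternative reading.
Events with fewer than two quantified samples in a group cannot be
assessed and are skipped with a recorded reason. "Top" events are ranked
by |dPSI| — the original ranking key is unstated, so the key is an
argument. The signature score of a new sample is the mean of
`sign(dpsi) · (psi − midpoint)` over quantified signature events;
positive predicts a good responder.

## Proteome enrichment and the GSEA statistic

Undetected proteins enter at log2FC = 0 (the stated convention), then
proteins sort ascending with gene-id tie-breaks. Enrichment of a gene
set among the top-k most downregulated reports fold = k/(n·K/N) and a
one-sided hypergeometric upper-tail p. Sidedness is fixed at one-sided
enrichment because that construction reproduces the printed example at
the study margins (N = 5355, K = 194, n = 50, k = 12 → fold 6.6,
p = 1.3e-7), which both the test suite and `scripts/acceptance.R`
recompute. The bootstrap SE resamples whole protein rows with
replacement (the natural exchangeable unit; the resampling unit was not
printed), re-ranks, and takes the sd of the fold over B = 100 resamples.
The GSEA ranking statistic is sign(LFC)·(−log10 adj p); infinite scores
from adj p = 0 become sign(LFC)·(max |finite| + u), u ~ Uniform(0,1)
seeded, keeping them above all finite scores yet distinct.

## Limiting dilution

The single-hit model — one active cell suffices to form a sphere — gives
P(negative well | d cells) = exp(−f·d), equivalently a binomial GLM on
well positivity with complementary log-log link and log(dose) offset
whose intercept is log f. Confidence intervals are Wald on log f,
exponentiated (the construction used by the standard ELDA software);
saturated doses participate through the likelihood with no continuity
correction. Frequency inequality between arms is a likelihood-ratio
chi-square with (arms − 1) df; single-hit adequacy frees the slope on
log(dose) and Wald-tests slope = 1. Frequencies are reported both as f
and "1 in 1/f cells", and a treated/control ratio is exposed as percent
relative change in sphere-forming capacity.

## Synthetic data: what it emulates, what it does not

The generators produce every input shape with planted truth under the
study conditions: three-sample ASE tables whose planted shared events
pass all filters with |ΔPSI| ≥ 0.10 and identical coordinates (background
p-values uniform, planted p-values Beta-concentrated near 0 — the
standard p-value mixture; background coordinates live on per-sample
offset grids so spurious 95% reciprocal matches cannot occur); baseline
PSI cohorts of 19 good and 12 poor lines with 45 signature events split
29 positive / 16 negative, group separation `delta` = 0.3, within-group
Gaussian noise sd 0.05 clipped to [0, 1], 10% missingness; nine-dose
half-log response curves (3 nM–30 µM) with Gaussian noise; a 5355-protein
universe with a 194-gene set and a shifted depleted fraction; the printed
ten-step dilution series (2000 … 4 cells/well, the odd values kept as
printed rather than exact halving) with six Bernoulli wells per dose; and
amplicon tables with noise peaks below 10% of total. Everything is
deterministic given `seed`.

Deliberately not emulated: read-level RNA-seq (so MATS/IRFinder p-values
are inputs, not outputs), electropherogram traces, image-based
confluence, batch and plate effects, and correlated missingness.
Passing recovery tests therefore demonstrates that the pipeline computes
its contracts correctly and recovers planted structure under idealized
noise — not that real cohorts meet these noise assumptions.

## Numerical choices and test scale

Discrete test calibration: the hypergeometric enrichment p has atoms
with mass ≈ 0.26 at the study margins, so a raw Kolmogorov–Smirnov test
against Uniform(0,1) would reject for *any* exactly calibrated discrete
test. Null-calibration checks therefore apply the randomized probability
integral transform — `P(X < k) + U·P(X = k)` is exactly Uniform(0,1)
under the null — which tests precisely the calibration property.

Suite problem sizes are chosen to make the statistical checks sharp yet
quick: filter-oracle equivalence on 10,000 random events; hypergeometric
oracle on 200 random instances with N ≤ 2000 against direct binomial-
coefficient tail summation; signature recovery over 50 planted cohorts
(mean recall ≥ 0.95, FPR ≤ 0.01); null calibration over 200 seeds; CI
coverage over 500 limiting-dilution simulations (93–97% band); EC50
recovery over 100 noisy curves (median within ±25%).

Other conventions: coordinates are 0-based half-open internally, with
dialect readers converting on input; all thresholds live in one flat
config (`default_config()`), overridable per call and from CLI flags;
every stochastic function takes an explicit `seed`.

## Known limitations

- Impact classification uses supplied transcript models only; there is
  no external database lookup, and MXE/A3SS/A5SS mapping falls back to
  the generic containment/exclusion rule rather than class-specific
  logic.
- The exact 2×2 construction behind the reported direction-vs-disruption
  p-value is not fully specified upstream; the implemented table
  (direction × disruption) is one faithful reading and is not expected
  to reproduce that printed p.
- Wald intervals on log f are slightly anti-conservative at extreme
  designs (few informative doses); profile-likelihood intervals are not
  implemented.
- The responder split threshold is a modelling choice (median AAC), not
  a recovered constant.
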