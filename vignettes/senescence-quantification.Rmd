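---
title: "Label-free quantification of hMSC senescence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free quantification of hMSC senescence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senospec)
```

## The problem

Human mesenchymal stromal cells (hMSCs) are expanded in vitro for cell
therapy, and replicatively senescent cells accumulate over passages,
degrading potency. The standard senescence readout — histochemical
senescence-associated β-galactosidase (SA-β-gal) staining — is destructive:
the assayed cells are lost. This package implements and benchmarks
non-destructive alternatives:

* **autofluorescence microspectroscopy**: a per-cell emission spectrum,
  acquired label-free, is decomposed into contributions from endogenous
  fluorophores — free NADH, protein-bound NADH, FAD, and lipopigments
  (lipofuscin and lipofuscin-like granules that accumulate in
  non-proliferating cells);
* **flow cytometry**: forward scatter (FSC, a cell-size proxy; senescent
  cells enlarge) and fluorogenic C12FDG detection of SA-β-gal activity on
  the FL1 channel.

Candidate metrics are benchmarked against the β-gal standard with per-donor
fold differences, one-tailed Welch tests and Spearman correlations.

## The spectral unmixing model

Each corrected cell spectrum $I(\lambda)$ over 400–850 nm is modelled as a
non-negative linear mixture of unit-peak component shapes $S_k(\lambda)$:

$$ I(\lambda) = \sum_{k} a_k\, S_k(\lambda) + \varepsilon(\lambda),
   \qquad a_k \ge 0 . $$

`unmix()` solves the non-negative least-squares problem with a
Lawson–Hanson active-set solver written in the package (the non-negativity
constraint is central: emission contributions cannot be negative, and an
unconstrained fit of overlapping components routinely goes negative).
From the fit we tabulate, per cell: the coefficient $a_k$, the peak of
$a_k S_k(\lambda)$, the trapezoidal integral of $a_k S_k(\lambda)$ over the
domain ("sum of intensities under the peak"), and the total
autofluorescence. Two conventions for the total are exposed: the default
integrates the corrected spectrum itself (model-free), the alternative sums
the per-component integrals; they differ only by the integrated residual.

Component shapes are sums of at most three Gaussians in wavelength —
smooth, positive, few parameters, and a standard emission-shape
parameterisation. The built-in simulation ground truth
(`default_library()`) places free NADH at 468 nm (sd 65 nm), bound NADH at
432 nm (sd 36 nm) — protein binding blue-shifts *and narrows* NADH emission,
and representing that narrowing matters because two nearly identical broad
Gaussians 20 nm apart would be almost collinear, which no usable instrument
library is — FAD at 525 nm (sd 40 nm), and a broad lipopigment band
(Gaussians at 560 and 640 nm) spanning roughly 450–700 nm with a red tail.

## Preprocessing

`preprocess()` conditions a measured spectrum in a fixed order: subtract the
pointwise mean of the background spectra (five measurements of imaging
solution per coverslip is the emulated protocol), crop to the 400–850 nm
analysis window, smooth, clip negatives to zero. The smoother is
Savitzky–Golay with an 11-point window and order 3 at the 1 nm grid
resolution: it preserves peak height and width far better than a moving
average. Smoothing can be disabled (`smooth = FALSE`) for already-clean
synthetic input; the noiseless identity tests use that path because any
filter perturbs an exact mixture at the $10^{-5}$ level. Resampling onto a
common grid is linear; extrapolation beyond a measured range is refused
rather than zero-filled.

## Library training

The three solution-trainable components are fitted by `fit_component()`:
replicate reference spectra are background-corrected, averaged, smoothed,
clipped, then least-squares fitted with up to three Gaussian terms
(Levenberg–Marquardt, greedy residual-peak initialisation, amplitude and
width bounds) and unit-peak normalized. The fit is invariant to uniform
intensity scaling and records its R² in the component provenance.

Lipopigment has no reference solution; `learn_residual_component()`
estimates it from senescent cells. The starting point is the classical
residual approach: unmix each senescent spectrum against the
three trained components, average the per-wavelength residuals, floor at
zero, smooth. That one-shot estimate is biased: the three-component fit
absorbs whatever part of the lipopigment band overlaps NADH/FAD, and in
fact the problem is structurally non-identifiable — for any candidate shape
$s$, every $s - S_3\gamma$ with $\gamma \ge 0$ fits noiseless data exactly
after compensating coefficient shifts. The package therefore adds
alternating refinement with an explicit identifying assumption:

1. re-unmix every spectrum against the three known shapes plus the current
   estimate;
2. re-solve the shape per wavelength by least squares given the
   coefficients;
3. regress each known component's apparent abundance on the learned
   component's abundance across cells and subtract the fitted admixture —
   absorbed flank signal manifests as exactly such a correlation.

Step 3 assumes lipopigment content varies from cell to cell independently
of the metabolic cofactors. Senescent cultures provide that variation:
lipofuscin accumulation is highly heterogeneous (the generator uses a CV of
0.5 for training cells, against 0.15 for the other fluorophores). When the
learned component's abundance is constant across training cells the
admixture is provably unrecoverable; the implementation then skips step 3
and returns the (biased) residual shape rather than failing. If the three
components already explain the spectra — the mean residual never exceeds
1% of the mean signal peak (`detect_tol`) — the function raises
`"no residual component detectable"` instead of inventing a component.

Libraries persist as versioned JSON with 17-significant-digit numbers, so a
save/load round trip reproduces every parameter exactly; unknown versions,
duplicate names, and non-positive widths are load errors.

## Flow cytometry and growth bookkeeping

Debris is excluded by a single forward-scatter threshold gate
(`gate_debris()`), the simplest gate consistent with "debris excluded by
gates"; the threshold is an explicit argument everywhere (default
`2e4` a.u. in `analyze_cohort()`, between the simulated debris and cell
populations — on real data it should come from an unstained control).
Channel summaries are arithmetic means on the linear scale, since channel
means are what get reported. Gating is idempotent and never modifies its
input sample. FCS files are out of scope; the canonical dialect is a plain
`FSC,FL1` CSV, with instrument-style `FSC-A`/`FL1-A` headers remapped.

Growth records yield per-passage population doublings
$\mathrm{PD} = \log_2(\text{harvested}/\text{seeded})$ and their cumulative
sum. Two early/senescent conventions circulate; the implemented defaults
are: **E** is the passage whose cumulative PD is closest to 6 (ties to the
earlier passage), and **S** is the first passage with less than 1 PD in 7
days, i.e. `pd_rate < 1/7` per day. The alternative arrest rule — failure
to double in two weeks, `pd_rate < 1/14` — is selectable
(`senescent_rule = "no_doubling_14d"`). "Days" are the per-passage days in
culture recorded in the growth table (calendar gaps between passages are
not modelled). β-gal positive percentages warn when fewer than 200 cells
were counted, reflecting the assay's counting rule.

## The benchmarking layer

For each metric and donor the effect size is the fold difference
$\bar{x}_S/\bar{x}_E$ of sample means; reversed effects (fold < 1) are
reported, not suppressed. Group comparisons use the one-tailed
unequal-variance Welch test with the direction fixed a priori as
senescent > early for every metric — a reversed effect therefore lands at
$p > 0.5$ and "ns". Stars follow the usual mapping (≤ 0.001 `***`,
≤ 0.01 `**`, ≤ 0.05 `*`), with boundary values included by the ≤
convention. Sample standard deviations (n−1) are used throughout, and no
multiple-testing correction is applied — the layer mirrors how such
benchmark panels are conventionally reported, donor by donor.

Each metric is correlated against the β-gal standard by Spearman's rank
correlation over the per-(donor, passage) sample means — with six donors
that is 12 points, early and senescent jointly. Correlating summary means
rather than pooled per-cell values is deliberate: the metrics live on
different per-cell sampling units (10 spectra vs 10⁵ events vs one stained
well). For $n \le 9$ the permutation distribution is enumerated exactly
(the $t$ approximation is poor there); the p-value is two-sided, the more
conservative choice where sidedness is not pinned down. Constant inputs
flag the correlation as undefined rather than returning a spurious value.

## The synthetic cohort generator

`simulate_cohort()` emulates the study's data-generating structure, not its
raw data (which is not published): per donor, E and S spectra sets (10
cells each, five backgrounds per group), E and S flow samples (10⁵ events,
5% debris), one β-gal well per passage (300 cells counted), and a
multi-passage growth record; plus a shared library-training set (three
reference solutions × 3 replicates, 50 senescent cells). Key defaults and
their reasoning:

* **abundances**: E = (1.0, 0.8, 0.6, 0.5) for (NADH_free, NADH_bound,
  FAD, lipopigment); S doubles lipopigment and raises the metabolic
  fluorophores 1.4-fold, so the total autofluorescence fold (~1.5) sits
  inside the range such cohorts report while the lipopigment shift (2.0)
  is the configured recovery target;
* **per-cell abundance CV 0.15** (lognormal), a moderate biological
  variability; training senescent cells use CV 0.5 for lipopigment (see
  above);
* **flow**: lognormal channels (scatter/fluorescence intensities are
  right-skewed positive), FSC median 5×10⁴ → 6.5×10⁴ (×1.3), C12FDG/FL1
  median ×3, σ = 0.25/0.35;
* **β-gal**: binomial counts with p = 0.10 (E) → 0.60 (S);
* **donor heterogeneity**: lognormal per-donor factors (CV 0.15 on
  spectral brightness, 0.05 on flow medians, 0.25 logit-sd on staining
  probabilities) applied to E and S alike, so configured S/E folds are
  preserved; they are kept modest so the group shifts dominate donor
  effects;
* **noise**: additive Gaussian at 1% of each spectrum's peak; background is
  a smooth low-amplitude curve plus noise;
* **growth**: doubling rate 0.45 PD/day decaying geometrically by 0.82 per
  passage over 12 weekly passages, which crosses the 1-PD-in-7-days arrest
  threshold around passage 7 with cumulative PD near 6 at passage 2.

Every dataset is reproducible byte-for-byte from `rng_seed`, and a truth
record (realized per-cell abundances, per-donor fold differences, staining
probabilities) is emitted alongside so parameter-recovery tests compare
pipeline output against what was actually simulated.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: optics and spectrometer response,
photobleaching, spectral calibration drift, autofluorescence from media or
substrate beyond a smooth background, compensation and multi-marker gating,
correlated abundances (e.g. a common cell-size factor linking all
fluorophores), non-Gaussian measurement noise, and counting error in β-gal
scoring. The component shapes themselves are synthetic stand-ins with
defensible parameters, not measured instrument spectra.

## Numerical choices

* NNLS tolerance: `10 · eps · max|A| · max(m, k)`; at most `30k` active-set
  iterations. On noiseless mixtures the residual is at the
  $10^{-15}$ level.
* Gaussian-sum fitting stops adding terms at uncentered R² ≥ 0.9999; each
  Levenberg–Marquardt refit is bounded (amplitude ≥ 0, width ≥ half a grid
  step) and a failed refit falls back to its initialisation.
* R² of an unmixing fit is uncentered (fraction of raw signal energy
  explained), which for NNLS is guaranteed to lie in [0, 1]; it is `NA`
  for an all-zero spectrum.
* Sample sd of a single observation is defined as 0 by convention.
* Degenerate Welch inputs (both groups constant) return t = 0, p = 0.5 on
  equal means and p ∈ {0, 1} otherwise.
* The cPD tie |cPD−6| is broken to the earlier passage by taking the first
  minimum.

## Problem sizes in the test suite

The suite runs the full pipeline on the default six-donor cohort (120
spectra, 1.2×10⁶ flow events, library trained from scratch), 100-spectrum
recovery batches, a 10,000-replicate null calibration of the Welch test at
n = 10 per group, and exact permutation enumeration up to n = 6 against a
brute-force oracle; these sizes keep the whole suite under a minute while
leaving the Monte-Carlo margins comfortably wider than the assertion
tolerances.

## Known limitations

* The residual-learning identifiability fix relies on independent
  cell-to-cell lipopigment variation; strongly correlated fluorophore
  abundances would re-introduce bias toward the known components.
* Per-measurement (not per-cell) averaging: if multiple spectra per cell
  exist they count as independent observations.
* The single-threshold debris gate is a deliberate simplification; no
  automated gate placement is attempted.
* Spearman p-values for n > 9 use the t approximation, adequate at the
  12-point scale used here but approximate.
* Fold differences require a positive early-passage mean; metrics that can
  legitimately average to zero should not be benchmarked as ratios.
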