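---
title: "Methods: quantifying and modelling axon myelination patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and modelling axon myelination patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myelotrace)
```

## The measurement problem

Cortical myelin is discontinuous. Along a single traced axon, myelin
appears as a sequence of internodes — sheaths laid down by individual
oligodendrocyte processes — separated by short nodes of Ranvier and,
in the cortex, by much longer stretches of bare axon. Three questions
drive the analyses in this package: how much of each axon is covered
(and how is that coverage arranged); what determines which axons get
selected for myelination; and how faithfully the pattern on each axon is
restored when myelin regenerates after demyelination.

The package operates downstream of tracing. Axons arrive as SWC
polyline trees (coordinates in μm); myelin arrives as arc-length
intervals `[s_start, s_end)` on named branches. Storing myelin as
intervals on the axon's own arc length — rather than as independently
traced 3D polylines — makes the coverage geometry exact: the classical
artifact in which independently traced sheaths sum to more than the axon
they cover is then something we *emulate* (via the generator's jitter
option) rather than something we inherit uncontrolled from the data
representation.

## Coverage metrics

**Smoothing.** Manual traces are jagged, which inflates length. Before
any length computation every branch is smoothed with a centred moving
average (default window: 3 points) whose window shrinks symmetrically at
the ends, so endpoints are preserved exactly. Each smoothed segment is a
convex combination of raw segments, hence total length never increases
and collinear traces pass through unchanged. The window is the smallest
that does anything at all; any contraction-type smoother would be
consistent with the measurement intent, and the choice is exposed as a
parameter (`smooth_window`).

**PLM.** Percent length myelinated is
`100 * sum(internode lengths) / total axon length`, pooled over the
branch tree. Annotations overlapping by at most 0.5 μm (rounding at
shared node boundaries) are merged on load; larger overlaps are rejected
as inconsistent input. When the raw quotient exceeds 100% — possible
only for jittered sheath traces that overrun the axon, admitted via
`allow_overrun = TRUE` — PLM is set to 99 (`cap_percent`). The cap
therefore fires exactly on the capped-artifact path and never on clean
geometry, which the tests assert both ways.

**Gaps.** A gap is the bare interval between two consecutive internodes
*on the same branch*; distance between sheaths is only well defined
along a single path, so annotations may not span bifurcations. Terminal
bare stretches are not gaps (their extent is censored by the image
boundary). Gaps of length ≤ 5 μm are classified as nodes of Ranvier;
defining non-nodal as strictly > 5 μm makes the two conventional
statements of the boundary ("< 5 μm nodal", "> 5 μm non-nodal")
consistent, with the boundary value itself counted nodal.

**Population summaries.** The proportion of axons myelinated is the
fraction with PLM > 0; with an animal grouping the per-animal fractions
are averaged and the SEM is taken across animals (N = animals, the unit
of replication in this literature). Scaled myelination prevalence — mean
binarized MBP intensity divided by the proportion of axons myelinated —
is the quotient that lets sparsely and densely myelinated regions be
compared on a per-axon-selectivity basis; it is undefined (error) where
no axon is myelinated. Unbiased axon selection is emulated by
`select_axon_seeds()`: cells of a 100 μm grid anchored at multiples of
the pitch (partially covered edge cells count), drawn uniformly without
replacement.

## Diameter by FWHM

A transverse intensity profile (gray values averaged over a 2 μm length
of axon) is reduced to a diameter as the full width at half maximum:
baseline = profile minimum (fluorescence rides on background), half-max
level = baseline + (peak − baseline)/2, crossings located by linear
interpolation between samples, and — for noisy or shouldered profiles —
the crossings *adjacent to the global peak*, which measures the central
lobe. This makes FWHM exactly invariant to additive shifts and positive
scalings, and accurate to the Gaussian closed form 2√(2 ln 2)·σ within
1% at sample spacing ≤ σ/5 (asserted in tests). No curve fitting and no
PSF deconvolution are attempted: diameters are taken at face value, as
is conventional for this measurement.

Per axon, 2–3 site FWHMs are averaged; the site myelination flags are
averaged into a **myelination fraction** (myelinated sites / total
sites), the quantity in [0, 1] that the GLM consumes. Note the fraction
is myelinated/total — the only definition that yields the intermediate
probabilities observed between fully myelinated and fully bare axons.

## The diameter + subtype model

The probability that an axon is myelinated is modelled as

  logit P(myelinated) = β₀ + β_d · diameter + β_type,

a binomial GLM with logit link under treatment coding (PV reference, so
β_type is each population's offset from PV). Site-fraction responses
enter as binomial proportions weighted by the site count. The fit is
ordinary maximum likelihood with a capped iteration budget.

**Separation.** A population none of whose axons is myelinated drives
its coefficient to −∞; the iterative fit stops at a large negative value
with an enormous standard error. Such terms (|coef| > 10 or SE > 100 by
default) are *flagged, not regularized*: the divergence is itself the
finding (a population essentially never myelinated in the sampled
layer), and a penalized estimate would disguise it. `d50()` refuses
flagged subtypes with a dedicated error.

**d50.** The diameter at which a subtype's modeled probability crosses
one half is d50 = −(β₀ + β_type)/β_d. Intervals come from the delta
method on this ratio using the fit covariance — the standard interval
for a coefficient ratio; the interval construction for published d50
brackets is not generally stated, so our intervals are documented as
delta-method and not compared against published brackets. With the
reference coefficient set shipped in `default_glm_coefficients()` the
d50 ladder is PV ≈ VM (≈ 0.52 μm) < PO (0.60) < RBP4 (0.70) <
NXPH4 (0.77): caliber matters, but identity shifts the whole curve.

The GLM route is cross-checked in the tests against an independent
brute-force grid search of the Bernoulli log-likelihood on tiny
instances, and by parameter recovery: simulating 20,000 axons from the
reference coefficients and refitting recovers β_d within ±0.3 and β₀
within ±0.2 averaged over 20 seeds.

## Remyelination analysis

Longitudinal records pair each axon's baseline PLM with its PLM after
recovery from demyelination. ΔPLM = recovery − baseline, in percentage
points (±100 bounds). Exclusions follow the tracing protocol exactly:
axons lost at the recovery timepoint are dropped; axons with PLM = 0 at
both timepoints are statused `excluded_always_unmyelinated` and dropped
from linear models (they were never candidates for remyelination and
would bias replacement trends) while remaining in proportion summaries.

Two models are fitted by OLS. The **simple** form
`recovery ~ 1 + baseline` summarizes pattern preservation; where its
line crosses the identity line, x\* = intercept/(1 − slope), separates
axons that tend to gain (below) from axons that tend to lose (above).
The **adjusted** form `recovery ~ 1 + baseline + baseline:ΔPLM` is
implemented verbatim as reported in this literature, and it must be said
plainly: ΔPLM is a function of the response, so the interaction
regressor leaks the outcome and its R² is mechanically inflated. The
package reproduces the published analysis rather than a corrected one;
the near-circularity is the reason its R² is asserted only
directionally (adjusted > simple) and never numerically.

The tracing-error band is the mean of the *negative* control ΔPLM values
mirrored around zero — an empirical noise floor below which longitudinal
change is indistinguishable from re-tracing variability. ROI sheath
fractions (100 · PV sheaths / all sheaths per ROI, mean ± SEM over ROIs)
summarize whether regenerated myelin is allocated to the same
populations as developmental myelin.

## Group statistics

PLM distributions are zero-inflated and skewed, so the omnibus test is
Kruskal–Wallis (tie-corrected, χ² p-value), followed by Dunn's post-hoc
pairwise comparisons on the pooled ranking: rank-mean difference,
standard error `sqrt((N(N+1)/12 − tie term)(1/nᵢ + 1/nⱼ))`, two-sided
normal p, Šidák-corrected with m = the number of pairwise comparisons
actually performed (15 for six groups). Confidence intervals on the
rank-mean difference use the Šidák-adjusted critical value so interval
and corrected p agree; estimates are on the rank scale, the reading
consistent with the magnitudes such comparison tables exhibit.
Kolmogorov–Smirnov (asymptotic) and paired t complete the toolkit. The
published comparison tables themselves depend on raw tracings that are
not redistributable; the package reproduces their *schema*
(`sample_1 sample_2 ci_lower estimate ci_upper corrected_p`) and the
tests hold the Kruskal–Wallis test to its nominal size (empirical type-I
error 0.05 ± 0.01 over 10,000 null simulations at n = 20 × 3 groups).

## Synthetic data: what it does and does not emulate

The generators produce inputs with the statistical structure the
analyses assume, with every stochastic step derived from one seed.

- **Axon populations.** Diameters are lognormal matched to a mean and sd
  per subtype: PV mean 0.6 μm, all others 0.5 μm (the reported VM mean;
  population-specific means for the remaining subtypes are not
  published, so the VM value is reused), sd 0.15 μm (synthetic default).
  Traces are unbranched and straight, length ~ N(400, 150²) μm truncated
  at 100 μm (the tracing protocol's minimum). Myelination status is
  Bernoulli from the logistic model with the reference coefficients.
  Internodes alternate with gaps from a uniform start offset:
  lengths ~ N(50, 15²) μm truncated at 10 μm; gaps nodal with
  probability 0.7 (uniform on (1, 5] μm) else lognormal
  (meanlog log 30, sdlog 0.8) truncated to [5, 150] μm. Internode and
  gap parameters are synthetic defaults — published data constrain them
  only graphically — and are all configurable.
- **Intensity profiles.** A box of width = diameter convolved with a
  Gaussian PSF (closed form as a difference of normal CDFs), constant
  baseline, i.i.d. noise proportional to the amplitude. Tested against a
  dense numerical-convolution oracle.
- **Longitudinal records.** Expected ΔPLM is piecewise linear in
  baseline: +`gain_at_zero` at baseline 0, zero at `pivot`, falling to
  −`loss_at_full` at baseline 100, plus Gaussian noise, with recovery
  clipped to [0, 99]. Defaults gain 25, loss 10, pivot 45, noise sd 10:
  the pivot matches the PV identity-line crossing scale and gain/loss
  are consistent with reported median gains of weakly myelinated axons
  and median losses of well-myelinated ones.

What the generators deliberately do **not** emulate: branched
morphology (straight unbranched traces suffice for every metric, and
branch handling is tested on hand-built trees), spatial correlation of
sheaths between neighboring axons (each axon is independent), axon loss
at the recovery timepoint, region-dependent parameters, and any imaging
physics beyond the PSF box model. Passing tests on generated data
therefore certify the *computations*, not the biological realism of any
particular parameter value.

## Numerical choices and degenerate inputs

- Annotation overlaps ≤ 0.5 μm merge; larger overlaps error. Abutting
  internodes (`[0,10)`, `[10,20)`) are valid and produce no gap.
- Gap length must be strictly positive; every gap is nodal xor
  non-nodal; the boundary value 5 μm is nodal.
- Length conservation on fully annotated unbranched axons holds to
  1e-9 μm (tested).
- FWHM errors on flat profiles and on profiles whose half level is not
  bracketed on both sides of the peak; profiles need ≥ 5 strictly
  increasing positions.
- The GLM errors on single-class responses (no information), on
  rank-deficient designs, and requires ≥ 2 subtypes; d50 warns when
  β_d ≤ 0 (non-monotone model) and errors on separation-flagged
  subtypes.
- `paired_t` returns t = 0, p = 1 for identically zero differences and
  errors on non-zero constant differences (zero variance).
- All generators restore the caller's RNG state; pipeline stage seeds
  are fixed offsets from the master seed.
- Problem sizes in the shipped tests: populations of 100–2,000 axons per
  subtype for distributional checks, 20 × 20,000 axons for parameter
  recovery, 10,000 simulations for the type-I error check — sizes at
  which the asserted tolerances are comfortably resolved.

## Known limitations

- The interval representation of myelin cannot express a sheath that
  crosses a bifurcation; such an annotation must be split upstream.
- Delta-method d50 intervals are symmetric and can be poor for weakly
  identified ratios (small |β_d|); profile-likelihood intervals would be
  the upgrade path.
- The adjusted remyelination model's R² is not a goodness-of-fit
  measure in the usual sense (see above) and is reported for
  comparability only.
- Separation detection is threshold-based (|coef| > 10, SE > 100);
  pathological designs could in principle evade it. Exact logistic
  regression or Firth correction are out of scope by design.
- SWC type and radius columns are ignored; multi-root SWC files (forest
  morphologies) are rejected.
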