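---
title: "Directed EEG connectivity networks: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed EEG connectivity networks: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dirconn)
```

This vignette is the package's own account of the analysis it implements:
the signal model, the two directed coupling measures, the permutation
statistics, the synthetic ground-truth generator, and the numerical and
design decisions taken where several defensible options existed.

## The analysis in one paragraph

Multichannel EEG is bandpass filtered with a zero-phase Butterworth filter
in a low "high theta" band (7–10 Hz) and a high "gamma" band (30–80 Hz),
and the analytic signal of each band yields instantaneous phase and
amplitude. Sensor data may be projected through a user-supplied linear
inverse operator (three dipole components per point source) and reduced to
one representative time course per atlas region (ROI) by a singular value
decomposition over the member sources. Artifact-free segments are
concatenated per subject and condition, and three directed connectivity
matrices are estimated: directed phase lag index (dPLI) in theta, dPLI in
gamma, and the theta-phase → gamma-amplitude normalized modulation index
(nMI). After a logit transform, group-level inference uses a directed
adaptation of the network-based statistic (NBS) over weakly connected
components, and per-source band power is contrasted between conditions
with a cluster-based permutation test. Finally, the anatomical distances
spanned by significant links are compared across connectivity types.

## Measures and their assumptions

**dPLI** is the sample fraction of positive wrapped phase differences,
`(1/N) Σ H(wrap(φ_x − φ_y))`. It assumes phases are meaningful, i.e. the
signals are narrowband; it is insensitive to coupling *strength* (any
consistent nonzero lead saturates toward 1) and, crucially, to zero-lag
linear mixing: a real instantaneous mixture of independent sources has a
phase-difference distribution symmetric about zero, so the expected dPLI
stays 0.5. Two numerical choices matter:

* **Wrapping convention.** Differences are wrapped to (−π, π] *before* the
  sign test — unwrapped differences would make the Heaviside sum
  meaningless. The interval is half-open so a difference of exactly π
  counts as a lead, never as both or neither.
* **H(0) = ½.** Exact-zero differences are measure-zero in theory but do
  occur in finite precision; splitting them preserves the complement
  identity `dPLI_xy + dPLI_yx = 1` exactly, which the anti-symmetry of the
  logit-scale matrices depends on.

**nMI** is `(1/√N) |Σ a e^{iφ}| / √(Σ a²)`: the circular concentration of
the fast-band amplitude over the slow-band phase, normalized so it lies in
[0, 1] (Cauchy–Schwarz) and is invariant to amplitude rescaling. It is
computed for *all* ordered ROI pairs including the diagonal — local
coupling within a region is a legitimate hypothesis and is tested, not
masked. The direction phase → amplitude carries no causal meaning. One
caveat the planted-recovery simulations make visible: when an amplitude
envelope genuinely oscillates at the slow frequency, its chance-level nMI
with *any* phase series rises, so condition contrasts can show weak
satellite links into strongly modulated regions. This is a property of the
estimator, not a bug; the permutation test keeps its error control either
way.

**Logit transform.** Both measures live in (0, 1); `log(p/(1−p))` maps
them to the real line so the first-level t-tests operate on an unbounded
scale, with 0.5 ↦ 0. Finite-sample dPLI can saturate at 0 or 1; saturated
entries are clipped to `1/(2N)` (with `N` the sample count behind the
matrix) — the tightest clipping that cannot reorder values — and the event
is reported as a warning. On the raw scale dPLI satisfies
`dPLI_xy = 1 − dPLI_yx`; true anti-symmetry (`M = −Mᵀ`) holds only after
the logit, and that is the scale on which the one-sample network test
operates.

## Preprocessing decisions

* **Filter convention.** "4th-order Butterworth, zero-phase" is read
  literally: a design order of 4 applied forward–backward (`filtfilt`),
  giving zero net phase and an effective order-8 magnitude profile. Tests
  verify the passband is zero-phase and out-of-band attenuation follows
  the squared analytic magnitude response.
* **Edge handling.** Both the filter and the Hilbert transform are
  unreliable near segment edges. One cycle of the band's lower edge is
  trimmed from each end of every segment after the analytic transform;
  segments shorter than three such cycles are rejected outright. When two
  bands must stay sample-aligned (theta phase vs gamma amplitude for nMI),
  both are trimmed by the same number of samples — one cycle of the
  *lowest* band edge.
* **Analytic transform per continuous segment.** Artifact excision cuts a
  trial into clean stretches; the Hilbert transform is applied per stretch
  and the resulting phase/amplitude arrays are concatenated. Splicing raw
  signals first would manufacture phase discontinuities at the seams. The
  alternative order (transform first, cut later) differs only in edge
  effects; the per-segment choice keeps every retained sample's phase
  estimate supported by real contiguous data.
* **Downsampling** applies an order-8 zero-phase Butterworth lowpass at
  80 % of the target Nyquist before decimation, the guard band absorbing
  the filter roll-off.

## Source and ROI reduction

The inverse operator is consumed, never computed: head modelling belongs
to the source-imaging software that produced it. Projection is linear and
applied to real and imaginary parts alike; per-source power is the squared
norm of the 3-component complex dipole vector.

**Standardization.** Power is z-scored per source across the *pooled*
time axis (all trials and conditions of a subject) before condition means
are taken. Standardizing within the same window that is later averaged
would force every mean to zero; pooling removes per-source activation
bias while leaving condition contrasts intact. Zero-variance sources
cannot be standardized and are flagged and excluded from statistics.

**SVD reduction.** Each ROI's representative time course is the first
left singular component of the time × (3 × members) matrix of
*band-filtered signed signals* — not power, because connectivity needs
oscillatory sign structure. The SVD sign ambiguity is resolved by a
majority rule: the component is oriented so that more than half of the
member series load on it positively, ties breaking toward no flip.
Consequently, flipping a majority of member series flips the output — an
equivariance the tests check explicitly. Whether the reduction should use
broadband or per-band signals is genuinely open; it is computed per band
here, so each band's representative course is optimal for that band.

## Permutation statistics

Both network tests share one computational core. For a sign vector `s`
over subjects, the per-link paired/one-sample t-statistics depend only on
`sᵀD` (because `Σ d²` is sign-invariant), so a whole block of permutations
is a single matrix product; component search runs per permutation on the
few suprathreshold links with a union-find. This keeps 200 null
calibration runs at 500 permutations each within seconds.

* **First-level threshold.** Links enter the component search at
  two-sided `p < alpha_init` from the t CDF (default 0.005; clusters use
  0.0005 per source). For the paired contrast, positive and negative
  links form components separately and the null takes the max over both
  signs. For the one-sample dPLI test only the leading (t > 0) direction
  of each pair is retained — its mirror is the same information negated.
* **Permutation schemes.** Paired contrast: conditions are swapped within
  subjects, which sign-flips the per-subject difference matrices.
  One-sample dPLI: each subject's matrix is independently transposed
  (link directions reversed), which on the anti-symmetric logit scale is
  again a per-subject sign flip. The equivalence is exact, not an
  approximation, and makes the two schemes share the vectorized core.
* **Component measure and p-value.** A component's measure is its number
  of links; `p = (1 + #{null ≥ observed}) / (1 + n_perm)` includes the
  observed statistic so p is never zero and the test is exact-level.
  Ties in the null maximum need no special handling — the null records
  the max, and ties cannot invalidate it.
* **Degenerate inputs.** Zero-variance links (e.g. identical conditions)
  are excluded with a warning; if nothing remains the result is an empty
  network set, not an error.
* **Condition differences for dPLI.** Because logit dPLI matrices are
  anti-symmetric, a paired between-condition contrast is ill-posed; each
  condition is tested separately for consistent lead directions and the
  overlap of the two conditions' significant link sets is reported. No
  automatic link removal is applied.

The cluster test on source power follows the same template with spatial
adjacency instead of graph components: sources are neighbors within a
radius of 1.5 × the median nearest-neighbor spacing when no explicit
neighborhood is supplied, suprathreshold sources cluster per sign, cluster
mass is the summed t, and the null is the max absolute mass.

**Distance profiles.** Links of the group-level significant networks
(one per connectivity type) are converted to centroid-to-centroid
Euclidean distances in mm; a one-way ANOVA across types is followed by all
pairwise t-tests with Dunn–Šidák adjustment `1 − (1 − p)^m`. Using
group-level networks (rather than pooling per-subject links) matches the
fact that the networks themselves are group-level objects; types with
fewer than two links are excluded with a warning.

## The synthetic generator: what it emulates, and what not

`sim_config()` defaults describe the acquisition the package targets:
2 conditions × 15 subjects × 40 trials of 30 s at 500 Hz, theta 7–10 Hz,
gamma 30–80 Hz. The generator emulates:

* **Pink (1/f) background noise** per ROI — the canonical EEG spectral
  shape the measures must tolerate.
* **Planted phase-lag pairs**: a narrowband carrier (filtered noise) and a
  partner produced by rotating the carrier's analytic signal by the
  planted lag; a fraction `1 − strength` of samples receive uniform phase
  jitter instead, so the expected dPLI is `(1 + strength)/2` with direct
  analytic control of the ground truth.
* **Planted phase-amplitude coupling**: the gamma carrier's envelope is
  `1 − depth + depth · exp(κ(cos(φ_θ − φ₀) − 1))`, a smooth von-Mises-type
  bump peaking at 1 at the preferred phase (κ = 2.5 by default): `depth`
  has a clean meaning, from constant envelope (0) to full silencing at
  the anti-preferred phase (1).
* **Zero-lag leakage** as an instantaneous real mixing matrix, and
  **artifact segments** (one marked high-amplitude interval per trial
  covering `artifact_fraction` of it).

Planted structure appears only in the memory-like condition, so the
control condition doubles as a built-in null. Ground truth is planted at
ROI level — recovery tests should not depend on inverse-modelling quality
— while a small synthetic forward/inverse pair exercises the
sensor → source path separately. The generator does *not* emulate
realistic head-volume conduction, ocular/muscle artifact morphology,
inter-subject anatomical variability, or behavioral covariates; passing
recovery tests therefore demonstrates correctness of the estimation and
inference chain, not robustness to everything real data can do.

## Validation scales and calibration conventions

The test battery runs at deliberately reduced problem sizes chosen to
exercise every code path while keeping the full suite in tens of seconds:
oracle equivalence on 100 random instances per operation; recovery with
12 subjects, 10 ROIs, 4 trials × 5 s at 250 Hz, 1000 permutations;
family-wise-error calibration of both NBS variants over 200 null
simulations (12 subjects, 20 ROIs, 500 permutations) directly at the
connectivity-matrix level — the exact null of the procedure under test.

One convention deserves explicit statement. The leakage-robustness check
("zero-lag mixtures keep dPLI at 0.5 within binomial error") cannot use
the raw sample count: narrowband phase differences are strongly
autocorrelated, and a binomial standard error at N samples would be wildly
anticonservative. The check subsamples wrapped phase differences at three
decorrelation times of the passband (spacing `3·fs/bandwidth`), at which
point the binomial SE is empirically well calibrated (SD/SE ≈ 0.94–1.05
across 400 simulated seeds), and allows at most one 3-SE excursion across
50 seeds — the nominal exceedance rate of a 3-SE bound makes strictly zero
excursions itself a ~14 % false alarm.

## Known limitations

* dPLI saturates: it ranks lead *consistency*, not coupling magnitude.
* nMI inherits the amplitude-rhythmicity sensitivity discussed above.
* The per-segment Hilbert convention discards two edge-trim windows per
  clean segment; heavily fragmented recordings lose proportionally more
  data.
* The sensor → source path assumes the provided operator is meaningful;
  no depth weighting, noise regularization or operator diagnostics are
  performed here.
* Group inference assumes exchangeability of subjects under the
  permutation scheme; unbalanced or non-paired designs are out of scope.
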