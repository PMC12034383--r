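---
title: "Phasor analysis of lifetime and spectral images: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasor analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasorlab)
```

## The phasor model

A FLIM pixel records `B` photon counts `I(b)` over one excitation period
`T = 1/f`; a hyperspectral pixel records counts over a detection band
`[λ0, λ1]`. The discrete phasor transform maps the distribution to

$$G_n = \frac{\sum_b I(b)\cos(2\pi n b/B)}{\sum_b I(b)}, \qquad
  S_n = \frac{\sum_b I(b)\sin(2\pi n b/B)}{\sum_b I(b)},$$

with harmonic number `n` and bins indexed by their left edges
`b = 0..B-1`. The transform is intensity-independent and linear: the phasor of
a photon-wise sum of signals is the photon-weighted average of their phasors.
This linearity is what makes cursor analysis, clustering and unmixing work.

For a single-exponential decay of lifetime `τ` at angular frequency
`ω = 2πfn`, the continuous transform gives
`G = 1/(1+(ωτ)²)`, `S = ωτ/(1+(ωτ)²)`, a point on the universal circle
`S² = G − G²`. Mixtures lie on chords, hence strictly inside the circle.

**Angle convention.** Using bin left edges makes a delta decay at bin 0 map
exactly to `(1, 0)`. The synthetic generator samples decays at bin *centres*
(as an integrating detector does), so an uncalibrated simulated decay is
rotated by half a bin angle. This is intentional: real instruments carry
arbitrary phase delays, and the calibration step absorbs both — mirroring
actual practice.

## Calibration

A measurement of a fluorophore with known single-exponential lifetime
`τ_ref` gives, per harmonic, a phase shift `Δφ(n)` and modulation factor
`k(n)` relating the measured aggregate phasor (intensity-weighted mean over
valid pixels — weighting by photons, not averaging per-pixel phases, because
phase noise scales inversely with photon count) to the closed-form point.
Applying a correction multiplies each pixel's `G + iS` by `k·e^{iΔφ}`. The
corrections form a group: `(−Δφ, 1/k)` inverts exactly, and manual coarse
corrections can be entered directly (phases wrapped into `(−π, π]`).

**Finite-binning limit.** The discrete phasor of a bin-sampled periodic
exponential is exactly `(1−x)/(1−x e^{iθ})` with `x = e^{−T/(Bτ)}` and
`θ = 2πn/B` (`single_exp_phasor_binned()`). Writing it as the continuous
closed form times `g(a)/g(a−iθ)` with `g(z) = (1−e^{−z})/z`, `a = T/(Bτ)`,
a series expansion shows that after calibration at `τ_ref` the residual
phase error is ≈ `θ(a − a_ref)/12` — zero only at `τ = τ_ref`, and about
`2×10⁻⁴` rad for `τ = 0.5` ns against `τ_ref = 4` ns at `B = 256`,
`f = 80` MHz. Calibration therefore cancels discretization *approximately*,
to about `10⁻³` in G/S at `B = 256` (comfortably inside our test bound) and
to `10⁻⁶` only for `B ≳ 4000`; the test suite demonstrates both regimes.
Lifetime estimates are far less affected (worst case ≈ 0.07% at 0.5 ns)
because the phase residual is small compared with the phase itself.

Spectral phasors are used uncalibrated: the transform is identical, but there
is no analogue of a known-lifetime reference, and empirical components (below)
absorb instrument response where it matters.

## Lifetime projections

With `φ = atan2(S, G)` and `M = √(G²+S²)`:

* tau-phase `τ_φ = S/(ωG)` — precise for fast lifetimes;
* tau-modulation `τ_M = √(1/M² − 1)/ω` — precise for slow lifetimes;
* tau-normalized: project radially from the circle centre `(½, 0)`;
  with `θ = atan2(S, G−½)` lifted to `[0, π]`, `G_N = (1+cos θ)/2` and
  `τ_N = √((1−G_N)/G_N)/ω`.

All three coincide on the circle (an analytic identity our tests assert to
1e-9 relative), and `τ_φ ≤ τ_M` holds strictly inside it. The radical forms of
`τ_M` and `τ_N` are forced by requiring that an on-circle point return the
exponential's true lifetime. `custom_projection()` generalises both: from an
arbitrary origin, the pixel is mapped along its ray to the universal circle —
the nearer forward intersection in `radial` mode, the farther in `angular`
mode, solved by a numerically guarded quadratic (tangent rays count as hits;
rays that miss flag the pixel invalid). Origin `(0,0)`/angular reproduces
tau-phase and `(½,0)`/radial reproduces tau-normalized to 1e-12, which the
suite checks against an independent `polyroot` intersection oracle.

Undefined projections are flagged invalid rather than clamped: `G ≤ 0` or
`S < 0` for phase, `M = 0` or `M > 1` for modulation, `S < 0` for normalized.
No sentinel values enter downstream statistics.

## Phasor-space operations

* **Filtering**: a uniform `k×k` box kernel (odd `k ≥ 3`, default 3), applied
  `repeats` times to every harmonic's G and S map simultaneously. Invalid
  pixels are excluded and the average renormalised by the valid-neighbour
  count, which also handles image edges. A box mean (not a median) is used:
  it preserves the linear-mixture interpretation of phasor coordinates and
  fixes constants exactly. Filtering G/S never touches intensity or validity.
* **Masking**: validity = positive intensity ∧ `tmin ≤ I ≤ tmax` (inclusive)
  ∧ an optional externally loaded mask.
* **Histogramming**: `R×R` grid (default 256) over `[−1,1]²`, half-open bins
  with the last edge closed so boundary points are counted; log scaling is a
  display transform (`log1p`) — stored counts stay raw.
* **Cursors**: circular regions tested boundary-inclusively; overlapping
  cursors resolve to the later-drawn one (painter's order — deterministic and
  matching interactive intuition). Reciprocity runs batch-wise: an image
  region maps to the set of occupied histogram bins.

## Gaussian-mixture clustering

Features are the valid pixels' `(G, S)` pairs of the selected harmonics
(default harmonic 1, i.e. 2-D; harmonics can be concatenated to 2·|H|
dimensions). The EM fit uses full covariances with:

* convergence at relative log-likelihood change `< 1e-7` or 500 iterations;
* a diagonal floor of `1e-8` keeping covariances positive definite
  (phasor clusters can be extremely tight at high photon counts);
* initialisation from user-supplied means (with identity covariances scaled
  to the pooled feature variance) or k-means++ under an explicit recorded
  seed — fits are bit-reproducible, and the log-likelihood trace is stored
  and asserted non-decreasing in every test fit.

Applying a model to another dataset is a pure E-step: posteriors sum to one
per valid pixel, hard labels take the maximum posterior with ties resolved to
the lowest cluster index. The display ellipse of a cluster at coverage level
`ℓ` uses the bivariate-normal Mahalanobis radius `r = √(−2 ln(1−ℓ))`
(the χ²₂ quantile), semi-axes `r·√eigenvalues(Σ)`; the default level is 0.88.
Tests verify coverage by Monte-Carlo with a geometric point-in-ellipse check,
independent of the Mahalanobis formula, and cross-check the EM fit against an
independent mixture implementation.

## Multi-harmonic unmixing

A pixel's phasor in `N` harmonics provides `2N` equations; photon
conservation adds one more, so up to `C = 2N+1` components are identifiable.
Column `i` of the component matrix stacks
`[G₁ⁱ, S₁ⁱ, …, G_Nⁱ, S_Nⁱ, 1]`; the per-pixel system `A f = m` is solved
exactly at capacity, by least squares for `C < 2N+1`, and by nonnegative
least squares (conservation row weighted ×1000, keeping `Σf = 1` within
1e-6) under `nonneg = TRUE`. Negative fractions from the unconstrained solver
are deliberately reported — they diagnose poorly chosen components. All
harmonics enter with equal weight; the residual norm per pixel is recorded.
Fractions are photon fractions (phasor mixing is intensity-weighted);
conversion to molar fractions would require brightness ratios and is out of
scope.

Component coordinates come from three sources: the continuous closed form
(the default, appropriate for instrument data where calibration has mapped
coordinates to the continuous ideal), the *binned* closed form at the
acquisition's `B` multiplied by the field's stored calibration (appropriate
when the binning is known and coarse — it makes noiseless simulated mixtures
unmix exactly, removing the finite-binning bias analysed above), or
empirical measurement: the intensity-weighted mean phasor of a user-selected
region, the standard route for spectral components.

**Noise propagation.** Identifiability at capacity does not mean precision.
For the five-lifetime benchmark set {0.5, 1, 2, 4, 8} ns on two harmonics at
80 MHz, the stacked matrix has condition number ≈ 225 and inverse-row norms
up to ≈ 53. Poisson statistics give phasor coordinates a standard deviation
≈ `√(0.5/N_photons)`, i.e. ≈ 2×10⁻³ at 10⁵ photons — so per-pixel fraction
errors of several percent are *expected* at that budget, and reaching 10⁻³
RMSE would take ~10⁹ photons per pixel or heavy spatial averaging. Closely
spaced lifetimes, not the solver, are the bottleneck; the acceptance test
records this honestly.

## Synthetic data

The generator produces the study conditions for every test: per-pixel
expected counts `∝ Σ_i w_i e^{−t_k/τ_i}` at bin centres `t_k = (k+½)T/B` in
periodic steady state (the decay tail wraps across the period, so high-`B`
simulations converge to the continuous closed form), normalised to the photon
budget and Poisson-sampled under a fixed seed; spectral scenes use Gaussian
emission bands discretised the same way. Ground truth (per-pixel photon
fractions, species parameters) travels with the stack. Reference fixtures for
calibration tests realise phase distortions by integer-bin circular time
shifts (exact per-harmonic rotations, the actually applied value recorded)
and modulation factors `k ≤ 1` by uniform-background mixing (exact scaling of
every harmonic).

What the generator does *not* emulate: instrument response functions (the
half-bin offset stands in for a phase-type IRF, but no pulse broadening),
detector afterpulsing, background autofluorescence, optical blur, or spatial
correlation of noise. Passing tests therefore demonstrate correctness of the
transform/calibration/clustering/unmixing chain under ideal Poisson imaging —
not robustness to every artefact of a real microscope.

## Problem sizes and runtime

The shipped tests run desk-scale by choice: 64×64 scenes with 256 bins for
unmixing, 16×16 or smaller elsewhere, 10⁵ Monte-Carlo samples for ellipse
coverage, 15 000 points for mixture fits. These sizes put every statistical
tolerance several standard errors wide of its threshold while keeping the
whole suite around a minute; the algorithms themselves are vectorised over
pixels and scale linearly in pixel count.

## Known limitations

* Finite-binning residual after calibration (quantified above) — intrinsic
  to multiplicative per-harmonic calibration, not removable by convention.
* Ill-conditioning of many-component unmixing with close lifetimes.
* The ref container is this package's own documented dialect; byte-level
  compatibility with legacy phasor software is not guaranteed.
* TIFF count storage is exact up to 2²⁴ per bin (16-bit pages below 2¹⁶,
  scaled float32 above); larger per-bin counts must be rebinned.
* Spectral data receive no wavelength-dependent calibration; empirical
  components are the supported route.
* No vendor file formats (.ptu, .sdt, .lsm, …) — generic TIFF/CSV only.
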