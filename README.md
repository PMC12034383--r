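# phasorlab

Scriptable phasor analysis for fluorescence lifetime (FLIM) and hyperspectral
microscopy in R.

In FLIM, every pixel of an image holds a histogram of photon arrival times; in
hyperspectral imaging, a histogram over wavelength bins. The phasor approach
maps each pixel's photon distribution `I(b)` (bins `b = 0..B-1`) to a point in
a 2-D "phasor space" via the first Fourier harmonics — no model fitting, no
prior knowledge of the sample:

```
G_n = Σ_b I(b) cos(2πnb/B) / Σ_b I(b)
S_n = Σ_b I(b) sin(2πnb/B) / Σ_b I(b)
```

Single-exponential decays of lifetime τ fall on the *universal circle*
`S² = G − G²` at `G = 1/(1+(ωτ)²)`, `S = ωτ/(1+(ωτ)²)` with `ω = 2πfn`;
mixtures fall inside it. Around that transform, phasorlab implements a full
analysis tool chain for microscopists working with either commercial or
custom-built systems:

* **Calibration** — per-harmonic phase-shift/modulation-factor corrections from
  a reference fluorophore of known lifetime, or entered manually.
* **Lifetime maps** — tau-phase `S/(ωG)`, tau-modulation `√(1/M²−1)/ω`,
  tau-normalized (radial projection from the circle centre), arbitrary custom
  projections onto the universal circle, and colour-gradient exports.
* **Phasor-space tools** — box filtering of G/S maps across all harmonics,
  intensity masking, 2-D histograms (linear/log), circular-cursor manual
  clustering, and batch reciprocity selections between image and phasor space.
* **GMM clustering** — Gaussian-mixture segmentation of phasor distributions by
  EM (seeded, reproducible), posterior-coloured exports, model reuse across
  datasets, and confidence ellipses (default display level 88%).
* **Quantitative unmixing** — per-pixel photon fractions of up to `2N+1` pure
  components from `N` harmonics, components defined by lifetime or measured
  empirically; fraction images, ratio-metric images, spreadsheet export.
* **Synthetic data** — multi-exponential decay and Gaussian emission-band
  scenes with Poisson photon noise and known ground truth, so every stage is
  testable without instrument data.
* **I/O** — multi-page TIFF stacks, CSV/TSV decay traces, a documented
  multi-harmonic phasor container ("ref" dialect: float32 planes intensity,
  φ₁°, M₁, φ₂, M₂, … with a JSON sidecar), and hard/soft/component-coloured
  image exports.

## Worked example

Simulate a two-fluorophore specimen, calibrate, and recover the photon
fractions from the theoretical lifetimes:

```r
library(phasorlab)

scene <- scene_spec(
  layout = 32,                                   # 32 x 32 pixels, one region
  species = list(list(tau = 1e-9), list(tau = 4e-9)),
  weights = c(0.4, 0.6),                         # photon fractions
  photons_per_pixel = 1e4, bins = 128, frequency = 80e6, seed = 1
)
stack <- simulate_decay_stack(scene)
stack
#> <decay_stack> 128 bins x 32 x 32 pixels, 10,235,892 photons total
#>   frequency 80 MHz (period 12.5 ns)

field <- phasor_transform(stack, harmonics = 1:2)
ref <- make_reference_stack(4e-9, dim = 8, bins = 128, noise = FALSE)
corr <- compute_correction(phasor_transform(ref, 1:2), tau_ref = 4e-9)
corr
#> <phasor_correction> (reference_file)
#>   n=1: dphi = +0.024444 rad, k = 0.999900
#>   n=2: dphi = +0.048888 rad, k = 0.999598
field <- apply_correction(field, corr)

lifetime_image(field, method = "phase")
#> <lifetime_image> method phase, 1024 valid pixels, tau in [1.72, 1.91] ns

comps <- component_set(
  list(lifetime_component("fast", 1e-9), lifetime_component("slow", 4e-9)),
  harmonics = 1:2, frequency = 80e6, prediction = "binned"
)
fractions <- unmix_field(field, comps)
round(c(fast = mean(fractions$fractions[, , 1]),
        slow = mean(fractions$fractions[, , 2])), 3)
#> fast slow
#>  0.4  0.6
```

The correction's small phase shift is the half-bin offset between the
simulator's bin-centre sampling and the transform's bin-edge convention —
exactly what calibration exists to absorb on a real instrument. The apparent
single-lifetime map sits between 1 and 4 ns (mixtures lie inside the universal
circle); the unmixing recovers the simulated 40:60 photon split.

`plot_phasor(field)` draws the phasor histogram with the universal circle, and
cluster ellipses or cursors can be overlaid. A batch pipeline
(`run_pipeline()`, or the `inst/cli/phasorlab.R` command-line wrapper) chains
simulate → transform → calibrate → filter/mask → lifetime/cursors/cluster/unmix
→ export from a single JSON config with a seeded, manifest-tracked run.

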