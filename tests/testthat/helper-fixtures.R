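# Shared fixtures: all synthetic, generated in code at test time.

FREQ <- 80e6   # 80 MHz laser, 12.5 ns period — typical two-photon TCSPC

# Noiseless (expected-count) single-exponential stack.
exp_stack <- function(tau, bins = 256L, side = 2L, photons = 1e6,
                      frequency = FREQ, noise = FALSE, seed = 1L) {
  sp <- scene_spec(side, list(list(tau = tau)), 1, photons,
                   bins = bins, frequency = frequency, seed = seed)
  simulate_decay_stack(sp, noise = noise)
}

# Field of a noiseless exponential, calibrated against a noiseless
# tau_ref reference simulated identically.
calibrated_exp_field <- function(tau, tau_ref = 4e-9, bins = 256L,
                                 harmonics = 1:2, frequency = FREQ) {
  ref <- phasor_transform(exp_stack(tau_ref, bins = bins,
                                    frequency = frequency), harmonics)
  corr <- compute_correction(ref, tau_ref)
  apply_correction(
    phasor_transform(exp_stack(tau, bins = bins, frequency = frequency),
                     harmonics),
    corr
  )
}

# Build a phasor field directly from per-harmonic coordinate matrices.
field_from_coords <- function(G, S, harmonics = 1L, intensity = NULL,
                              valid = NULL, frequency = FREQ,
                              calibrated = TRUE, bins = 256L) {
  if (is.null(dim(G))) G <- matrix(G, 1L)
  if (is.null(dim(S))) S <- matrix(S, 1L)
  d <- dim(G)[1:2]
  K <- length(harmonics)
  if (length(dim(G)) == 2L) {
    G <- array(G, c(d, K)); S <- array(S, c(d, K))
  }
  if (is.null(intensity)) intensity <- matrix(1, d[1L], d[2L])
  if (is.null(valid)) valid <- intensity > 0
  phasorlab:::new_phasor_field(
    G = G, S = S, intensity = intensity, valid = valid,
    harmonics = harmonics, bins = bins, frequency = frequency,
    calibrated = calibrated
  )
}

# Independent brute-force phasor oracle: direct summation, one pixel.
oracle_phasor <- function(counts, n) {
  B <- length(counts)
  g <- 0; s <- 0
  for (k in 0:(B - 1L)) {
    g <- g + counts[k + 1L] * cos(2 * pi * n * k / B)
    s <- s + counts[k + 1L] * sin(2 * pi * n * k / B)
  }
  c(G = g / sum(counts), S = s / sum(counts))
}

expect_no_na <- function(x) expect_false(anyNA(x))
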