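#' Specify a synthetic imaging scene
#'
#' A scene assigns to each pixel (via an integer `layout` image) a mixture
#' of species, each species being either a single-exponential decay
#' (`tau`, seconds; lifetime scenes) or a Gaussian emission band
#' (`center`/`sigma`, nm; spectral scenes). Mixture weights are photon
#' fractions and must sum to 1 within each layout label.
#'
#' @param layout Integer `H x W` label image (labels `1..L`), or a single
#'   integer `n` for a uniform `n x n` single-label scene.
#' @param species List of species definitions: `list(tau = ...)` or
#'   `list(center = ..., sigma = ...)`.
#' @param weights `L x length(species)` matrix of photon fractions (rows sum
#'   to 1), or a single vector for one label.
#' @param photons_per_pixel Expected photon count per pixel (`> 0`).
#' @param bins Number of time/wavelength bins.
#' @param frequency Laser frequency in Hz (lifetime scenes).
#' @param lambda_range `c(lambda0, lambda1)` nm (spectral scenes).
#' @param seed RNG seed for the Poisson sampling.
#' @return A `scene_spec`.
#' @export
scene_spec <- function(layout, species, weights, photons_per_pixel,
                       bins = 256L, frequency = NULL, lambda_range = NULL,
                       seed = 1L) {
  if (length(layout) == 1L) layout <- matrix(1L, layout, layout)
  layout <- as.matrix(layout)
  if (is.null(dim(weights))) weights <- matrix(weights, nrow = 1L)
  L <- max(layout)
  if (nrow(weights) != L || ncol(weights) != length(species)) {
    stop("`weights` must be an L x n_species matrix", call. = FALSE)
  }
  if (any(abs(rowSums(weights) - 1) > 1e-9)) {
    stop("mixture weights must sum to 1 within each label", call. = FALSE)
  }
  if (photons_per_pixel <= 0) stop("`photons_per_pixel` must be > 0", call. = FALSE)
  structure(
    list(layout = layout, species = species, weights = weights,
         photons_per_pixel = photons_per_pixel, bins = as.integer(bins),
         frequency = frequency, lambda_range = lambda_range, seed = seed),
    class = "scene_spec"
  )
}

# normalized expected bin profile of one decay species
decay_profile <- function(tau, bins, frequency) {
  if (tau <= 0) stop("species lifetimes must be > 0", call. = FALSE)
  Tp <- 1 / frequency
  tk <- (seq_len(bins) - 0.5) * Tp / bins   # bin centres
  e <- exp(-tk / tau)                       # periodic steady state: the
  e / sum(e)                                # wrapped tail is a constant factor
}

# normalized expected bin profile of one Gaussian emission band
band_profile <- function(center, sigma, bins, lambda_range) {
  lam <- lambda_range[1L] +
    (seq_len(bins) - 0.5) * diff(lambda_range) / bins
  e <- if (sigma <= 0) {
    as.numeric(seq_len(bins) == which.min(abs(lam - center)))
  } else {
    exp(-0.5 * ((lam - center) / sigma)^2)
  }
  if (sum(e) == 0) stop("emission band has no support in the spectral range",
                        call. = FALSE)
  e / sum(e)
}

simulate_stack_core <- function(spec, profiles, noise) {
  layout <- spec$layout
  H <- nrow(layout); W <- ncol(layout); B <- spec$bins
  nsp <- length(spec$species)
  cm <- matrix(0, B, H * W)
  fractions <- array(0, c(H, W, nsp))
  for (lab in seq_len(max(layout))) {
    wl <- spec$weights[lab, ]
    expected <- spec$photons_per_pixel *
      as.vector(profiles %*% wl)             # B vector
    pix <- which(layout == lab)
    cm[, pix] <- expected
    for (i in seq_len(nsp)) {
      fi <- fractions[, , i]
      fi[pix] <- wl[i]
      fractions[, , i] <- fi
    }
  }
  counts <- array(cm, c(B, H, W))
  if (noise) {
    counts <- with_seed(spec$seed,
                        array(stats::rpois(length(counts), counts), dim(counts)))
  }
  list(counts = counts, fractions = fractions)
}

#' Simulate a TCSPC decay stack with known ground truth
#'
#' Per pixel, expected bin counts are proportional to the mixture
#' `sum_i w_i * exp(-t_k / tau_i)` of the label's species, sampled at bin
#' centres `t_k = (k + 1/2) * T / B` in periodic steady state (the decay
#' wraps across the excitation period), normalised to `photons_per_pixel`,
#' then Poisson-sampled under the scene's seed. With `noise = FALSE` the
#' expected (real-valued) counts are returned — the noiseless limit used in
#' analytical checks.
#'
#' @param spec A [scene_spec()] with `frequency` set and `tau` species.
#' @param noise Poisson-sample the counts (default `TRUE`).
#' @return A [decay_stack()] with attribute `"ground_truth"`: a list with
#'   per-pixel photon `fractions` (`H x W x n_species`) and the species
#'   `taus`.
#' @export
simulate_decay_stack <- function(spec, noise = TRUE) {
  stopifnot(inherits(spec, "scene_spec"))
  if (is.null(spec$frequency)) stop("scene has no `frequency`", call. = FALSE)
  taus <- vapply(spec$species, `[[`, numeric(1L), "tau")
  profiles <- vapply(taus, decay_profile, numeric(spec$bins),
                     bins = spec$bins, frequency = spec$frequency)
  sim <- simulate_stack_core(spec, profiles, noise)
  out <- decay_stack(sim$counts, spec$frequency)
  attr(out, "ground_truth") <- list(fractions = sim$fractions, taus = taus)
  out
}

#' Simulate a hyperspectral stack with known ground truth
#'
#' Gaussian emission bands discretised over the spectral range at bin
#' centres, mixed per label, normalised to the photon budget and
#' Poisson-sampled. Bands whose centre lies outside `lambda_range` are
#' truncated (with a warning; the truncation is recorded in the ground
#' truth).
#'
#' @param spec A [scene_spec()] with `lambda_range` set and
#'   `center`/`sigma` species.
#' @param noise Poisson-sample the counts (default `TRUE`).
#' @return A [spectral_stack()] with attribute `"ground_truth"`.
#' @export
simulate_spectral_stack <- function(spec, noise = TRUE) {
  stopifnot(inherits(spec, "scene_spec"))
  if (is.null(spec$lambda_range)) stop("scene has no `lambda_range`", call. = FALSE)
  centers <- vapply(spec$species, `[[`, numeric(1L), "center")
  sigmas <- vapply(spec$species, `[[`, numeric(1L), "sigma")
  truncated <- centers < spec$lambda_range[1L] | centers > spec$lambda_range[2L]
  if (any(truncated)) {
    warning("emission band centre outside the spectral range; band truncated",
            call. = FALSE)
  }
  profiles <- mapply(band_profile, centers, sigmas,
                     MoreArgs = list(bins = spec$bins,
                                     lambda_range = spec$lambda_range))
  sim <- simulate_stack_core(spec, profiles, noise)
  out <- spectral_stack(sim$counts, spec$lambda_range)
  attr(out, "ground_truth") <- list(fractions = sim$fractions,
                                    centers = centers, sigmas = sigmas,
                                    truncated = truncated)
  out
}

#' Simulate a distorted calibration-reference measurement
#'
#' Simulates a single-exponential reference of lifetime `tau_ref` and
#' corrupts its phasor content to emulate an instrument response:
#' * phase: the decay is circularly shifted in time by an integer number of
#'   bins `j = round(dphi / (2*pi/B))`, which rotates harmonic `n` by
#'   exactly `n * j * 2*pi/B`;
#' * modulation: a uniform-background photon fraction `1 - k` is mixed in,
#'   which scales every harmonic's modulus by exactly `k` (hence `k <= 1`).
#'
#' The exactly applied distortion is recorded in the ground truth
#' (`dphi_applied` per harmonic, `k_applied`), so tests can verify that
#' [compute_correction()] recovers its inverse.
#'
#' @param tau_ref Reference lifetime in seconds.
#' @param dphi Requested phase distortion at harmonic 1 (radians); rounded
#'   to an integer-bin time shift.
#' @param k Modulation distortion factor in (0, 1].
#' @param dim Image side length (default 16).
#' @param photons_per_pixel Expected photons per pixel.
#' @param bins,frequency Acquisition settings.
#' @param seed RNG seed.
#' @param harmonics Harmonics for which `dphi_applied` is reported.
#' @param noise Poisson-sample (default `TRUE`).
#' @return A [decay_stack()] with attribute `"ground_truth"` listing
#'   `dphi_applied` (named by harmonic), `k_applied`, `shift_bins`,
#'   `tau_ref`.
#' @export
make_reference_stack <- function(tau_ref, dphi = 0, k = 1, dim = 16L,
                                 photons_per_pixel = 1e4, bins = 256L,
                                 frequency = 80e6, seed = 1L,
                                 harmonics = c(1L, 2L), noise = TRUE) {
  if (k <= 0 || k > 1) {
    stop("`k` must be in (0, 1]: modulation distortion is realized by background mixing",
         call. = FALSE)
  }
  j <- round(dphi / (2 * pi / bins))
  prof <- decay_profile(tau_ref, bins, frequency)
  shifted <- if (j == 0) prof else {
    idx <- ((seq_len(bins) - 1L - j) %% bins) + 1L
    prof[idx]
  }
  mixed <- k * shifted + (1 - k) / bins
  expected <- photons_per_pixel * mixed
  counts <- array(rep(expected, dim * dim), c(bins, dim, dim))
  if (noise) {
    counts <- with_seed(seed,
                        array(stats::rpois(length(counts), counts), dim(counts)))
  }
  out <- decay_stack(counts, frequency)
  attr(out, "ground_truth") <- list(
    dphi_applied = stats::setNames(wrap_angle(harmonics * j * 2 * pi / bins),
                                   harmonics),
    k_applied = k, shift_bins = j, tau_ref = tau_ref
  )
  out
}
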