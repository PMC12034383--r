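#' Calibration corrections for phasor fields
#'
#' FLIM instruments delay and demodulate the recorded decay relative to the
#' excitation, so raw phasor coordinates are rotated and scaled away from
#' their theoretical positions. A `phasor_correction` stores, per harmonic
#' `n`, a phase shift `dphi(n)` (radians, in `(-pi, pi]`) and a modulation
#' factor `k(n) > 0`; applying it multiplies each pixel's phasor
#' `G + iS` by `k(n) * exp(i * dphi(n))`.
#'
#' @name phasor_correction
NULL

new_correction <- function(harmonics, dphi, k, provenance, tau_ref = NA_real_) {
  structure(
    list(harmonics = as.integer(harmonics),
         dphi = wrap_angle(as.numeric(dphi)),
         k = as.numeric(k),
         provenance = provenance, tau_ref = tau_ref),
    class = "phasor_correction"
  )
}

# wrap into (-pi, pi]
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' @export
print.phasor_correction <- function(x, ...) {
  cat(sprintf("<phasor_correction> (%s)\n", x$provenance))
  for (j in seq_along(x$harmonics)) {
    cat(sprintf("  n=%d: dphi = %+.6f rad, k = %.6f\n",
                x$harmonics[j], x$dphi[j], x$k[j]))
  }
  invisible(x)
}

#' Compute a calibration correction from a reference measurement
#'
#' The reference is a measurement of a fluorophore solution with known
#' single-exponential lifetime `tau_ref`. Its aggregated phasor (the
#' intensity-weighted mean over valid pixels, per harmonic) is compared with
#' the theoretical point [single_exp_phasor()]: `dphi(n)` is the phase of
#' theory minus the phase of the measurement and `k(n)` the ratio of their
#' moduli.
#'
#' @param reference A `phasor_field` of the reference measurement
#'   (uncalibrated).
#' @param tau_ref Known reference lifetime in seconds (`>= 0`).
#' @param frequency Laser frequency in Hz; defaults to the field's.
#' @param harmonics Harmonics to calibrate; defaults to all in the field.
#' @return A `phasor_correction` with provenance `"reference_file"`.
#' @export
compute_correction <- function(reference, tau_ref, frequency = NULL,
                               harmonics = NULL) {
  stopifnot(inherits(reference, "phasor_field"))
  if (tau_ref < 0) stop("`tau_ref` must be >= 0", call. = FALSE)
  if (is.null(frequency)) frequency <- reference$frequency
  if (is.null(frequency)) stop("laser frequency required", call. = FALSE)
  if (is.null(harmonics)) harmonics <- reference$harmonics
  if (sum(reference$valid) < 1L) {
    stop("reference has no valid pixels", call. = FALSE)
  }
  dphi <- numeric(length(harmonics))
  k <- numeric(length(harmonics))
  for (j in seq_along(harmonics)) {
    n <- harmonics[j]
    mp <- aggregate_phasor(reference, n)
    m_meas <- Mod(mp)
    if (m_meas == 0) {
      stop(sprintf("degenerate reference: zero modulation at harmonic %d", n),
           call. = FALSE)
    }
    th <- single_exp_phasor(tau_ref, frequency, n)
    tp <- complex(real = th[1L, "G"], imaginary = th[1L, "S"])
    dphi[j] <- Arg(tp) - Arg(mp)
    k[j] <- Mod(tp) / m_meas
  }
  new_correction(harmonics, dphi, k, "reference_file", tau_ref)
}

# Intensity-weighted mean phasor of the valid pixels at one harmonic.
aggregate_phasor <- function(field, harmonic) {
  sl <- harmonic_slice(field, harmonic)
  w <- field$intensity[field$valid]
  complex(real = sum(w * sl$G[field$valid]) / sum(w),
          imaginary = sum(w * sl$S[field$valid]) / sum(w))
}

#' Manually entered calibration correction
#'
#' Coarse calibration: the user supplies the phase shift and modulation
#' factor per harmonic directly. Phase shifts are wrapped into `(-pi, pi]`.
#'
#' @param dphi Numeric vector of phase shifts (radians), one per harmonic.
#' @param k Numeric vector of modulation factors (`> 0`), recycled.
#' @param harmonics Harmonic numbers (default `seq_along(dphi)`).
#' @return A `phasor_correction` with provenance `"manual"`.
#' @export
manual_correction <- function(dphi, k = 1, harmonics = seq_along(dphi)) {
  k <- rep_len(k, length(dphi))
  if (any(k <= 0)) stop("modulation factors must be > 0", call. = FALSE)
  new_correction(harmonics, dphi, k, "manual")
}

#' Apply a calibration correction to a phasor field
#'
#' Per pixel and harmonic the phasor `G + iS` is multiplied by
#' `k(n) * exp(i * dphi(n))`. Intensity and validity are unchanged. The
#' correction is stored on the returned field (used e.g. by binned component
#' prediction in [build_component_matrix()]).
#'
#' @param field A `phasor_field`.
#' @param correction A `phasor_correction` covering every harmonic of the
#'   field.
#' @return The calibrated `phasor_field` (`calibrated = TRUE`).
#' @export
apply_correction <- function(field, correction) {
  stopifnot(inherits(field, "phasor_field"),
            inherits(correction, "phasor_correction"))
  idx <- match(field$harmonics, correction$harmonics)
  if (anyNA(idx)) {
    stop("correction does not cover every harmonic of the field",
         call. = FALSE)
  }
  for (j in seq_along(field$harmonics)) {
    rot <- correction$k[idx[j]] * exp(1i * correction$dphi[idx[j]])
    p <- complex(real = field$G[, , j], imaginary = field$S[, , j]) * rot
    field$G[, , j] <- Re(p)
    field$S[, , j] <- Im(p)
  }
  field$calibrated <- TRUE
  field$correction <- correction
  field
}

#' Invert a calibration correction
#'
#' Applying `invert_correction(corr)` after `corr` restores a field (to
#' floating-point precision): the inverse is `(-dphi, 1/k)` per harmonic.
#'
#' @param correction A `phasor_correction`.
#' @return The inverse `phasor_correction`.
#' @export
invert_correction <- function(correction) {
  new_correction(correction$harmonics, -correction$dphi, 1 / correction$k,
                 correction$provenance, correction$tau_ref)
}

#' Write or read a correction as a JSON sidecar
#' @param correction A `phasor_correction`.
#' @param path File path.
#' @return `read_correction` returns the `phasor_correction`;
#'   `write_correction` returns `path` invisibly.
#' @export
write_correction <- function(correction, path) {
  jsonlite::write_json(
    list(harmonics = correction$harmonics, dphi = correction$dphi,
         k = correction$k, provenance = correction$provenance,
         tau_ref = correction$tau_ref),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_correction
#' @export
read_correction <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_correction(x$harmonics, x$dphi, x$k, x$provenance,
                 if (is.null(x$tau_ref)) NA_real_ else x$tau_ref)
}
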