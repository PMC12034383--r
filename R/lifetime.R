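#' Phase and modulation images of a phasor field
#'
#' Polar coordinates of each pixel's phasor: `phi = atan2(S, G)`
#' (full-quadrant) and `M = sqrt(G^2 + S^2)`.
#'
#' @param field A `phasor_field`.
#' @param harmonic Harmonic to use.
#' @return A `polar_measurement`: list with `phi` and `mod` matrices
#'   (`NA` at invalid pixels) and the `valid` mask.
#' @export
phase_modulation <- function(field, harmonic = 1L) {
  sl <- harmonic_slice(field, harmonic)
  structure(
    list(phi = atan2(sl$S, sl$G),
         mod = sqrt(sl$G^2 + sl$S^2),
         valid = field$valid, harmonic = harmonic),
    class = "polar_measurement"
  )
}

new_lifetime_image <- function(tau, method, valid) {
  tau[!valid] <- NA_real_
  structure(list(tau = tau, method = method, valid = valid),
            class = "lifetime_image")
}

#' @export
print.lifetime_image <- function(x, ...) {
  rng <- range(x$tau[x$valid], na.rm = TRUE)
  cat(sprintf("<lifetime_image> method %s, %d valid pixels, tau in [%.3g, %.3g] ns\n",
              x$method, sum(x$valid), rng[1] * 1e9, rng[2] * 1e9))
  invisible(x)
}

check_calibrated <- function(field, on_uncalibrated) {
  if (!isTRUE(field$calibrated)) {
    msg <- "field is not calibrated; lifetime projections assume calibrated coordinates"
    switch(on_uncalibrated,
           warn = warning(msg, call. = FALSE),
           error = stop(msg, call. = FALSE),
           none = invisible(NULL))
  }
}

#' Lifetime projections onto the universal circle
#'
#' Three classical frequency-domain lifetime estimators, all obtained by
#' projecting the phasor point onto the universal circle
#' `S^2 = G - G^2` (`omega = 2*pi*frequency*harmonic`):
#'
#' * `phase`: `tau_phi = S / (omega * G)` — the exponential with the same
#'   phase as the measurement. More precise for fast lifetimes.
#' * `modulation`: `tau_M = sqrt(1/M^2 - 1) / omega` — the exponential with
#'   the same modulation. More precise for slow lifetimes.
#' * `normalized`: project radially from the circle centre `(1/2, 0)`:
#'   `theta = atan2(S, G - 1/2)` lifted to `[0, pi]`,
#'   `G_N = (1 + cos(theta)) / 2`, `tau_N = sqrt((1 - G_N)/G_N) / omega`.
#'
#' Pixels where a projection is undefined are flagged invalid: `G <= 0` or
#' `S < 0` for `phase`; `M = 0` or `M > 1` for `modulation`; `S < 0` or
#' `G_N = 0` for `normalized`.
#'
#' @param field A calibrated `phasor_field`.
#' @param harmonic Harmonic to use.
#' @param method One of `"phase"`, `"modulation"`, `"normalized"`.
#' @param frequency Laser frequency in Hz; defaults to the field's.
#' @param on_uncalibrated `"warn"` (default), `"error"`, or `"none"`.
#' @return A `lifetime_image` (`tau` in seconds, `method`, `valid`).
#' @export
lifetime_image <- function(field, harmonic = 1L,
                           method = c("phase", "modulation", "normalized"),
                           frequency = NULL,
                           on_uncalibrated = c("warn", "error", "none")) {
  method <- match.arg(method)
  on_uncalibrated <- match.arg(on_uncalibrated)
  check_calibrated(field, on_uncalibrated)
  if (is.null(frequency)) frequency <- field$frequency
  w <- omega_phys(frequency, harmonic)
  sl <- harmonic_slice(field, harmonic)
  G <- sl$G; S <- sl$S
  if (method == "phase") {
    ok <- field$valid & !is.na(G) & G > 0 & S >= 0
    tau <- S / (w * G)
  } else if (method == "modulation") {
    M <- sqrt(G^2 + S^2)
    ok <- field$valid & !is.na(M) & M > 0 & M <= 1
    tau <- sqrt(pmax(1 / M^2 - 1, 0)) / w
  } else {
    theta <- atan2(S, G - 0.5)      # in [0, pi] for S >= 0
    gn <- 0.5 * (1 + cos(theta))
    ok <- field$valid & !is.na(S) & S >= 0 & gn > 0
    tau <- sqrt(pmax((1 - gn) / gn, 0)) / w
  }
  ok[is.na(ok)] <- FALSE
  new_lifetime_image(tau, method, ok)
}

#' Custom projection of phasor coordinates onto the universal circle
#'
#' Generalises the lifetime projections: from an arbitrary origin
#' `(G0, S0)`, each pixel's phasor is mapped to a point on the universal
#' circle either `"radial"`ly (the nearer intersection, along the ray from
#' the origin through the pixel) or `"angular"`ly (the circle point at the
#' pixel's polar angle about the origin, i.e. the farther forward
#' intersection). Tangent rays count as hits; rays that miss the circle give
#' invalid pixels. The projected point `(Gc, Sc)` is converted to a lifetime
#' `tau = Sc / (omega * Gc)`.
#'
#' `custom_projection(field, c(0, 0), "angular")` reproduces the `phase`
#' projection; `custom_projection(field, c(0.5, 0), "radial")` reproduces
#' `normalized`.
#'
#' @param field A calibrated `phasor_field`.
#' @param origin Numeric `c(G0, S0)` inside the unit region.
#' @param mode `"radial"` or `"angular"`.
#' @param harmonic Harmonic to use.
#' @param frequency Laser frequency in Hz; defaults to the field's.
#' @param on_uncalibrated `"warn"`, `"error"`, or `"none"`.
#' @return A list with `projection` (matrices `G`, `S` of the circle points)
#'   and `tau` (a `lifetime_image`, method `"custom"`).
#' @export
custom_projection <- function(field, origin, mode = c("radial", "angular"),
                              harmonic = 1L, frequency = NULL,
                              on_uncalibrated = c("warn", "error", "none")) {
  mode <- match.arg(mode)
  on_uncalibrated <- match.arg(on_uncalibrated)
  check_calibrated(field, on_uncalibrated)
  if (length(origin) != 2L || any(abs(origin) > 1.5)) {
    stop("`origin` must be c(G0, S0) inside the unit region", call. = FALSE)
  }
  if (is.null(frequency)) frequency <- field$frequency
  w <- omega_phys(frequency, harmonic)
  sl <- harmonic_slice(field, harmonic)
  dg <- sl$G - origin[1L]
  ds <- sl$S - origin[2L]
  len <- sqrt(dg^2 + ds^2)
  ug <- dg / len
  us <- ds / len
  # ray: origin + t*u ; circle centre (1/2, 0), radius 1/2
  cg <- origin[1L] - 0.5
  cs <- origin[2L]
  b <- ug * cg + us * cs
  cc <- cg^2 + cs^2 - 0.25
  disc <- b^2 - cc
  sq <- sqrt(pmax(disc, 0))
  t1 <- -b - sq
  t2 <- -b + sq
  eps <- 1e-12
  tt <- if (mode == "radial") ifelse(t1 > eps, t1, t2) else t2
  ok <- field$valid & !is.na(disc) & disc >= 0 & tt > eps & len > 0
  Gc <- origin[1L] + tt * ug
  Sc <- origin[2L] + tt * us
  tau <- Sc / (w * Gc)
  ok <- ok & !is.na(Gc) & Gc > 0 & Sc >= 0
  ok[is.na(ok)] <- FALSE
  Gc[!ok] <- NA_real_
  Sc[!ok] <- NA_real_
  list(projection = list(G = Gc, S = Sc),
       tau = new_lifetime_image(tau, "custom", ok))
}

#' Map values to a colour-gradient RGB image
#'
#' Affinely maps values clipped to `range` onto a colormap; invalid pixels
#' render black. The colormap index of the midpoint value is the middle
#' entry; 8-bit channels are rounded half away from zero.
#'
#' @param values A `lifetime_image`, `polar_measurement` (its `phi`), or a
#'   numeric matrix.
#' @param range `c(vmin, vmax)` with `vmin < vmax`.
#' @param colormap Palette name passed to [grDevices::hcl.colors()]
#'   (default `"viridis"`).
#' @param n_colors Number of colormap entries (default 256).
#' @return An `H x W x 3` numeric array of 8-bit channel values (0–255),
#'   class `rgb_image`.
#' @export
gradient_colormap <- function(values, range, colormap = "viridis",
                              n_colors = 256L) {
  if (inherits(values, "lifetime_image")) {
    v <- values$tau
    v[!values$valid] <- NA_real_
  } else if (inherits(values, "polar_measurement")) {
    v <- values$phi
    v[!values$valid] <- NA_real_
  } else {
    v <- as.matrix(values)
  }
  if (range[1L] >= range[2L]) stop("`range` must have vmin < vmax", call. = FALSE)
  pal <- grDevices::col2rgb(grDevices::hcl.colors(n_colors, colormap))
  u <- pmin(pmax(v, range[1L]), range[2L])
  idx <- 1L + as.integer(round_half_away((u - range[1L]) /
                                           (range[2L] - range[1L]) * (n_colors - 1L)))
  img <- array(0, c(nrow(v), ncol(v), 3L))
  ok <- !is.na(idx)
  for (ch in 1:3) {
    m <- matrix(0, nrow(v), ncol(v))
    m[ok] <- pal[ch, idx[ok]]
    img[, , ch] <- m
  }
  structure(img, class = "rgb_image")
}

# round half away from zero (documented 8-bit rounding rule)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
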