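#' Discrete phasor transform of a photon-count stack
#'
#' Maps every pixel's photon distribution to phasor coordinates
#' \deqn{G_n = \sum_k I_k \cos(2\pi n k / B) / \sum_k I_k, \quad
#'       S_n = \sum_k I_k \sin(2\pi n k / B) / \sum_k I_k,}
#' with `k = 0..B-1` indexing bins by their left edges. The same discrete
#' formula serves lifetime (time bins over one excitation period) and
#' spectral (wavelength bins over the detection band) stacks. Half-bin and
#' instrument-response phase offsets are absorbed by calibration
#' ([compute_correction()]), mirroring real instruments.
#'
#' Pixels with zero total counts are flagged invalid; their G/S values are
#' `NA` and they are excluded from all downstream statistics.
#'
#' @param stack A [decay_stack()] or [spectral_stack()].
#' @param harmonics Integer vector of harmonic numbers `n >= 1`, each `< B`.
#' @return A `phasor_field`: list with `G`, `S` (`H x W x length(harmonics)`
#'   arrays), `intensity` (`H x W` total counts), `valid` (`H x W` logical),
#'   `harmonics`, `bins`, and the acquisition metadata (`frequency` or
#'   `lambda_range`, `domain`). `calibrated` starts `FALSE`.
#' @examples
#' st <- decay_stack(c(5, 3, 2, 1), frequency = 80e6)
#' phasor_transform(st, harmonics = 1)
#' @export
phasor_transform <- function(stack, harmonics = c(1L, 2L)) {
  if (!inherits(stack, "photon_stack")) {
    stop("`stack` must be a decay_stack or spectral_stack", call. = FALSE)
  }
  harmonics <- as.integer(harmonics)
  if (length(harmonics) == 0L) {
    stop("`harmonics` must be non-empty", call. = FALSE)
  }
  if (any(harmonics < 1L)) stop("harmonics must be >= 1", call. = FALSE)
  B <- stack$bins
  if (any(harmonics >= B)) {
    stop(sprintf("harmonic >= number of bins (%d) would alias", B),
         call. = FALSE)
  }
  d <- dim(stack$counts)
  H <- d[2L]; W <- d[3L]
  m <- matrix(stack$counts, nrow = B)      # B x (H*W)
  tot <- colSums(m)
  valid <- matrix(tot > 0, H, W)
  k <- 0:(B - 1L)
  K <- length(harmonics)
  G <- array(NA_real_, c(H, W, K))
  S <- array(NA_real_, c(H, W, K))
  safe_tot <- ifelse(tot > 0, tot, 1)
  for (j in seq_len(K)) {
    th <- 2 * pi * harmonics[j] * k / B
    g <- crossprod(m, cos(th))[, 1L] / safe_tot
    s <- crossprod(m, sin(th))[, 1L] / safe_tot
    g[tot == 0] <- NA_real_
    s[tot == 0] <- NA_real_
    G[, , j] <- g
    S[, , j] <- s
  }
  new_phasor_field(
    G = G, S = S,
    intensity = matrix(tot, H, W), valid = valid,
    harmonics = harmonics, bins = B,
    frequency = if (inherits(stack, "decay_stack")) stack$frequency else NULL,
    lambda_range = if (inherits(stack, "spectral_stack")) stack$lambda_range else NULL,
    domain = if (inherits(stack, "decay_stack")) "lifetime" else "spectral"
  )
}

new_phasor_field <- function(G, S, intensity, valid, harmonics, bins = NA_integer_,
                             frequency = NULL, lambda_range = NULL,
                             domain = "lifetime", calibrated = FALSE,
                             correction = NULL) {
  structure(
    list(
      G = G, S = S, intensity = intensity, valid = valid,
      harmonics = as.integer(harmonics), bins = bins,
      frequency = frequency, lambda_range = lambda_range,
      domain = domain, calibrated = calibrated, correction = correction
    ),
    class = "phasor_field"
  )
}

#' @export
print.phasor_field <- function(x, ...) {
  cat(sprintf(
    "<phasor_field> %d x %d pixels (%d valid), harmonics {%s}%s%s\n",
    nrow(x$intensity), ncol(x$intensity), sum(x$valid),
    paste(x$harmonics, collapse = ","),
    if (isTRUE(x$calibrated)) ", calibrated" else "",
    if (x$domain == "spectral") ", spectral" else ""
  ))
  invisible(x)
}

# Extract the G/S matrices of one harmonic.
harmonic_slice <- function(field, harmonic) {
  j <- match(as.integer(harmonic), field$harmonics)
  if (is.na(j)) {
    stop(sprintf("harmonic %d not present in field (has {%s})",
                 harmonic, paste(field$harmonics, collapse = ",")),
         call. = FALSE)
  }
  d <- dim(field$intensity)
  list(G = matrix(field$G[, , j], d[1L], d[2L]),
       S = matrix(field$S[, , j], d[1L], d[2L]))
}

# Angular frequency (rad/s) of harmonic n for lifetime semantics.
omega_phys <- function(field_or_f, harmonic) {
  f <- if (inherits(field_or_f, "phasor_field")) field_or_f$frequency else field_or_f
  if (is.null(f)) stop("no laser frequency available", call. = FALSE)
  2 * pi * f * harmonic
}

#' Closed-form phasor of a single-exponential decay
#'
#' For lifetime `tau` observed at angular frequency `omega = 2*pi*f*n`:
#' `G = 1/(1+(wt)^2)`, `S = wt/(1+(wt)^2)` with `wt = omega*tau`. The point
#' lies exactly on the universal circle `S^2 = G - G^2`.
#'
#' @param tau Lifetime in seconds (`>= 0`); vectorised.
#' @param frequency Laser repetition frequency in Hz.
#' @param harmonic Harmonic number `n >= 1`.
#' @return A matrix with columns `G` and `S` (one row per `tau`).
#' @examples
#' single_exp_phasor(2e-9, 80e6, 1)
#' @export
single_exp_phasor <- function(tau, frequency, harmonic = 1L) {
  stopifnot(all(tau >= 0), frequency > 0, harmonic >= 1)
  wt <- 2 * pi * frequency * harmonic * tau
  cbind(G = 1 / (1 + wt^2), S = wt / (1 + wt^2))
}

#' Discrete-sampling phasor of a wrapped single-exponential decay
#'
#' The phasor that [phasor_transform()] returns for an ideal noiseless
#' exponential of lifetime `tau` sampled into `bins` bins over one period
#' `1/frequency` (periodic steady state). Closed form: with
#' `x = exp(-T/(B*tau))` and `theta = 2*pi*n/B`,
#' `G + iS = (1 - x) / (1 - x*exp(i*theta))`.
#' Converges to [single_exp_phasor()] as `bins` grows; the difference is the
#' finite-binning aliasing that calibration only cancels at the reference
#' lifetime itself.
#'
#' @inheritParams single_exp_phasor
#' @param bins Number of time bins `B >= 2`.
#' @return A matrix with columns `G` and `S`.
#' @export
single_exp_phasor_binned <- function(tau, frequency, harmonic = 1L, bins) {
  stopifnot(all(tau >= 0), frequency > 0, harmonic >= 1, bins >= 2)
  x <- exp(-1 / (frequency * bins * tau))
  x[tau == 0] <- 0
  th <- 2 * pi * harmonic / bins
  p <- (1 - x) / (1 - x * exp(1i * th))
  cbind(G = Re(p), S = Im(p))
}

#' Restrict the validity mask by intensity thresholds and an external mask
#'
#' Keeps a pixel valid only if its total intensity lies in
#' `[tmin, tmax]` (inclusive) and, when given, the external mask is `TRUE`
#' there. Zero-intensity pixels always stay invalid.
#'
#' @param field A `phasor_field`.
#' @param tmin,tmax Count thresholds, `tmin <= tmax` (defaults keep all).
#' @param external Optional logical `H x W` image (e.g. a mask loaded from
#'   another program).
#' @return The field with an updated `valid` mask.
#' @export
intensity_mask <- function(field, tmin = 0, tmax = Inf, external = NULL) {
  stopifnot(inherits(field, "phasor_field"))
  if (tmin > tmax) stop("`tmin` must be <= `tmax`", call. = FALSE)
  keep <- field$valid & field$intensity >= tmin & field$intensity <= tmax
  if (!is.null(external)) {
    if (!identical(dim(external), dim(field$intensity))) {
      stop("external mask shape does not match the field", call. = FALSE)
    }
    ext <- matrix(as.logical(external), nrow(keep), ncol(keep))
    ext[is.na(ext)] <- FALSE
    keep <- keep & ext
  }
  field$valid <- keep
  field
}

#' Spatial box filtering of phasor coordinates
#'
#' Convolves every per-pixel G and S map (all harmonics simultaneously) with
#' a uniform `kernel_size x kernel_size` mean kernel, `repeats` times.
#' Invalid pixels are excluded from each neighbourhood average and the sum is
#' renormalised by the number of valid neighbours (this also handles image
#' edges). Intensity and validity are unchanged.
#'
#' @param field A `phasor_field`.
#' @param kernel_size Odd integer `>= 3`.
#' @param repeats Number of passes, `>= 1`.
#' @return The filtered `phasor_field`.
#' @export
filter_phasor <- function(field, kernel_size = 3L, repeats = 1L) {
  stopifnot(inherits(field, "phasor_field"))
  kernel_size <- as.integer(kernel_size)
  repeats <- as.integer(repeats)
  if (kernel_size < 3L || kernel_size %% 2L == 0L) {
    stop("`kernel_size` must be an odd integer >= 3", call. = FALSE)
  }
  if (repeats < 1L) stop("`repeats` must be >= 1", call. = FALSE)
  h <- kernel_size %/% 2L
  w <- field$valid * 1
  denom <- box_sum(w, h)
  denom[denom == 0] <- NA_real_
  for (j in seq_along(field$harmonics)) {
    g <- field$G[, , j]
    s <- field$S[, , j]
    for (r in seq_len(repeats)) {
      g0 <- ifelse(field$valid, g, 0)
      s0 <- ifelse(field$valid, s, 0)
      g <- box_sum(g0, h) / denom
      s <- box_sum(s0, h) / denom
    }
    g[!field$valid] <- NA_real_
    s[!field$valid] <- NA_real_
    field$G[, , j] <- g
    field$S[, , j] <- s
  }
  field
}

# Zero-padded (2h+1)^2 box sum via separable running sums.
box_sum <- function(m, h) {
  run <- function(x) {
    n <- nrow(x)
    cs <- rbind(0, apply(x, 2L, cumsum))
    cs[pmin(seq_len(n) + h, n) + 1L, , drop = FALSE] -
      cs[pmax(seq_len(n) - h - 1L, 0L) + 1L, , drop = FALSE]
  }
  t(run(t(run(m))))
}

#' 2D histogram of a phasor distribution
#'
#' Bins the valid pixels of one harmonic into an `resolution x resolution`
#' grid over `extent`. Bins are half-open `[edge, next)` except the last,
#' which is closed. A `log` scale affects only the display values returned by
#' [as.data.frame.phasor_histogram()] and plotting; stored counts stay raw.
#'
#' @param field A `phasor_field`.
#' @param harmonic Harmonic to histogram.
#' @param resolution Grid resolution `R >= 2` (default 256).
#' @param extent `c(gmin, gmax, smin, smax)` (default `c(-1, 1, -1, 1)`).
#' @param scale `"linear"` or `"log"`.
#' @return A `phasor_histogram`: integer `R x R` matrix `counts`
#'   (rows index S ascending, columns index G ascending) plus the grid
#'   metadata.
#' @export
phasor_histogram <- function(field, harmonic = 1L, resolution = 256L,
                             extent = c(-1, 1, -1, 1),
                             scale = c("linear", "log")) {
  stopifnot(inherits(field, "phasor_field"))
  scale <- match.arg(scale)
  resolution <- as.integer(resolution)
  if (resolution < 2L) stop("`resolution` must be >= 2", call. = FALSE)
  sl <- harmonic_slice(field, harmonic)
  g <- sl$G[field$valid]
  s <- sl$S[field$valid]
  idx <- cbind(
    bin_index(s, extent[3L], extent[4L], resolution),
    bin_index(g, extent[1L], extent[2L], resolution)
  )
  keep <- !is.na(idx[, 1L]) & !is.na(idx[, 2L])
  counts <- matrix(0L, resolution, resolution)
  if (any(keep)) {
    tab <- table(factor(idx[keep, 1L], levels = seq_len(resolution)),
                 factor(idx[keep, 2L], levels = seq_len(resolution)))
    counts <- matrix(as.integer(tab), resolution, resolution)
  }
  structure(
    list(counts = counts, extent = as.numeric(extent),
         resolution = resolution, scale = scale, harmonic = harmonic),
    class = "phasor_histogram"
  )
}

# 1-based bin index with the last edge closed; NA outside the extent.
bin_index <- function(v, lo, hi, n) {
  i <- floor((v - lo) / (hi - lo) * n) + 1L
  i[v == hi] <- n
  i[v < lo | v > hi] <- NA_integer_
  as.integer(i)
}

#' @export
print.phasor_histogram <- function(x, ...) {
  cat(sprintf("<phasor_histogram> %dx%d, harmonic %d, %d pixels, %s scale\n",
              x$resolution, x$resolution, x$harmonic, sum(x$counts), x$scale))
  invisible(x)
}

#' Tidy a phasor histogram into a data frame
#'
#' @param x A `phasor_histogram`.
#' @param row.names,optional Unused, for generic consistency.
#' @param drop_empty Drop zero-count bins (default `TRUE`).
#' @param ... Unused.
#' @return A data frame with bin-centre `g`, `s`, raw `count`, and `display`
#'   (`log1p(count)` when the histogram's scale is `"log"`).
#' @export
as.data.frame.phasor_histogram <- function(x, row.names = NULL,
                                           optional = FALSE,
                                           drop_empty = TRUE, ...) {
  R <- x$resolution
  gw <- (x$extent[2L] - x$extent[1L]) / R
  sw <- (x$extent[4L] - x$extent[3L]) / R
  df <- data.frame(
    g = rep(x$extent[1L] + (seq_len(R) - 0.5) * gw, each = R),
    s = rep(x$extent[3L] + (seq_len(R) - 0.5) * sw, times = R),
    count = as.vector(x$counts)
  )
  if (drop_empty) df <- df[df$count > 0L, , drop = FALSE]
  df$display <- if (x$scale == "log") log1p(df$count) else df$count
  df
}
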