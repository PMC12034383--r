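#' Photon-count decay stack
#'
#' A `decay_stack` holds per-pixel TCSPC photon-count histograms as a
#' `B x H x W` array (time-bin axis first) together with the laser repetition
#' frequency. The excitation period is `T = 1/f`; bin `k` (0-based) covers
#' times `[k, k+1) * T/B`.
#'
#' @param counts Non-negative numeric array `B x H x W`, or a length-`B`
#'   vector for a single decay trace (promoted to `B x 1 x 1`).
#' @param frequency Laser repetition frequency in Hz (`> 0`).
#' @param calibration_tag Optional character tag naming the calibration this
#'   stack should be matched with.
#' @return An object of class `decay_stack` with elements `counts`,
#'   `bins`, `frequency`, `period`.
#' @examples
#' s <- decay_stack(matrix(rpois(64, 10), 64, 1), frequency = 80e6)
#' dim(s$counts)
#' @export
decay_stack <- function(counts, frequency, calibration_tag = NULL) {
  counts <- as_stack_array(counts)
  if (!is.numeric(frequency) || length(frequency) != 1L || frequency <= 0) {
    stop("`frequency` must be a single positive number (Hz)", call. = FALSE)
  }
  structure(
    list(
      counts = counts,
      bins = dim(counts)[1L],
      frequency = frequency,
      period = 1 / frequency,
      calibration_tag = calibration_tag
    ),
    class = c("decay_stack", "photon_stack")
  )
}

#' Hyperspectral photon-count stack
#'
#' Per-pixel emission spectra binned over a detection band
#' `[lambda0, lambda1]` (nm), wavelength-bin axis first.
#'
#' @param counts Non-negative numeric array `B x H x W` (or length-`B` vector).
#' @param lambda_range Numeric length-2, detection band limits in nm,
#'   `lambda_range[2] > lambda_range[1]`.
#' @return An object of class `spectral_stack`.
#' @export
spectral_stack <- function(counts, lambda_range) {
  counts <- as_stack_array(counts)
  if (length(lambda_range) != 2L || !is.numeric(lambda_range) ||
      lambda_range[2L] <= lambda_range[1L]) {
    stop("`lambda_range` must be c(lambda0, lambda1) with lambda1 > lambda0",
         call. = FALSE)
  }
  structure(
    list(
      counts = counts,
      bins = dim(counts)[1L],
      lambda_range = as.numeric(lambda_range)
    ),
    class = c("spectral_stack", "photon_stack")
  )
}

# Validate and promote raw count input to a B x H x W array.
as_stack_array <- function(counts) {
  if (is.null(dim(counts))) {
    counts <- array(counts, dim = c(length(counts), 1L, 1L))
  } else if (length(dim(counts)) == 2L) {
    # a single B x 1 matrix-style trace
    counts <- array(counts, dim = c(dim(counts)[1L], dim(counts)[2L], 1L))
  }
  if (length(dim(counts)) != 3L) {
    stop("`counts` must be a B x H x W array", call. = FALSE)
  }
  if (dim(counts)[1L] < 2L) {
    stop("stack must have at least 2 bins", call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must be non-negative and free of NA", call. = FALSE)
  }
  counts
}

#' @export
print.photon_stack <- function(x, ...) {
  d <- dim(x$counts)
  kind <- if (inherits(x, "decay_stack")) "decay" else "spectral"
  cat(sprintf("<%s_stack> %d bins x %d x %d pixels, %s photons total\n",
              kind, d[1], d[2], d[3], format(sum(x$counts), big.mark = ",")))
  if (inherits(x, "decay_stack")) {
    cat(sprintf("  frequency %.4g MHz (period %.4g ns)\n",
                x$frequency / 1e6, x$period * 1e9))
  } else {
    cat(sprintf("  band [%g, %g] nm\n", x$lambda_range[1], x$lambda_range[2]))
  }
  invisible(x)
}
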