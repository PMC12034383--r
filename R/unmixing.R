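#' Define a set of pure components for phasor unmixing
#'
#' Components may be defined by a single-exponential lifetime (`tau`,
#' seconds) or by empirical phasor coordinates per harmonic (see
#' [empirical_component()]). With `N = length(harmonics)` harmonics, at most
#' `2N + 1` components can be resolved.
#'
#' `prediction` selects how lifetime-defined component coordinates are
#' computed: `"continuous"` (default) uses the continuous closed form
#' [single_exp_phasor()]; `"binned"` uses the finite-binning closed form
#' [single_exp_phasor_binned()] at the acquisition's bin count, multiplied
#' by the field's calibration — appropriate when the data's binning is known
#' and coarse.
#'
#' @param components A list; each element a list with `name`, `color`, and
#'   either `tau` (seconds) or `phasor` (a `2 x N` matrix / list of
#'   `c(G, S)` per harmonic).
#' @param harmonics Integer vector of harmonics `H` used for unmixing.
#' @param frequency Laser frequency in Hz (needed for lifetime-defined
#'   components).
#' @param prediction `"continuous"` or `"binned"`.
#' @return A `component_set`.
#' @export
component_set <- function(components, harmonics = c(1L, 2L), frequency = NULL,
                          prediction = c("continuous", "binned")) {
  prediction <- match.arg(prediction)
  harmonics <- as.integer(harmonics)
  C <- length(components)
  if (C > 2L * length(harmonics) + 1L) {
    stop(sprintf("%d components exceed the 2N+1 = %d resolvable with %d harmonics",
                 C, 2L * length(harmonics) + 1L, length(harmonics)),
         call. = FALSE)
  }
  comps <- lapply(seq_len(C), function(i) {
    co <- components[[i]]
    if (is.null(co$name)) co$name <- paste0("component", i)
    if (is.null(co$color)) co$color <- grDevices::hcl.colors(max(C, 2L), "Dark 3")[i]
    if (is.null(co$tau) && is.null(co$phasor)) {
      stop(sprintf("component '%s' needs `tau` or `phasor`", co$name),
           call. = FALSE)
    }
    if (!is.null(co$tau) && co$tau < 0) {
      stop("component lifetimes must be >= 0", call. = FALSE)
    }
    co
  })
  structure(
    list(components = comps, harmonics = harmonics, frequency = frequency,
         prediction = prediction),
    class = "component_set"
  )
}

#' Lifetime-defined pure component
#' @param name Component name.
#' @param tau Lifetime in seconds.
#' @param color Display colour.
#' @return A component definition for [component_set()].
#' @export
lifetime_component <- function(name, tau, color = NULL) {
  list(name = name, tau = tau, color = color)
}

#' Measure a pure component empirically from an image region
#'
#' The component's phasor per harmonic is the intensity-weighted mean over
#' the valid pixels of `region` — useful when no literature lifetime exists,
#' and the standard route for spectral components.
#'
#' @param field A `phasor_field`.
#' @param region Logical `H x W` image with at least one valid pixel.
#' @param name,color Component name and display colour.
#' @return A component definition (with `phasor`) for [component_set()].
#' @export
empirical_component <- function(field, region, name, color = NULL) {
  stopifnot(inherits(field, "phasor_field"))
  if (!identical(dim(region), dim(field$valid))) {
    stop("region shape does not match the field", call. = FALSE)
  }
  sub <- field
  sub$valid <- field$valid & region
  if (sum(sub$valid) < 1L) stop("region contains no valid pixels", call. = FALSE)
  ph <- sapply(field$harmonics, function(n) {
    p <- aggregate_phasor(sub, n)
    c(G = Re(p), S = Im(p))
  })
  colnames(ph) <- field$harmonics
  list(name = name, phasor = ph, color = color)
}

#' Build the stacked component matrix for multi-harmonic unmixing
#'
#' Column `i` holds component `i`'s coordinates stacked over the harmonics
#' plus the photon-conservation row:
#' `[G_1, S_1, ..., G_N, S_N, 1]`. Lifetime-defined components are evaluated
#' by the closed form selected in the set's `prediction`; empirical
#' components use their stored coordinates.
#'
#' @param set A `component_set`.
#' @param bins Bin count for `"binned"` prediction.
#' @param correction Optional `phasor_correction` applied to binned
#'   predictions (so they match calibrated data).
#' @return A `(2N + 1) x C` matrix with named rows and columns.
#' @export
build_component_matrix <- function(set, bins = NULL, correction = NULL) {
  stopifnot(inherits(set, "component_set"))
  H <- set$harmonics
  C <- length(set$components)
  A <- matrix(0, 2L * length(H) + 1L, C)
  for (i in seq_len(C)) {
    co <- set$components[[i]]
    for (j in seq_along(H)) {
      n <- H[j]
      if (!is.null(co$tau)) {
        if (is.null(set$frequency)) {
          stop("`frequency` required for lifetime-defined components",
               call. = FALSE)
        }
        gs <- if (set$prediction == "binned") {
          if (is.null(bins)) stop("`bins` required for binned prediction",
                                  call. = FALSE)
          single_exp_phasor_binned(co$tau, set$frequency, n, bins)
        } else {
          single_exp_phasor(co$tau, set$frequency, n)
        }
        g <- gs[1L, "G"]; s <- gs[1L, "S"]
        if (set$prediction == "binned" && !is.null(correction)) {
          cj <- match(n, correction$harmonics)
          if (is.na(cj)) stop("correction does not cover harmonic", call. = FALSE)
          p <- complex(real = g, imaginary = s) *
            correction$k[cj] * exp(1i * correction$dphi[cj])
          g <- Re(p); s <- Im(p)
        }
      } else {
        ph <- co$phasor
        col <- if (!is.null(colnames(ph))) match(as.character(n), colnames(ph)) else j
        if (is.na(col)) stop(sprintf("component '%s' lacks harmonic %d", co$name, n),
                             call. = FALSE)
        g <- ph[1L, col]; s <- ph[2L, col]
      }
      A[2L * j - 1L, i] <- g
      A[2L * j, i] <- s
    }
    A[nrow(A), i] <- 1
  }
  rownames(A) <- c(as.vector(rbind(paste0("G", H), paste0("S", H))), "sum")
  colnames(A) <- vapply(set$components, `[[`, character(1L), "name")
  dup <- which(as.matrix(stats::dist(t(A))) < 1e-9 &
                 upper.tri(matrix(0, C, C)), arr.ind = TRUE)
  if (nrow(dup) > 0L) {
    stop(sprintf("components '%s' and '%s' have (near-)identical phasors",
                 colnames(A)[dup[1L, 1L]], colnames(A)[dup[1L, 2L]]),
         call. = FALSE)
  }
  A
}

#' Per-pixel photon-fraction unmixing
#'
#' Solves, at every valid pixel, the stacked linear system `A f = m` with
#' `m = [G_1, S_1, ..., G_N, S_N, 1]` (the pixel's multi-harmonic phasor
#' plus photon conservation): an exact solve when `C = 2N + 1` and `A` is
#' nonsingular, least squares when `C < 2N + 1`. With `nonneg = TRUE` a
#' nonnegative least-squares solver is used with the conservation row
#' weighted by 1000 so fractions sum to 1 within 1e-6. Fractions are photon
#' fractions (phasor mixing is intensity-weighted).
#'
#' @param field A calibrated `phasor_field` whose harmonics cover the set's.
#' @param set A `component_set`.
#' @param nonneg Enforce `f >= 0` via NNLS (default `FALSE`: negative
#'   fractions are reported as a diagnostic of poor component choices).
#' @param sum_weight Weight of the conservation row in the unconstrained
#'   solve (default 1).
#' @param on_uncalibrated `"warn"`, `"error"`, or `"none"`.
#' @return A `fraction_field`: `fractions` (`H x W x C`), `residual`
#'   (per-pixel residual norm of the stacked equations), `valid`,
#'   `intensity`, `components`, `colors`.
#' @export
unmix_field <- function(field, set, nonneg = FALSE, sum_weight = 1,
                        on_uncalibrated = c("warn", "error", "none")) {
  stopifnot(inherits(field, "phasor_field"), inherits(set, "component_set"))
  on_uncalibrated <- match.arg(on_uncalibrated)
  check_calibrated(field, on_uncalibrated)
  if (!all(set$harmonics %in% field$harmonics)) {
    stop("field harmonics do not cover the component set's harmonics",
         call. = FALSE)
  }
  A <- build_component_matrix(set, bins = field$bins,
                              correction = field$correction)
  C <- ncol(A)
  if (rcond_square(A) < 1e-12) {
    d <- as.matrix(stats::dist(t(A)))
    diag(d) <- Inf
    ij <- which(d == min(d), arr.ind = TRUE)[1L, ]
    stop(sprintf("component matrix is numerically singular (closest pair: '%s', '%s')",
                 colnames(A)[ij[1L]], colnames(A)[ij[2L]]), call. = FALSE)
  }
  # stacked measurement matrix over valid pixels
  vals <- lapply(set$harmonics, function(n) {
    sl <- harmonic_slice(field, n)
    rbind(sl$G[field$valid], sl$S[field$valid])
  })
  M <- rbind(do.call(rbind, vals), 1)
  w <- c(rep(1, nrow(M) - 1L), if (nonneg) 1e3 else sum_weight)
  Aw <- A * w
  Mw <- M * w
  P <- ncol(M)
  if (nonneg) {
    Fmat <- matrix(0, C, P)
    for (p in seq_len(P)) {
      Fmat[, p] <- pracma::lsqnonneg(Aw, Mw[, p])$x
    }
  } else if (C == nrow(A)) {
    Fmat <- solve(Aw, Mw)
  } else {
    Fmat <- qr.coef(qr(Aw), Mw)
  }
  res <- sqrt(colSums((A %*% Fmat - M)^2))
  d <- dim(field$valid)
  fr <- array(NA_real_, c(d[1L], d[2L], C))
  for (i in seq_len(C)) {
    m <- matrix(NA_real_, d[1L], d[2L])
    m[field$valid] <- Fmat[i, ]
    fr[, , i] <- m
  }
  residual <- matrix(NA_real_, d[1L], d[2L])
  residual[field$valid] <- res
  structure(
    list(fractions = fr, residual = residual, valid = field$valid,
         intensity = field$intensity,
         components = colnames(A),
         colors = vapply(set$components, `[[`, character(1L), "color")),
    class = "fraction_field"
  )
}

rcond_square <- function(A) {
  if (nrow(A) == ncol(A)) return(rcond(A))
  sv <- svd(A, nu = 0L, nv = 0L)$d
  min(sv) / max(sv)
}

#' @export
print.fraction_field <- function(x, ...) {
  cat(sprintf("<fraction_field> %d components (%s), %d valid pixels\n",
              length(x$components), paste(x$components, collapse = ", "),
              sum(x$valid)))
  invisible(x)
}

#' Ratio-metric image of two components
#'
#' Per pixel `f_i / (f_i + f_j)`; undefined (NA) where the denominator is
#' at or below 1e-12 or the pixel is invalid.
#'
#' @param fractions A `fraction_field`.
#' @param i,j Distinct component indices or names.
#' @return A numeric `H x W` matrix.
#' @export
ratio_image <- function(fractions, i, j) {
  stopifnot(inherits(fractions, "fraction_field"))
  if (is.character(i)) i <- match(i, fractions$components)
  if (is.character(j)) j <- match(j, fractions$components)
  if (is.na(i) || is.na(j) || i == j) {
    stop("`i` and `j` must be distinct valid component indices", call. = FALSE)
  }
  fi <- fractions$fractions[, , i]
  fj <- fractions$fractions[, , j]
  den <- fi + fj
  out <- fi / den
  out[!fractions$valid | is.na(den) | den <= 1e-12] <- NA_real_
  matrix(out, nrow(fractions$valid), ncol(fractions$valid))
}
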