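#' Circular phasor-space cursor
#'
#' Manual clustering selects pixels whose phasor coordinates fall inside
#' circles drawn on the phasor plot. Cursors are ordered: where cursors
#' overlap, the later-drawn cursor wins (painter's order). Containment is
#' boundary-inclusive (`distance <= r`).
#'
#' @param g,s Centre coordinates (within `[-1.5, 1.5]`).
#' @param r Radius (`> 0`).
#' @param color Cursor colour (any R colour specification).
#' @return A `phasor_cursor`.
#' @export
cursor <- function(g, s, r, color = "red") {
  if (r <= 0) stop("cursor radius must be > 0", call. = FALSE)
  if (abs(g) > 1.5 || abs(s) > 1.5) {
    stop("cursor centre must lie within [-1.5, 1.5]^2", call. = FALSE)
  }
  structure(list(g = g, s = s, r = r, color = color), class = "phasor_cursor")
}

#' Label image pixels by phasor-space cursors
#'
#' Each valid pixel gets the order index of the last cursor containing its
#' phasor; pixels in no cursor, and invalid pixels, get label 0.
#'
#' @param field A `phasor_field`.
#' @param cursors A list of [cursor()] objects (draw order).
#' @param harmonic Harmonic whose coordinates are tested.
#' @return An integer `H x W` label image with attribute `"colors"`.
#' @export
select_by_cursors <- function(field, cursors, harmonic = 1L) {
  stopifnot(inherits(field, "phasor_field"))
  if (inherits(cursors, "phasor_cursor")) cursors <- list(cursors)
  if (length(cursors) == 0L) stop("`cursors` must be non-empty", call. = FALSE)
  sl <- harmonic_slice(field, harmonic)
  labels <- matrix(0L, nrow(field$valid), ncol(field$valid))
  for (i in seq_along(cursors)) {
    cu <- cursors[[i]]
    inside <- field$valid &
      (sl$G - cu$g)^2 + (sl$S - cu$s)^2 <= cu$r^2
    inside[is.na(inside)] <- FALSE
    labels[inside] <- i
  }
  attr(labels, "colors") <- vapply(cursors, function(cu) cu$color, character(1L))
  labels
}

#' Reciprocal selection: image region to phasor bins
#'
#' The reciprocity principle maps selections between image space and phasor
#' space. Given an image-space region, this returns the phasor-histogram bin
#' mask marking exactly the bins that contain at least one valid pixel of
#' the region (the batch counterpart of hover inspection).
#'
#' @param field A `phasor_field`.
#' @param region Logical `H x W` image.
#' @param harmonic Harmonic to use.
#' @param resolution,extent Histogram grid (see [phasor_histogram()]).
#' @return A logical `resolution x resolution` bin mask (rows index S,
#'   columns index G, both ascending).
#' @export
reciprocal_select <- function(field, region, harmonic = 1L,
                              resolution = 256L, extent = c(-1, 1, -1, 1)) {
  stopifnot(inherits(field, "phasor_field"))
  if (!identical(dim(region), dim(field$valid))) {
    stop("region shape does not match the field", call. = FALSE)
  }
  sub <- field
  sub$valid <- field$valid & region
  h <- phasor_histogram(sub, harmonic, resolution, extent)
  h$counts > 0L
}
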