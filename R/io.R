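#' Read a photon-count stack from disk
#'
#' Supported layouts:
#' * multi-page grayscale TIFF (`.tif`/`.tiff`), one page per bin, all pages
#'   the same size, non-negative integer counts;
#' * CSV/TSV decay or spectral trace (`.csv`/`.txt`): two columns
#'   `bin_index, count` (header optional, separator sniffed), promoted to a
#'   `B x 1 x 1` stack.
#'
#' Acquisition metadata must be supplied: `frequency` for lifetime data or
#' `lambda_range` for spectral data. A JSON sidecar written by
#' [write_stack()] (same path + `.json`) is honoured when present.
#'
#' @param path File path.
#' @param frequency Laser repetition frequency in Hz (lifetime stacks).
#' @param lambda_range `c(lambda0, lambda1)` in nm (spectral stacks).
#' @return A [decay_stack()] or [spectral_stack()].
#' @export
read_stack <- function(path, frequency = NULL, lambda_range = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(frequency) && !is.null(meta$frequency)) frequency <- meta$frequency
    if (is.null(lambda_range) && !is.null(meta$lambda_range)) lambda_range <- meta$lambda_range
    scale <- if (is.null(meta$count_scale)) 1 else meta$count_scale
  } else {
    scale <- 1
  }
  ext <- tolower(tools::file_ext(path))
  counts <- if (ext %in% c("tif", "tiff")) {
    read_stack_tiff(path, scale)
  } else {
    read_trace(path)
  }
  if (any(counts < 0)) stop("stack contains negative counts", call. = FALSE)
  if (!is.null(frequency)) {
    decay_stack(counts, frequency)
  } else if (!is.null(lambda_range)) {
    spectral_stack(counts, lambda_range)
  } else {
    stop("metadata missing: supply `frequency` (lifetime) or `lambda_range` (spectral)",
         call. = FALSE)
  }
}

read_stack_tiff <- function(path, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = scale == 1)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L) stop("stack TIFF must have >= 2 pages", call. = FALSE)
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1L) stop("ragged TIFF: pages differ in size", call. = FALSE)
  d <- dims[[1L]]
  if (length(d) != 2L) stop("stack TIFF pages must be single-channel grayscale",
                            call. = FALSE)
  counts <- array(0, c(length(pages), d[1L], d[2L]))
  for (b in seq_along(pages)) {
    counts[b, , ] <- if (scale == 1) pages[[b]] else round(pages[[b]] * scale)
  }
  counts
}

# Two-column bin,count text trace; separator sniffed (comma or tab),
# header optional.
read_trace <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  has_header <- !grepl("^[0-9eE.+-]+[,\t][0-9eE.+-]+\\s*$", first)
  df <- utils::read.table(path, sep = sep, header = has_header)
  if (ncol(df) < 2L) stop("trace must have two columns (bin, count)", call. = FALSE)
  cnt <- as.numeric(df[[2L]][order(df[[1L]])])
  array(cnt, c(length(cnt), 1L, 1L))
}

#' Write a photon-count stack to disk
#'
#' TIFF output (`.tif`): 16-bit grayscale pages when every count fits in 16
#' bits (bit-exact roundtrip), otherwise 32-bit float pages holding
#' `counts / 2^24` with the scale recorded in the JSON sidecar (exact for
#' counts below 2^24 after rounding on read). CSV output (`.csv`): a
#' two-column `bin,count` trace (single-pixel stacks only). A sidecar
#' `<path>.json` stores the acquisition metadata.
#'
#' @param stack A [decay_stack()] or [spectral_stack()].
#' @param path Output path (`.tif` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "photon_stack"))
  ext <- tolower(tools::file_ext(path))
  d <- dim(stack$counts)
  meta <- list(
    frequency = stack$frequency, lambda_range = stack$lambda_range,
    bins = d[1L], count_scale = 1
  )
  if (ext == "csv") {
    if (d[2L] != 1L || d[3L] != 1L) {
      stop("CSV traces hold a single pixel; use TIFF for images", call. = FALSE)
    }
    utils::write.csv(
      data.frame(bin = seq_len(d[1L]) - 1L, count = as.vector(stack$counts)),
      path, row.names = FALSE, quote = FALSE
    )
  } else {
    mx <- max(stack$counts)
    if (mx < 2^16 && all(stack$counts == round(stack$counts))) {
      pages <- lapply(seq_len(d[1L]), function(b) {
        matrix(stack$counts[b, , ], d[2L], d[3L]) / (2^16 - 1)
      })
      tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    } else {
      if (mx >= 2^24) {
        stop("counts >= 2^24 cannot be stored losslessly; rebin or split",
             call. = FALSE)
      }
      meta$count_scale <- 2^24
      pages <- lapply(seq_len(d[1L]), function(b) {
        matrix(stack$counts[b, , ], d[2L], d[3L]) / 2^24
      })
      tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    }
  }
  jsonlite::write_json(drop_null(meta), paste0(path, ".json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(path)
}

drop_null <- function(x) x[!vapply(x, is.null, logical(1L))]

#' Multi-harmonic phasor container ("ref" dialect)
#'
#' `write_ref()` stores a phasor field as raw little-endian 32-bit float
#' planes in the order: intensity, then per harmonic `1..N` a phase plane in
#' degrees and a modulation plane (plane count `1 + 2N`). Invalid pixels are
#' stored as phase 0, modulation 0 and flagged invalid on read. A JSON
#' sidecar (`<path>.json`) records width, height, harmonic count, laser
#' frequency and the dialect version. This container is this package's own
#' documented dialect; byte-level compatibility with legacy software is not
#' guaranteed.
#'
#' @param field A `phasor_field` with contiguous harmonics `1..N`.
#' @param path Output path (conventionally `.ref`).
#' @return `write_ref`: `path` invisibly. `read_ref`: the reconstructed
#'   `phasor_field` (G/S recovered from phase/modulation to float32
#'   precision).
#' @export
write_ref <- function(field, path) {
  stopifnot(inherits(field, "phasor_field"))
  N <- length(field$harmonics)
  if (!identical(field$harmonics, 1:N)) {
    stop("ref container requires contiguous harmonics 1..N", call. = FALSE)
  }
  d <- dim(field$intensity)
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(m) writeBin(as.numeric(m), con, size = 4L,
                              endian = "little")
  put(field$intensity)
  for (j in seq_len(N)) {
    g <- field$G[, , j]
    s <- field$S[, , j]
    phi <- atan2(s, g) * 180 / pi
    mod <- sqrt(g^2 + s^2)
    phi[!field$valid | is.na(phi)] <- 0
    mod[!field$valid | is.na(mod)] <- 0
    put(phi)
    put(mod)
  }
  jsonlite::write_json(
    drop_null(list(width = d[2L], height = d[1L], harmonics = N,
                   frequency = field$frequency, bins = field$bins,
                   domain = field$domain, dialect = "phasorlab-ref-1")),
    paste0(path, ".json"), digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_ref
#' @export
read_ref <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  h <- meta$height; w <- meta$width; N <- meta$harmonics
  npix <- h * w
  con <- file(path, "rb")
  on.exit(close(con))
  total <- (1 + 2 * N) * npix
  vals <- readBin(con, numeric(), n = total + 1L, size = 4L, endian = "little")
  if (length(vals) != total) {
    stop(sprintf("ref container has %d values, expected %d (1 + 2N planes)",
                 length(vals), total), call. = FALSE)
  }
  intensity <- matrix(vals[seq_len(npix)], h, w)
  G <- array(NA_real_, c(h, w, N))
  S <- array(NA_real_, c(h, w, N))
  valid <- intensity > 0
  off <- npix
  for (j in seq_len(N)) {
    phi <- matrix(vals[off + seq_len(npix)], h, w) * pi / 180
    off <- off + npix
    mod <- matrix(vals[off + seq_len(npix)], h, w)
    off <- off + npix
    valid <- valid & !(phi == 0 & mod == 0)
    G[, , j] <- mod * cos(phi)
    S[, , j] <- mod * sin(phi)
  }
  for (j in seq_len(N)) {
    g <- G[, , j]; g[!valid] <- NA_real_; G[, , j] <- g
    s <- S[, , j]; s[!valid] <- NA_real_; S[, , j] <- s
  }
  new_phasor_field(
    G = G, S = S, intensity = intensity, valid = valid,
    harmonics = 1:N,
    bins = if (is.null(meta$bins)) NA_integer_ else meta$bins,
    frequency = meta$frequency,
    domain = if (is.null(meta$domain)) "lifetime" else meta$domain,
    calibrated = TRUE
  )
}

#' Export per-pixel component fractions as a spreadsheet
#'
#' One row per valid pixel: `row`, `col` (0-based), `intensity`, then one
#' fraction column per component. RFC-4180 CSV with a header row.
#'
#' @param fractions A `fraction_field` from [unmix_field()].
#' @param path Output CSV path; `NULL` returns the data frame only.
#' @return The exported data frame, invisibly when written.
#' @export
export_fraction_table <- function(fractions, path = NULL) {
  stopifnot(inherits(fractions, "fraction_field"))
  valid <- fractions$valid
  idx <- which(valid, arr.ind = TRUE)
  C <- dim(fractions$fractions)[3L]
  df <- data.frame(row = idx[, 1L] - 1L, col = idx[, 2L] - 1L,
                   intensity = fractions$intensity[valid])
  for (i in seq_len(C)) {
    df[[fractions$components[i]]] <- matrix(fractions$fractions[, , i],
                                            nrow(valid), ncol(valid))[valid]
  }
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    return(invisible(df))
  }
  df
}

#' Export a colour-coded image
#'
#' Three colouring modes (Fig.-style exports for cursors, clustering and
#' unmixing results):
#' * `hard`: every pixel of label `L` gets exactly `colors[L]`; label 0 /
#'   invalid pixels are black.
#' * `soft`: the label colour is weighted by `intensity / max(intensity)`
#'   (after `log1p` when `intensity_scale = "log"`).
#' * `component`: linear addition of component colours weighted by their
#'   fraction images, times the intensity weight.
#'
#' 8-bit channels are rounded half away from zero.
#'
#' @param path Output path (`.png` or `.tif`); `NULL` to only return the
#'   image.
#' @param labels Integer label image (`hard`/`soft` modes; 0 = unassigned).
#' @param fractions A `fraction_field` or `H x W x C` array (`component`
#'   mode).
#' @param colors Colours, one per label value / component: any R colour
#'   specification or an `n x 3` 0–255 RGB matrix.
#' @param intensity Intensity image (`soft`/`component` modes).
#' @param mode `"hard"`, `"soft"` or `"component"`.
#' @param intensity_scale `"linear"` or `"log"`.
#' @return The `H x W x 3` `rgb_image` (0–255), invisibly when written.
#' @export
export_colored_image <- function(path = NULL, labels = NULL, fractions = NULL,
                                 colors, intensity = NULL,
                                 mode = c("hard", "soft", "component"),
                                 intensity_scale = c("linear", "log")) {
  mode <- match.arg(mode)
  intensity_scale <- match.arg(intensity_scale)
  cols <- as_rgb_matrix(colors)
  if (mode %in% c("soft", "component")) {
    if (is.null(intensity)) stop("`intensity` required for this mode", call. = FALSE)
    wimg <- if (intensity_scale == "log") log1p(intensity) else intensity
    mw <- max(wimg)
    wimg <- if (mw > 0) wimg / mw else wimg * 0
  }
  if (mode %in% c("hard", "soft")) {
    if (is.null(labels)) stop("`labels` required", call. = FALSE)
    labs <- sort(unique(as.vector(labels)))
    labs <- labs[labs > 0L]
    if (length(labs) > 0 && max(labs) > nrow(cols)) {
      stop(sprintf("no colour for label %d", max(labs)), call. = FALSE)
    }
    img <- array(0, c(nrow(labels), ncol(labels), 3L))
    for (ch in 1:3) {
      m <- matrix(0, nrow(labels), ncol(labels))
      pos <- labels > 0L
      m[pos] <- cols[labels[pos], ch]
      if (mode == "soft") m <- m * wimg
      img[, , ch] <- m
    }
  } else {
    fr <- if (inherits(fractions, "fraction_field")) fractions$fractions else fractions
    if (is.null(fr)) stop("`fractions` required for component mode", call. = FALSE)
    C <- dim(fr)[3L]
    if (C > nrow(cols)) stop("need one colour per component", call. = FALSE)
    img <- array(0, c(dim(fr)[1L], dim(fr)[2L], 3L))
    for (ch in 1:3) {
      m <- matrix(0, dim(fr)[1L], dim(fr)[2L])
      for (i in seq_len(C)) {
        fi <- matrix(fr[, , i], dim(fr)[1L], dim(fr)[2L])
        fi[is.na(fi)] <- 0
        m <- m + fi * cols[i, ch]
      }
      img[, , ch] <- m * wimg
    }
  }
  img <- round_half_away(pmin(pmax(img, 0), 255))
  img <- structure(img, class = "rgb_image")
  if (!is.null(path)) {
    write_rgb_image(img, path)
    return(invisible(img))
  }
  img
}

as_rgb_matrix <- function(colors) {
  if (is.matrix(colors)) {
    stopifnot(ncol(colors) == 3L, all(colors >= 0), all(colors <= 255))
    return(colors)
  }
  t(grDevices::col2rgb(colors))
}

#' Write an RGB image to PNG or single-page TIFF
#' @param img An `rgb_image` (`H x W x 3`, 0–255) or compatible array.
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(img, path) {
  arr <- unclass(img) / 255
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(arr, path, bits.per.sample = 8L)
  } else {
    png::writePNG(arr, path)
  }
  invisible(path)
}

#' Read an externally produced binary mask image
#'
#' Single-page grayscale TIFF or PNG; pixels with value > 0 are `TRUE`.
#'
#' @param path File path.
#' @return A logical matrix.
#' @export
read_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  m <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path) else png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m > 0
}
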