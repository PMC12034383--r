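#' Plot a phasor distribution with the universal circle
#'
#' Density plot of the phasor histogram with the universal semicircle
#' `S^2 = G - G^2` overlaid; optionally cluster ellipses and cursors.
#' Requires ggplot2.
#'
#' @param x A `phasor_field` or `phasor_histogram`.
#' @param harmonic Harmonic to plot (fields only).
#' @param resolution Histogram resolution (fields only).
#' @param scale `"linear"` or `"log"` density colouring.
#' @param ellipses Optional list of [cluster_ellipse()] objects to overlay.
#' @param cursors Optional list of [cursor()] objects to overlay.
#' @return A ggplot object.
#' @export
plot_phasor <- function(x, harmonic = 1L, resolution = 256L,
                        scale = c("linear", "log"),
                        ellipses = NULL, cursors = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_phasor() requires the ggplot2 package", call. = FALSE)
  }
  scale <- match.arg(scale)
  h <- if (inherits(x, "phasor_histogram")) {
    x
  } else {
    phasor_histogram(x, harmonic = harmonic, resolution = resolution,
                     scale = scale)
  }
  df <- as.data.frame(h)
  th <- seq(0, pi, length.out = 200L)
  circ <- data.frame(g = 0.5 + 0.5 * cos(th), s = 0.5 * sin(th))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = g, y = s)) +
    ggplot2::geom_raster(ggplot2::aes(fill = display)) +
    ggplot2::geom_path(data = circ, inherit.aes = FALSE,
                       ggplot2::aes(x = g, y = s),
                       linewidth = 0.3, colour = "grey30") +
    ggplot2::scale_fill_viridis_c(name = if (h$scale == "log") "log(1+n)" else "pixels") +
    ggplot2::coord_equal(xlim = h$extent[1:2], ylim = h$extent[3:4]) +
    ggplot2::labs(x = "G", y = "S",
                  title = sprintf("Phasor plot, harmonic %d", h$harmonic)) +
    ggplot2::theme_minimal()
  for (e in ellipses) {
    tt <- seq(0, 2 * pi, length.out = 181L)
    u <- e$semi_axes[1L] * cos(tt)
    v <- e$semi_axes[2L] * sin(tt)
    ed <- data.frame(
      g = e$center[1L] + u * cos(e$angle) - v * sin(e$angle),
      s = e$center[2L] + u * sin(e$angle) + v * cos(e$angle)
    )
    p <- p + ggplot2::geom_path(data = ed, inherit.aes = FALSE,
                                ggplot2::aes(x = g, y = s),
                                colour = "white", linewidth = 0.4)
  }
  for (cu in cursors) {
    tt <- seq(0, 2 * pi, length.out = 121L)
    cd <- data.frame(g = cu$g + cu$r * cos(tt), s = cu$s + cu$r * sin(tt))
    p <- p + ggplot2::geom_path(data = cd, inherit.aes = FALSE,
                                ggplot2::aes(x = g, y = s),
                                colour = cu$color, linewidth = 0.4)
  }
  p
}
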