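#' @importFrom graphics abline axis image lines points
NULL

#' @export
plot.bilayer_frame <- function(x, leaflet = "upper", ...) {
  df <- x$leaflets[[leaflet]]
  sp <- factor(df$species)
  plot(df$x, df$y, col = as.integer(sp), pch = 16, cex = 0.6, asp = 1,
       xlab = "x (nm)", ylab = "y (nm)",
       main = sprintf("%s leaflet, t = %g ns", leaflet, x$time), ...)
  invisible(x)
}

#' @export
plot.radial_profile <- function(x, ...) {
  plot(x$r, x$g, type = "l", xlab = "r (nm)", ylab = "g(r)", ...)
  abline(h = 1, lty = 3)
  invisible(x)
}

#' @export
plot.spectrum_profile <- function(x, ...) {
  plot(x$q, x$S, type = "l", xlab = "q (1/nm)", ylab = "S(q)", ...)
  abline(h = 1, lty = 3)
  invisible(x)
}

#' @export
plot.surface_grid <- function(x, ...) {
  image(x$x, x$y, x$z, xlab = "x (nm)", ylab = "y (nm)", asp = 1,
        main = "leaflet height (nm)", ...)
  invisible(x)
}

#' @export
plot.state_map <- function(x, leaflet = "upper", ...) {
  image(seq_len(nrow(x[[leaflet]])) * x$cell_size,
        seq_len(ncol(x[[leaflet]])) * x$cell_size,
        x[[leaflet]] * 1, xlab = "x (nm)", ylab = "y (nm)", asp = 1,
        main = sprintf("%s leaflet state", leaflet), ...)
  invisible(x)
}
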