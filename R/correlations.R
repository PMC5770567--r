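#' In-plane 2D radial distribution function
#'
#' Pair correlation of same-leaflet sites of the chosen species under the
#' periodic minimum image. Normalization is by ring area times the average
#' density, so a Poisson point pattern gives g(r) = 1; self-pairs are
#' excluded. In practice the unsaturated lipid is used, as it is enriched in
#' the disordered phase and lacks long-range translational order.
#'
#' @param frame a [bilayer_frame()], a list of frames (the per-frame
#'   profiles are averaged), or a data frame of `x`, `y` positions (then
#'   `box` must be given).
#' @param species species label set to include (ignored for a plain data
#'   frame).
#' @param leaflet which leaflet.
#' @param bin_width bin width in nm (default 0.1).
#' @param r_max maximum pair distance, at most `min(box)/2` (the minimum
#'   image bound); default exactly that.
#' @param box periodic box when `frame` is a plain data frame.
#' @param normalize `"ideal"` (default): ring area times average density, the
#'   textbook g(r). `"all_sites"`: additionally divide by the all-species
#'   g(r) of the same leaflet, which cancels any packing (translational
#'   order) shared by all species and isolates the composition correlation —
#'   appropriate for lattice-generated configurations, whose shell structure
#'   would otherwise alias into the species profile.
#' @return object of class `radial_profile`: data frame `r` (bin centres),
#'   `g`, `count`, with attributes `bin_width`, `n_sites`, `box`, `density`.
#' @export
rdf2d <- function(frame, species = NULL, leaflet = "upper", bin_width = 0.1,
                  r_max = NULL, box = NULL,
                  normalize = c("ideal", "all_sites")) {
  normalize <- match.arg(normalize)
  if (is.list(frame) && !is.data.frame(frame) &&
      !inherits(frame, "bilayer_frame")) {
    # list of frames: average the per-frame profiles
    profs <- lapply(frame, rdf2d, species = species, leaflet = leaflet,
                    bin_width = bin_width, r_max = r_max, box = box,
                    normalize = normalize)
    out <- profs[[1]]
    out$g <- rowMeans(do.call(cbind, lapply(profs, `[[`, "g")))
    out$count <- rowSums(do.call(cbind, lapply(profs, `[[`, "count")))
    attr(out, "n_frames") <- length(profs)
    return(out)
  }
  all_df <- NULL
  if (inherits(frame, "bilayer_frame")) {
    box <- frame$box
    all_df <- frame$leaflets[[leaflet]]
    df <- all_df
    if (!is.null(species)) df <- df[df$species %in% species, , drop = FALSE]
  } else {
    df <- as.data.frame(frame)
    if (is.null(box)) stopf("box required for plain coordinates")
  }
  if (nrow(df) < 2) stopf("need at least 2 sites of the chosen species")
  out <- cross_rdf(df[, c("x", "y")], df[, c("x", "y")], box, bin_width,
                   r_max, self = TRUE)
  if (normalize == "all_sites") {
    if (is.null(all_df) || nrow(all_df) <= nrow(df))
      return(out) # species set covers the leaflet: nothing to cancel
    ref <- cross_rdf(all_df[, c("x", "y")], all_df[, c("x", "y")], box,
                     bin_width, r_max, self = TRUE)
    out$g <- ifelse(ref$g > 0, out$g / ref$g, NA_real_)
    attr(out, "normalized_by") <- "all_sites"
  }
  out
}

# shared RDF engine; `self = TRUE` for same-set pairs (excludes i == j)
cross_rdf <- function(pa, pb, box, bin_width, r_max, self) {
  if (is.null(r_max)) r_max <- min(box) / 2
  if (r_max > min(box) / 2 + 1e-9)
    stopf("r_max exceeds min(box)/2: minimum-image distances are invalid")
  na <- nrow(pa); nb <- nrow(pb)
  dx <- min_image(outer(pa$x, pb$x, "-"), box[1])
  dy <- min_image(outer(pa$y, pb$y, "-"), box[2])
  r <- sqrt(dx^2 + dy^2)
  if (self) r[cbind(seq_len(na), seq_len(na))] <- NA
  r <- r[!is.na(r) & r <= r_max]
  breaks <- seq(0, r_max + bin_width, by = bin_width)
  breaks <- breaks[breaks <= r_max + bin_width / 2]
  counts <- hist_counts(r, breaks)
  centers <- (head(breaks, -1) + breaks[-1]) / 2
  ring <- pi * (breaks[-1]^2 - head(breaks, -1)^2)
  area <- box[1] * box[2]
  dens_b <- nb / area
  # expected pairs per bin for an ideal gas: na * dens_b * ring (ordered pairs)
  g <- counts / (na * dens_b * ring)
  out <- data.frame(r = centers, g = g, count = counts)
  attr(out, "bin_width") <- bin_width
  attr(out, "n_sites") <- c(na, nb)
  attr(out, "box") <- box
  attr(out, "density") <- dens_b
  class(out) <- c("radial_profile", "data.frame")
  out
}

hist_counts <- function(x, breaks) {
  if (!length(x)) return(numeric(length(breaks) - 1))
  tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                        left.open = TRUE) , nbins = length(breaks) - 1)
}

#' Correlation length from an exponential fit to a 2D RDF
#'
#' Fits `g(r) = a0 * exp(-r/xi) + a1` by nonlinear least squares with
#' multiple starting values for `xi`. The fit is refused (no `xi` reported)
#' when the exponential does not beat a constant model in an F-test at the
#' 5% level, or when the optimiser fails from every start — a flat profile
#' has no identifiable correlation length.
#'
#' @param profile a `radial_profile`.
#' @param fit_range `c(min, max)` in nm. The default starts at 1.0 nm, past
#'   the nearest-neighbour packing peak, and runs to the end of the profile.
#' @return object of class `correlation_fit`: list with `xi`, `a0`, `a1`,
#'   `converged`, `refused`, `p_value` (exponential vs constant),
#'   `residual_norm`, `cov` (covariance of estimates), `fit_range`, `n`.
#' @export
fit_correlation_length <- function(profile, fit_range = NULL) {
  stopifnot(inherits(profile, "radial_profile"))
  fit_range <- fit_range %||% c(1.0, max(profile$r))
  sel <- profile$r >= fit_range[1] & profile$r <= fit_range[2] &
    is.finite(profile$g)
  d <- profile[sel, ]
  if (nrow(d) < 5) stopf("need at least 5 bins in the fit range")

  rss0 <- sum((d$g - mean(d$g))^2)
  best <- NULL
  for (xi0 in c(0.5, 1, 2, 5, 10, 0.25 * diff(range(d$r)))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(g ~ a0 * exp(-r / xi) + a1, data = d,
                        start = list(a0 = max(d$g) - min(d$g) + 0.1,
                                     xi = xi0, a1 = min(d$g)),
                        lower = c(-Inf, 1e-6, -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(structure(list(xi = NA_real_, a0 = NA_real_, a1 = NA_real_,
                          converged = FALSE, refused = TRUE,
                          p_value = NA_real_, residual_norm = NA_real_,
                          cov = NULL, fit_range = fit_range, n = nrow(d)),
                     class = "correlation_fit"))
  }
  co <- coef(best$fit)
  n <- nrow(d)
  # F-test: does the exponential (3 params) beat the constant (1 param)?
  fstat <- ((rss0 - best$rss) / 2) / (best$rss / (n - 3))
  pval <- pf(fstat, 2, n - 3, lower.tail = FALSE)
  refused <- !is.finite(pval) || pval > 0.05 || co[["a0"]] <= 0
  cov <- tryCatch(stats::vcov(best$fit), error = function(e) NULL)
  structure(list(xi = if (refused) NA_real_ else co[["xi"]],
                 a0 = co[["a0"]], a1 = co[["a1"]],
                 converged = TRUE, refused = refused, p_value = pval,
                 residual_norm = sqrt(best$rss),
                 cov = cov, fit_range = fit_range, n = n),
            class = "correlation_fit")
}

#' @export
print.correlation_fit <- function(x, ...) {
  if (x$refused) {
    cat("<correlation_fit> refused (no identifiable exponential decay)\n")
  } else {
    cat(sprintf("<correlation_fit> xi = %.3f nm (a0 = %.3f, a1 = %.3f, p = %.2g)\n",
                x$xi, x$a0, x$a1, x$p_value))
  }
  invisible(x)
}

# Decay-shape comparison for the phase classifier: linear versus
# exponential decay pinned to the profile's tail level, both with equal
# parameter count, restricted to the monotone decay segment (from r_min to
# the running minimum of the lightly smoothed profile). One-phase profiles
# decay exponentially toward the uncorrelated tail level; phase-separated
# profiles cross below it on the way to the inter-domain undulation, which
# the pinned exponential cannot follow but a line can.
compare_decay_models <- function(profile, r_min = 0.8) {
  stopifnot(inherits(profile, "radial_profile"))
  ok <- is.finite(profile$g)
  gg <- profile$g[ok]; r <- profile$r[ok]
  rmax <- max(r)
  tail_lvl <- mean(gg[r > 0.8 * rmax])
  sm <- as.numeric(stats::filter(gg, rep(1 / 3, 3), sides = 2))
  sm[is.na(sm)] <- gg[is.na(sm)]
  end <- which.min(sm)
  sel <- which(r <= r[end] & r >= r_min)
  d <- data.frame(r = r[sel], g = gg[sel])
  n <- nrow(d)
  if (n < 5) {
    return(list(decided = FALSE, linear_preferred = FALSE,
                aicc_linear = NA_real_, aicc_exponential = NA_real_,
                segment = c(NA_real_, NA_real_), tail_level = tail_lvl,
                reason = "no resolvable decay segment"))
  }
  lf <- lm(g ~ r, data = d)
  rss_l <- sum(stats::resid(lf)^2)
  ef <- tryCatch(
    minpack.lm::nlsLM(g ~ a0 * exp(-r / xi) + tail_lvl, data = d,
                      start = list(a0 = max(d$g) - tail_lvl + 0.1, xi = 2),
                      lower = c(1e-6, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  rss_e <- if (is.null(ef)) Inf else sum(stats::resid(ef)^2)
  aicc_l <- aicc_from_rss(rss_l, n, 3)
  aicc_e <- if (is.finite(rss_e)) aicc_from_rss(rss_e, n, 3) else Inf
  list(decided = TRUE, linear_preferred = aicc_l < aicc_e,
       aicc_linear = aicc_l, aicc_exponential = aicc_e,
       segment = range(d$r), tail_level = tail_lvl,
       linear_slope = coef(lf)[[2]], n = n)
}

# small-sample-corrected information criterion from a residual sum of squares
aicc_from_rss <- function(rss, n, k) {
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / max(1, n - k - 1)
}

#' In-plane 2D static structure factor
#'
#' `S(q) = |sum_n exp(-i q . r_n)|^2 / N` evaluated on the wave-vector grid
#' commensurate with the box, `q = 2*pi*(j/Lx, k/Ly)`, then averaged over the
#' polar angle in radial bins one grid step wide. The q = 0 term (which is
#' just N) is excluded from the radial profile. A peak at q corresponds to a
#' real-space period of `2*pi/q`; the q resolution is set by the inverse box
#' size, `dq = 2*pi/L`.
#'
#' @inheritParams rdf2d
#' @param max_modes largest Fourier index per axis (default 40, i.e. features
#'   down to L/40).
#' @return object of class `spectrum_profile`: data frame `q`, `S`, `count`
#'   with attributes `S2d` (full 2D grid), `qx`, `qy`, `dq`.
#' @export
structure_factor <- function(frame, species = NULL, leaflet = "upper",
                             max_modes = 40, box = NULL) {
  if (inherits(frame, "bilayer_frame")) {
    box <- frame$box
    df <- frame$leaflets[[leaflet]]
    if (!is.null(species)) df <- df[df$species %in% species, , drop = FALSE]
  } else {
    df <- as.data.frame(frame)
    if (is.null(box)) stopf("box required for plain coordinates")
  }
  if (nrow(df) < 2) stopf("need at least 2 sites of the chosen species")
  n <- nrow(df)
  jj <- -max_modes:max_modes
  qx <- 2 * pi * jj / box[1]
  qy <- 2 * pi * jj / box[2]
  # separable phase sums: F[a,b] = sum_n exp(-i qx_a x_n) exp(-i qy_b y_n)
  Ax <- exp(-1i * outer(qx, df$x))
  Ay <- exp(-1i * outer(qy, df$y))
  FF <- Ax %*% t(Ay) # plain (non-conjugate) transpose: sums over particles
  S2 <- Mod(FF)^2 / n

  qmag <- sqrt(outer(qx^2, qy^2, "+"))
  dq <- max(2 * pi / box[1], 2 * pi / box[2])
  keep <- qmag > 0
  bins <- ceiling(qmag[keep] / dq)
  S <- tapply(S2[keep], bins, mean)
  cnt <- tapply(S2[keep], bins, length)
  centers <- (as.integer(names(S)) - 0.5) * dq
  out <- data.frame(q = centers, S = as.numeric(S), count = as.integer(cnt))
  out <- out[out$q <= max_modes * dq, , drop = FALSE]
  attr(out, "S2d") <- S2
  attr(out, "qx") <- qx
  attr(out, "qy") <- qy
  attr(out, "dq") <- dq
  attr(out, "n_sites") <- n
  class(out) <- c("spectrum_profile", "data.frame")
  out
}

# FFT cross-check of the structure factor for points sitting on the nodes of
# an nx x ny grid: the squared modulus of the DFT of the gridded point
# density equals the direct sum on commensurate wave vectors.
structure_factor_fft <- function(pts, box, nx, ny) {
  gx <- floor(pts$x / box[1] * nx + 0.5) %% nx
  gy <- floor(pts$y / box[2] * ny + 0.5) %% ny
  cnt <- matrix(0, nx, ny)
  for (i in seq_len(nrow(pts))) {
    cnt[gx[i] + 1, gy[i] + 1] <- cnt[gx[i] + 1, gy[i] + 1] + 1
  }
  Mod(fft(cnt))^2 / nrow(pts)
}

#' Correlation time of the local density
#'
#' Samples the per-species site count on a regular grid for a sequence of
#' closely spaced frames, computes the cell-averaged autocorrelation of the
#' density fluctuations (normalized to 1 at zero lag), and fits a single
#' exponential decay `C(t) = exp(-t/tau)`. The fit is refused when there is
#' no decay to fit: a static sequence (C stays at 1; `tau` flagged infinite)
#' or an uncorrelated one (C drops below noise at the first lag; `tau`
#' unresolved below the frame spacing).
#'
#' @param frames list of [bilayer_frame()] objects (equally spaced in time),
#'   or a [generate_brownian_trajectory()] result.
#' @param species optional species subset.
#' @param leaflet which leaflet (for frames).
#' @param grid grid dimensions (default `c(20, 20)`).
#' @param n_lags number of lags for the fit (default 9, i.e. 10 frames).
#' @return object of class `correlation_time`: list with `tau` (same units
#'   as the frame times), `status` (`"ok"`, `"static"`, `"unresolved"`,
#'   `"refused"`), `C` (autocorrelation), `lags`, `dt`.
#' @export
density_time_correlation <- function(frames, species = NULL,
                                     leaflet = "upper", grid = c(20, 20),
                                     n_lags = 9) {
  if (inherits(frames, "brownian_traj")) {
    box <- frames$box
    times <- frames$times
    pts <- traj_frames(frames)
  } else {
    box <- frames[[1]]$box
    times <- vapply(frames, function(f) f$time, numeric(1))
    pts <- lapply(frames, function(f) f$leaflets[[leaflet]])
  }
  if (!is.null(species))
    pts <- lapply(pts, function(p) p[p$species %in% species, , drop = FALSE])
  nf <- length(pts)
  if (nf < n_lags + 1) stopf("need at least n_lags + 1 frames")
  dts <- diff(times)
  dt <- mean(dts)
  if (any(abs(dts - dt) > 1e-6 * max(dt, 1)))
    stopf("frames must be equally spaced in time")

  nx <- grid[1]; ny <- grid[2]
  dens <- vapply(pts, function(p) {
    gx <- pmin(nx - 1, floor(p$x / box[1] * nx))
    gy <- pmin(ny - 1, floor(p$y / box[2] * ny))
    tabulate(gx + nx * gy + 1, nbins = nx * ny)
  }, numeric(nx * ny))
  # dens: (cells) x (frames); remove per-cell mean
  dn <- dens - rowMeans(dens)
  denom <- sum(dn^2) / nf
  if (denom < 1e-12) {
    return(structure(list(tau = Inf, status = "static",
                          C = rep(1, n_lags + 1), lags = 0:n_lags, dt = dt),
                     class = "correlation_time"))
  }
  C <- vapply(0:n_lags, function(l) {
    a <- dn[, seq_len(nf - l), drop = FALSE]
    b <- dn[, seq_len(nf - l) + l, drop = FALSE]
    sum(a * b) / (nf - l)
  }, numeric(1))
  C <- C / C[1]
  if (all(abs(C) == 1)) {
    return(structure(list(tau = Inf, status = "static", C = C,
                          lags = 0:n_lags, dt = dt),
                     class = "correlation_time"))
  }
  if (C[2] < 0.05) {
    return(structure(list(tau = NA_real_, status = "unresolved", C = C,
                          lags = 0:n_lags, dt = dt),
                     class = "correlation_time"))
  }
  # single exponential through C(0) = 1: log-linear fit on the positive lags
  # (log scale keeps the whole decay informative, not just the first lags)
  pos <- which(C[-1] > 0.05)
  if (length(pos) < 2) {
    return(structure(list(tau = NA_real_, status = "refused", C = C,
                          lags = 0:n_lags, dt = dt),
                     class = "correlation_time"))
  }
  tt <- pos * dt
  slope <- sum(tt * log(C[pos + 1])) / sum(tt^2)
  if (slope >= 0) {
    return(structure(list(tau = NA_real_, status = "refused", C = C,
                          lags = 0:n_lags, dt = dt),
                     class = "correlation_time"))
  }
  structure(list(tau = -1 / slope, status = "ok", C = C,
                 lags = 0:n_lags, dt = dt),
            class = "correlation_time")
}

#' @export
print.correlation_time <- function(x, ...) {
  cat(sprintf("<correlation_time> tau = %s (%s)\n",
              format(x$tau, digits = 4), x$status))
  invisible(x)
}

#' Time-windowed 2D density maps
#'
#' Splits the trajectory into consecutive non-overlapping windows of the
#' requested duration and reports the time-averaged number density of the
#' chosen species on a regular grid for each window. Persistent domains
#' retain contrast at long windows; transient fluctuations average out.
#'
#' @param frames list of [bilayer_frame()] objects or a `brownian_traj`.
#' @param species optional species subset.
#' @param window_ns window duration in ns.
#' @param grid_spacing grid cell edge in nm.
#' @param leaflet which leaflet.
#' @return list of `density_map` objects: matrix `density` (nm^-2), with
#'   `window_start`, `window_ns`, `cell_area`.
#' @export
density_map <- function(frames, species = NULL, window_ns, grid_spacing = 1,
                        leaflet = "upper") {
  if (inherits(frames, "brownian_traj")) {
    box <- frames$box
    times <- frames$times
    pts <- traj_frames(frames)
  } else {
    box <- frames[[1]]$box
    times <- vapply(frames, function(f) f$time, numeric(1))
    pts <- lapply(frames, function(f) f$leaflets[[leaflet]])
  }
  if (!is.null(species))
    pts <- lapply(pts, function(p) p[p$species %in% species, , drop = FALSE])
  span <- max(times) - min(times)
  if (window_ns > span + 1e-9 && length(pts) > 1)
    stopf("window longer than the trajectory span")
  nx <- max(2L, round(box[1] / grid_spacing))
  ny <- max(2L, round(box[2] / grid_spacing))
  cell_area <- (box[1] / nx) * (box[2] / ny)
  wid <- if (span <= 0) rep(1L, length(pts)) else
    pmin(floor((times - min(times)) / window_ns) + 1L,
         max(1L, floor(span / window_ns)))
  lapply(sort(unique(wid)), function(w) {
    sel <- which(wid == w)
    acc <- matrix(0, nx, ny)
    for (i in sel) {
      p <- pts[[i]]
      gx <- pmin(nx - 1, floor(p$x / box[1] * nx))
      gy <- pmin(ny - 1, floor(p$y / box[2] * ny))
      acc <- acc + matrix(tabulate(gx + nx * gy + 1, nbins = nx * ny), nx, ny)
    }
    structure(list(density = acc / length(sel) / cell_area,
                   window_start = min(times) + (w - 1) * window_ns,
                   window_ns = window_ns, cell_area = cell_area,
                   n_frames = length(sel)),
              class = "density_map")
  })
}

#' Contrast of a density map
#'
#' Max-to-mean ratio of the cell densities; 1 for a perfectly uniform map.
#'
#' @param map a `density_map`.
#' @return numeric contrast.
#' @export
map_contrast <- function(map) {
  d <- map$density
  max(d) / mean(d)
}
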