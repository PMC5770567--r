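#' Chain orientational order parameter
#'
#' For every internal chain site n the segment vector runs from site n-1 to
#' site n+1; its angle theta to the monolayer normal contributes
#' `(3*cos^2(theta) - 1)/2`, averaged over sites, chains and lipids.
#' Straight chains along the normal give 1, chains lying in the plane give
#' -0.5, an isotropic melt gives 0. Cholesterol has no ordinary chains and is
#' excluded by default.
#'
#' @param x a [bilayer_frame()] with chains attached, or a list of lipids
#'   (each a list of `k x 3` chain matrices) as produced by
#'   [generate_chains()].
#' @param normal_axis unit normal of the monolayer (default z).
#' @param excluded_species species labels to skip (default `"chol"`); only
#'   used when `x` is a frame.
#' @param leaflet which leaflet when `x` is a frame.
#' @return object of class `order_result`: list with `per_lipid` (numeric),
#'   `mean`, `sd`, `n_lipids`, `n_skipped` (chains with fewer than 3 sites).
#' @export
chain_order <- function(x, normal_axis = c(0, 0, 1),
                        excluded_species = "chol", leaflet = "upper") {
  if (inherits(x, "bilayer_frame")) {
    chains <- x$chains[[leaflet]]
    if (is.null(chains)) stopf("frame has no chain sites for leaflet '%s'",
                               leaflet)
    species <- x$leaflets[[leaflet]]$species
    keep <- !(species %in% excluded_species)
    chains <- chains[keep]
  } else chains <- x
  nrm <- normal_axis / sqrt(sum(normal_axis^2))
  skipped <- 0L
  per_lipid <- vapply(chains, function(lipid) {
    vals <- unlist(lapply(lipid, function(ch) {
      if (is.null(ch) || nrow(ch) < 3) {
        skipped <<- skipped + 1L
        return(NULL)
      }
      k <- nrow(ch)
      v <- ch[3:k, , drop = FALSE] - ch[1:(k - 2), , drop = FALSE]
      ct <- (v %*% nrm) / sqrt(rowSums(v^2))
      0.5 * (3 * ct^2 - 1)
    }))
    if (is.null(vals)) NA_real_ else mean(vals)
  }, numeric(1))
  per_lipid <- per_lipid[!is.na(per_lipid)]
  if (any(per_lipid < -0.5 - 1e-9 | per_lipid > 1 + 1e-9))
    stop("internal error: order parameter out of [-0.5, 1]")
  structure(list(per_lipid = per_lipid, mean = mean(per_lipid),
                 sd = if (length(per_lipid) > 1) sd(per_lipid) else NA_real_,
                 n_lipids = length(per_lipid), n_skipped = skipped),
            class = "order_result")
}

#' @export
print.order_result <- function(x, ...) {
  cat(sprintf("<order_result> S_z = %.4f (sd %.4f, n = %d, skipped %d)\n",
              x$mean, x$sd, x$n_lipids, x$n_skipped))
  invisible(x)
}

#' Fit a leaflet surface on a regular grid
#'
#' Interpolates the height of scattered leaflet reference sites onto an
#' equally spaced periodic grid (default 0.4 nm) by Gaussian-kernel weighted
#' averaging under the periodic metric, then smooths with a separable
#' binomial (1-4-6-4-1)/16 filter with periodic wrap. The filter preserves
#' constants and the grid mean; its gain at wavenumber k is cos^4(k*dx/2)
#' per pass, so long-wavelength undulations pass nearly unattenuated.
#'
#' @param sites data frame with `x`, `y`, `z` (nm), or a [bilayer_frame()]
#'   whose leaflet carries a `z` column.
#' @param box periodic in-plane box (taken from the frame if given).
#' @param grid_spacing target node spacing in nm (default 0.4; the actual
#'   spacing divides the box exactly).
#' @param smoothing_passes binomial filter passes (default 2).
#' @param bandwidth Gaussian kernel bandwidth in nm (default: the grid
#'   spacing).
#' @param leaflet which leaflet when a frame is given.
#' @return object of class `surface_grid`: list with `z` (matrix, x rows),
#'   `x`, `y` node coordinates, `dx`, `dy`, `box`, `passes`.
#' @export
fit_surface <- function(sites, box = NULL, grid_spacing = 0.4,
                        smoothing_passes = 2, bandwidth = NULL,
                        leaflet = "upper") {
  if (inherits(sites, "bilayer_frame")) {
    box <- sites$box
    sites <- sites$leaflets[[leaflet]]
  }
  stopifnot(!is.null(box))
  if (grid_spacing <= 0) stopf("grid spacing must be positive")
  if (nrow(sites) < 4) stopf("need at least 4 sites")
  if (is.null(sites$z) || anyNA(sites$z)) stopf("sites need a z coordinate")
  nx <- max(5L, round(box[1] / grid_spacing))
  ny <- max(5L, round(box[2] / grid_spacing))
  dx <- box[1] / nx; dy <- box[2] / ny
  gx <- (seq_len(nx) - 1) * dx
  gy <- (seq_len(ny) - 1) * dy
  h <- bandwidth %||% max(dx, dy)

  z <- matrix(NA_real_, nx, ny)
  ddx2 <- min_image(outer(gx, sites$x, "-"), box[1])^2
  for (j in seq_len(ny)) {
    d2 <- ddx2 + matrix(min_image(gy[j] - sites$y, box[2])^2, nx,
                        nrow(sites), byrow = TRUE)
    w <- exp(-d2 / (2 * h^2))
    w[d2 > (4 * h)^2] <- 0
    rs <- rowSums(w)
    bad <- rs <= 0
    if (any(bad)) { # fall back to the nearest site
      nearest <- max.col(-d2[bad, , drop = FALSE], ties.method = "first")
      z[bad, j] <- sites$z[nearest]
    }
    z[!bad, j] <- (w %*% sites$z)[!bad] / rs[!bad]
  }
  for (p in seq_len(smoothing_passes)) z <- binomial_smooth(z)
  structure(list(z = z, x = gx, y = gy, dx = dx, dy = dy,
                 box = as.numeric(box), passes = smoothing_passes),
            class = "surface_grid")
}

# one pass of the separable periodic 1-4-6-4-1 binomial filter
binomial_smooth <- function(z) {
  k <- c(1, 4, 6, 4, 1) / 16
  sm_axis <- function(m) {
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (s in -2:2) {
      idx <- ((seq_len(n) - 1 + s) %% n) + 1
      out <- out + k[s + 3] * m[idx, , drop = FALSE]
    }
    out
  }
  t(sm_axis(t(sm_axis(z))))
}

#' Principal and mean curvature of a gridded surface
#'
#' Monge-gauge curvature from central finite differences with periodic wrap:
#' first and second fundamental forms give the shape operator, whose
#' eigenvalues are the principal curvatures `c1 >= c2`; the mean curvature is
#' `H = (c1 + c2)/2`. Sign convention: a surface bulging toward +z has
#' positive H (so flipping z negates H everywhere).
#'
#' @param surface a [fit_surface()] result or a [generate_surface()] list
#'   (must expose `z`, and spacings `dx`, `dy` or `grid_spacing`).
#' @return object of class `curvature_field`: list with matrices `H`, `c1`,
#'   `c2`, `K` (Gaussian curvature), all in nm^-1 (K in nm^-2).
#' @export
curvature <- function(surface) {
  z <- surface$z
  dx <- surface$dx %||% surface$grid_spacing[1]
  dy <- surface$dy %||% surface$grid_spacing[2]
  if (nrow(z) < 5 || ncol(z) < 5) stopf("grid must be at least 5 x 5")
  sh <- function(m, i, j) {
    n <- nrow(m); p <- ncol(m)
    m[((seq_len(n) - 1 + i) %% n) + 1, ((seq_len(p) - 1 + j) %% p) + 1,
      drop = FALSE]
  }
  zx <- (sh(z, 1, 0) - sh(z, -1, 0)) / (2 * dx)
  zy <- (sh(z, 0, 1) - sh(z, 0, -1)) / (2 * dy)
  zxx <- (sh(z, 1, 0) - 2 * z + sh(z, -1, 0)) / dx^2
  zyy <- (sh(z, 0, 1) - 2 * z + sh(z, 0, -1)) / dy^2
  zxy <- (sh(z, 1, 1) - sh(z, 1, -1) - sh(z, -1, 1) + sh(z, -1, -1)) /
    (4 * dx * dy)
  W2 <- 1 + zx^2 + zy^2
  # upward-normal Monge forms; sign flipped so bulging toward +z is positive
  H <- -((1 + zy^2) * zxx - 2 * zx * zy * zxy + (1 + zx^2) * zyy) /
    (2 * W2^1.5)
  K <- (zxx * zyy - zxy^2) / W2^2
  disc <- sqrt(pmax(0, H^2 - K))
  structure(list(H = H, c1 = H + disc, c2 = H - disc, K = K,
                 dx = dx, dy = dy),
            class = "curvature_field")
}

#' Lateral diffusion coefficients from mean squared displacement
#'
#' Einstein relation on the in-plane MSD of unwrapped coordinates:
#' `MSD(dt) = 4*D*dt` for 2D Brownian motion. The MSD is averaged over
#' particles and (strided) time origins, and D is the slope of a linear fit
#' over a configurable lag window (default the middle third of lags, past
#' short-time noise and before the poorly averaged long lags), divided by 4.
#'
#' @param traj a [generate_brownian_trajectory()] result, or a list with
#'   `unwrapped` (`n x 2 x n_frames` array in nm), `species`, `times` (ns).
#' @param species optional species subset (default: all, reported per
#'   species).
#' @param fit_window fraction range of lags used for the fit.
#' @param max_lags maximum number of distinct lags evaluated (default 100).
#' @param max_lag_fraction largest lag as a fraction of the trajectory length
#'   (default 1/3; longer lags average over too few independent intervals).
#' @return data frame `species`, `D` (cm^2/s), `slope` (nm^2/ns),
#'   `intercept`, `r_squared`, with the lag MSD curves as attribute `msd`.
#' @export
lateral_diffusion <- function(traj, species = NULL,
                              fit_window = c(1 / 3, 2 / 3), max_lags = 100,
                              max_lag_fraction = 1 / 3) {
  un <- traj$unwrapped
  if (is.null(un))
    stopf(paste("unwrapped coordinates required: wrapped-only input cannot",
                "be used — unwrap the trajectory first"))
  times <- traj$times
  nf <- dim(un)[3]
  if (nf < 10) stopf("need at least 10 frames")
  spp <- species %||% sort(unique(traj$species))
  top_lag <- max(3L, floor((nf - 1) * max_lag_fraction))
  lags <- unique(round(seq(1, top_lag, length.out = min(max_lags, top_lag))))
  origin_stride <- max(1L, (nf - 1L) %/% 64L)

  msd_for <- function(idx) {
    vapply(lags, function(l) {
      orig <- seq(1, nf - l, by = origin_stride)
      tot <- 0
      for (o in orig) {
        d <- un[idx, , o + l] - un[idx, , o]
        tot <- tot + mean(rowSums(matrix(d, ncol = 2)^2))
      }
      tot / length(orig)
    }, numeric(1))
  }

  dtlag <- lags * mean(diff(times))
  sel <- seq(max(1, ceiling(fit_window[1] * length(lags))),
             max(2, floor(fit_window[2] * length(lags))))
  msd_tab <- list()
  out <- do.call(rbind, lapply(spp, function(s) {
    idx <- which(traj$species == s)
    m <- msd_for(idx)
    msd_tab[[s]] <<- data.frame(lag_ns = dtlag, msd = m)
    if (all(m == 0)) {
      return(data.frame(species = s, D = 0, slope = 0, intercept = 0,
                        r_squared = NA_real_))
    }
    fit <- lm(m[sel] ~ dtlag[sel])
    data.frame(species = s, D = coef(fit)[[2]] / 4 * 1e-5,
               slope = coef(fit)[[2]], intercept = coef(fit)[[1]],
               r_squared = summary(fit)$r.squared)
  }))
  rownames(out) <- NULL
  attr(out, "msd") <- msd_tab
  out
}
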