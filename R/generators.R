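#' Generate chain-site sets with a prescribed orientational order parameter
#'
#' Builds straight hydrocarbon chains whose segment vectors have a population
#' mean of the second Legendre polynomial, `P2 = (3*cos^2(theta) - 1)/2`,
#' equal to `target_Sz`. Orientations are drawn from a mixture of a perfectly
#' aligned (or perfectly in-plane) component and an isotropic component whose
#' weight is solved so the expectation is exact; the sample mean then
#' converges to the target at the Monte Carlo rate.
#'
#' @param n_lipids number of lipids (each gets `chains_per_lipid` chains).
#' @param target_Sz target order parameter in `[-0.5, 1]`.
#' @param sites_per_chain chain sites per chain (>= 3).
#' @param seed integer seed.
#' @param chains_per_lipid chains per lipid (default 2).
#' @param bond_length chain bond length in nm (default 0.47, a coarse-grained
#'   bond).
#' @return list of lipids; each lipid is a list of `sites_per_chain x 3` chain
#'   matrices. Suitable as the `chains` entry of a leaflet or directly for
#'   [chain_order()].
#' @export
generate_chains <- function(n_lipids, target_Sz, sites_per_chain = 5,
                            seed = 1, chains_per_lipid = 2,
                            bond_length = 0.47) {
  if (target_Sz < -0.5 || target_Sz > 1)
    stopf("target_Sz must be in [-0.5, 1]")
  if (sites_per_chain < 3) stopf("sites_per_chain must be >= 3")
  n_chains <- n_lipids * chains_per_lipid
  with_seed(seed, {
    if (target_Sz >= 0) {
      # aligned fraction p, isotropic rest: E[P2] = p*1 + (1-p)*0. The
      # aligned count is deterministic so only the isotropic part adds
      # sampling noise.
      p <- target_Sz
      n_fix <- round(p * n_chains)
      cost <- c(rep(1, n_fix), runif(n_chains - n_fix, -1, 1))
    } else {
      # in-plane fraction p, isotropic rest: E[P2] = -p/2
      p <- -2 * target_Sz
      n_fix <- round(p * n_chains)
      cost <- c(rep(0, n_fix), runif(n_chains - n_fix, -1, 1))
    }
    cost <- sample(cost)
    phi <- runif(n_chains, 0, 2 * pi)
    sint <- sqrt(pmax(0, 1 - cost^2))
    bx <- bond_length * sint * cos(phi)
    by <- bond_length * sint * sin(phi)
    bz <- bond_length * cost
    origin <- matrix(runif(3 * n_chains, 0, 10), ncol = 3)
    ch <- 0L
    lapply(seq_len(n_lipids), function(i) {
      lapply(seq_len(chains_per_lipid), function(j) {
        ch <<- ch + 1L
        k <- seq_len(sites_per_chain) - 1
        cbind(origin[ch, 1] + k * bx[ch],
              origin[ch, 2] + k * by[ch],
              origin[ch, 3] + k * bz[ch])
      })
    })
  })
}

#' Generate an analytic height field with its closed-form mean curvature
#'
#' Produces a surface `z(x, y)` sampled on a regular grid together with the
#' exact Monge-gauge mean curvature, for validating [curvature()]. The sign
#' convention is that a surface bulging toward +z has positive mean
#' curvature.
#'
#' @param kind one of `"plane"`, `"sphere_cap"`, `"sinusoid"`.
#' @param params list of shape parameters: `z0` (baseline height, default 0);
#'   for `sphere_cap`: `radius` (nm) and optional `cap_fraction` (fraction of
#'   the radius used as the in-plane cap radius, default 0.6); for
#'   `sinusoid`: `amplitude` (nm) and `wavelength` (nm, along x).
#' @param grid_spacing nm between grid nodes.
#' @param box in-plane box `(Lx, Ly)` in nm (default `c(20, 20)`).
#' @return list with `x`, `y` (node coordinates), `z` (matrix, x indexing
#'   rows), `H_true` (analytic mean curvature, NA outside a sphere cap),
#'   `mask` (logical matrix of nodes where `H_true` is defined), `box`,
#'   `grid_spacing`.
#' @export
generate_surface <- function(kind = c("plane", "sphere_cap", "sinusoid"),
                             params = list(), grid_spacing = 0.4,
                             box = c(20, 20)) {
  kind <- match.arg(kind)
  z0 <- params$z0 %||% 0
  nx <- max(5L, round(box[1] / grid_spacing))
  ny <- max(5L, round(box[2] / grid_spacing))
  x <- (seq_len(nx) - 1) * box[1] / nx
  y <- (seq_len(ny) - 1) * box[2] / ny
  X <- matrix(x, nx, ny)
  Y <- matrix(y, nx, ny, byrow = TRUE)
  mask <- matrix(TRUE, nx, ny)
  if (kind == "plane") {
    z <- matrix(z0, nx, ny)
    H <- matrix(0, nx, ny)
  } else if (kind == "sphere_cap") {
    R <- params$radius
    if (is.null(R) || R <= 0) stopf("sphere_cap needs radius > 0")
    cf <- params$cap_fraction %||% 0.6
    cx <- box[1] / 2; cy <- box[2] / 2
    rho2 <- (X - cx)^2 + (Y - cy)^2
    rcap2 <- (cf * R)^2
    mask <- rho2 < rcap2
    z <- matrix(z0, nx, ny)
    z[mask] <- z0 + sqrt(R^2 - rho2[mask]) - sqrt(R^2 - rcap2)
    H <- matrix(NA_real_, nx, ny)
    H[mask] <- 1 / R # bulges toward +z: positive by convention
  } else {
    A <- params$amplitude %||% 0.5
    lam <- params$wavelength %||% box[1]
    k <- 2 * pi / lam
    if (A * k >= 1) stopf("sinusoid too steep: amplitude * wavenumber must be < 1")
    z <- z0 + A * sin(k * X)
    zx <- A * k * cos(k * X)
    zxx <- -A * k^2 * sin(k * X)
    H <- -zxx / (2 * (1 + zx^2)^1.5)
  }
  list(x = x, y = y, z = z, H_true = H, mask = mask, box = box,
       grid_spacing = c(box[1] / nx, box[2] / ny), kind = kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate Brownian in-plane trajectories with species-dependent diffusion
#'
#' Particles take independent 2D Gaussian steps with total step variance
#' `4 * D * dt` (Einstein relation by construction). Both wrapped and
#' unwrapped coordinates are retained; diffusion estimation uses the
#' unwrapped ones.
#'
#' @param n_per_species named integer vector, particles per species.
#' @param D_per_species named numeric vector, diffusion coefficients in
#'   cm^2/s (1e-7 cm^2/s is a typical lipid value).
#' @param dt frame interval in ns.
#' @param n_frames number of frames.
#' @param box periodic box `(Lx, Ly)` in nm.
#' @param seed integer seed.
#' @return object of class `brownian_traj`: list with `unwrapped` (array
#'   `n x 2 x n_frames`, nm), `species`, `times` (ns), `box`, and
#'   `frames()`-compatible wrapped coordinates via [traj_frames()].
#' @export
generate_brownian_trajectory <- function(n_per_species, D_per_species,
                                         dt, n_frames, box = c(50, 50),
                                         seed = 1) {
  stopifnot(length(n_per_species) == length(D_per_species),
            !is.null(names(n_per_species)))
  if (any(D_per_species < 0) || dt <= 0) stopf("need D >= 0 and dt > 0")
  n <- sum(n_per_species)
  species <- rep(names(n_per_species), n_per_species)
  # 1 cm^2/s = 1e5 nm^2/ns
  sd_axis <- sqrt(2 * rep(D_per_species, n_per_species) * 1e5 * dt)
  with_seed(seed, {
    pos0 <- cbind(runif(n, 0, box[1]), runif(n, 0, box[2]))
    un <- array(NA_real_, dim = c(n, 2, n_frames))
    un[, , 1] <- pos0
    if (n_frames > 1) {
      for (t in 2:n_frames) {
        un[, , t] <- un[, , t - 1] +
          cbind(rnorm(n, 0, sd_axis), rnorm(n, 0, sd_axis))
      }
    }
    structure(list(unwrapped = un, species = species,
                   times = (seq_len(n_frames) - 1) * dt,
                   box = as.numeric(box), seed = seed),
              class = "brownian_traj")
  })
}

#' Wrapped per-frame coordinates of a Brownian trajectory
#'
#' @param traj a [generate_brownian_trajectory()] result.
#' @return list of data frames (id, species, x, y), one per frame, wrapped
#'   into the box.
#' @export
traj_frames <- function(traj) {
  stopifnot(inherits(traj, "brownian_traj"))
  lapply(seq_along(traj$times), function(t) {
    data.frame(id = seq_along(traj$species), species = traj$species,
               x = wrap_box(traj$unwrapped[, 1, t], traj$box[1]),
               y = wrap_box(traj$unwrapped[, 2, t], traj$box[2]),
               stringsAsFactors = FALSE)
  })
}
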