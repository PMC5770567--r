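#' Parameters for the Kawasaki lattice-gas bilayer generator
#'
#' The generator emulates the lateral statistics of a two-leaflet lipid
#' mixture: species live on a triangular lattice (so that jittered Voronoi
#' cells are hexagonal, as in a fluid bilayer), demix under a like/unlike
#' contact energy, and couple across leaflets through a site-wise alignment
#' bonus on the binary ordered/disordered relabelling. Composition is strictly
#' conserved (Kawasaki nearest-neighbour exchange), as it is in a real
#' bilayer.
#'
#' @param lattice_side sites per dimension (must be even; the triangular
#'   lattice is built in alternating-row offset form).
#' @param species_fractions named nonnegative fractions summing to 1, e.g.
#'   `c(sat = 0.6, unsat = 0.4)` or `c(sat = 0.35, unsat = 0.35, chol = 0.30)`.
#' @param coupling like-unlike contact energy J in kT units (>= 0). Zero gives
#'   ideal mixing; the demixing transition for the 3:2 binary mixture sits
#'   near J ~ 0.55 (triangular-lattice Ising mapping J_c = 2*ln(3)/4 in these
#'   unlike-pair units).
#' @param interleaflet_coupling alignment bonus Lambda in kT (>= 0) favouring
#'   the same ordered/disordered state across leaflets at the same site.
#' @param sweeps Monte Carlo sweeps (one attempted exchange per site per
#'   leaflet each sweep).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param jitter positional noise amplitude in lattice units, in [0, 0.5).
#' @param lattice_spacing nm per lattice unit (default 0.8 nm gives ~0.55 nm^2
#'   per site, a realistic area per lipid).
#' @param ordered_species labels counted as "ordered" for the interleaflet
#'   term (default: every species except `"unsat"`).
#' @param chol_affinity fractional discount of the contact cost between the
#'   saturated-like and cholesterol-like labels (default 0.75, so a sat-chol
#'   contact costs 0.25*J); only used when a `"chol"` label is present.
#' @param density_contrast strength of the packing-density contrast between
#'   ordered and disordered regions. After the Monte Carlo step, sites drift
#'   along the gradient of the smoothed ordered-fraction field, compressing
#'   ordered regions (smaller Voronoi cells) and dilating disordered ones —
#'   ordered phases pack tighter in real bilayers, where the area per lipid
#'   is ~10% smaller than in the disordered phase. The parameter is the
#'   fractional area contrast on a fully demixed configuration (default 0.1,
#'   i.e. ~10%); 0 disables the drift.
#' @return an object of class `lattice_gas_params`.
#' @export
lattice_gas_params <- function(lattice_side = 32,
                               species_fractions = c(sat = 0.6, unsat = 0.4),
                               coupling = 0,
                               interleaflet_coupling = 0,
                               sweeps = 1000,
                               seed = 1,
                               jitter = 0.15,
                               lattice_spacing = 0.8,
                               ordered_species = NULL,
                               chol_affinity = 0.75,
                               density_contrast = 0.1) {
  f <- species_fractions
  if (is.null(names(f)) || any(!nzchar(names(f))))
    stopf("species_fractions must be named")
  if (any(f < 0)) stopf("species fractions must be nonnegative")
  if (abs(sum(f) - 1) > 1e-9) stopf("species fractions must sum to 1")
  if (lattice_side < 4 || lattice_side %% 2 != 0)
    stopf("lattice_side must be an even integer >= 4")
  if (coupling < 0 || interleaflet_coupling < 0)
    stopf("couplings must be >= 0")
  if (sweeps < 0) stopf("sweeps must be >= 0")
  if (jitter < 0 || jitter >= 0.5) stopf("jitter must be in [0, 0.5)")
  if (density_contrast < 0 || density_contrast > 1)
    stopf("density_contrast must be in [0, 1]")
  if (is.null(ordered_species))
    ordered_species <- setdiff(names(f), "unsat")
  structure(list(lattice_side = as.integer(lattice_side),
                 species_fractions = f,
                 coupling = coupling,
                 interleaflet_coupling = interleaflet_coupling,
                 sweeps = as.integer(sweeps), seed = seed,
                 jitter = jitter, lattice_spacing = lattice_spacing,
                 ordered_species = ordered_species,
                 chol_affinity = chol_affinity,
                 density_contrast = density_contrast),
            class = "lattice_gas_params")
}

# triangular lattice in alternating-row offset form; returns positions (nm),
# the 6-neighbour index matrix (1-based) and the periodic box
triangular_lattice <- function(L, a) {
  r <- rep(0:(L - 1), each = L)
  c <- rep(0:(L - 1), times = L)
  x <- (c + 0.5 * (r %% 2)) * a
  y <- r * a * sqrt(3) / 2
  idx <- function(rr, cc) (rr %% L) * L + (cc %% L) + 1
  odd <- r %% 2 == 1
  co <- ifelse(odd, 1L, 0L) # column shift for row-offset parity
  nbr <- cbind(idx(r, c - 1), idx(r, c + 1),
               idx(r - 1, c - 1 + co), idx(r - 1, c + co),
               idx(r + 1, c - 1 + co), idx(r + 1, c + co))
  list(x = x, y = y, nbr = nbr, box = c(L * a, L * a * sqrt(3) / 2))
}

# exact integer species counts for n sites honouring the fractions
species_counts <- function(fractions, n) {
  cnt <- floor(fractions * n)
  rem <- n - sum(cnt)
  if (rem > 0) {
    frac_part <- fractions * n - cnt
    add <- order(frac_part, decreasing = TRUE)[seq_len(rem)]
    cnt[add] <- cnt[add] + 1
  }
  cnt
}

# Compress ordered regions and dilate disordered ones by a smooth,
# divergence-controlled displacement field. The binary ordered indicator is
# rasterized and smoothed, the potential u solving  laplace(u) = -eps * rho
# (rho = ordered fraction minus its mean) is obtained spectrally on the
# periodic grid, and sites move along grad(u). The local relative area
# change is div(grad u) = -eps * rho, so `strength` (eps) is the fractional
# area contrast between the phases: eps = 0.1 makes ordered cells ~10%
# smaller than disordered ones on a fully demixed configuration.
order_field_drift <- function(x, y, ordered, box, a, strength) {
  nx <- max(8L, 2L * round(box[1] / a / 2))
  ny <- max(8L, 2L * round(box[2] / a / 2))
  gx <- floor(x / box[1] * nx) %% nx
  gy <- floor(y / box[2] * ny) %% ny
  cnt <- matrix(0, nx, ny)
  ocnt <- matrix(0, nx, ny)
  for (i in seq_along(x)) {
    cnt[gx[i] + 1, gy[i] + 1] <- cnt[gx[i] + 1, gy[i] + 1] + 1
    if (ordered[i]) ocnt[gx[i] + 1, gy[i] + 1] <- ocnt[gx[i] + 1, gy[i] + 1] + 1
  }
  phi <- ifelse(cnt > 0, ocnt / pmax(cnt, 1), mean(ordered))
  for (p in 1:2) phi <- binomial_smooth(phi)
  rho <- phi - mean(phi)
  kx <- 2 * pi * c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1)) / box[1]
  ky <- 2 * pi * c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1)) / box[2]
  k2 <- outer(kx^2, ky^2, "+")
  rho_hat <- fft(rho)
  u_hat <- strength * rho_hat / pmax(k2, 1e-12)
  u_hat[1, 1] <- 0
  dx_f <- Re(fft(1i * matrix(kx, nx, ny) * u_hat, inverse = TRUE)) / (nx * ny)
  dy_f <- Re(fft(1i * matrix(ky, nx, ny, byrow = TRUE) * u_hat,
                 inverse = TRUE)) / (nx * ny)
  # bilinear interpolation of the displacement at the site positions
  interp <- function(f) {
    px <- x / box[1] * nx - 0.5
    py <- y / box[2] * ny - 0.5
    i0 <- floor(px); j0 <- floor(py)
    tx <- px - i0; ty <- py - j0
    at <- function(ii, jj) f[cbind((ii %% nx) + 1, (jj %% ny) + 1)]
    (1 - tx) * (1 - ty) * at(i0, j0) + tx * (1 - ty) * at(i0 + 1, j0) +
      (1 - tx) * ty * at(i0, j0 + 1) + tx * ty * at(i0 + 1, j0 + 1)
  }
  list(dx = interp(dx_f), dy = interp(dy_f))
}

#' Generate synthetic bilayer configurations from the Kawasaki lattice gas
#'
#' Runs conserved-composition (Kawasaki) Monte Carlo on two coupled leaflets
#' of a triangular lattice and returns jittered, wrapped bilayer frames.
#' Depending on `coupling` the output spans ideal mixing (J = 0), growing
#' composition fluctuations (subcritical J), and full phase separation
#' (J above the demixing threshold).
#'
#' @param params a [lattice_gas_params()] object.
#' @param n_frames number of frames to return; for `n_frames > 1` snapshots
#'   are recorded at evenly spaced sweep counts ending at `sweeps`.
#' @param time_per_sweep nominal frame time per sweep, ns (bookkeeping only).
#' @return a single [bilayer_frame()] if `n_frames == 1`, else a list of
#'   frames. The parameters are attached as attribute `"params"`.
#' @export
generate_lattice_gas <- function(params, n_frames = 1, time_per_sweep = 1) {
  stopifnot(inherits(params, "lattice_gas_params"))
  L <- params$lattice_side
  lat <- triangular_lattice(L, params$lattice_spacing)
  n <- L * L
  f <- params$species_fractions
  sp_names <- names(f)
  cnt <- species_counts(f, n)
  if (any(cnt == 0 & f > 0))
    stopf("lattice too small to hold all species")

  cost <- matrix(params$coupling, length(f), length(f),
                 dimnames = list(sp_names, sp_names))
  diag(cost) <- 0
  if (all(c("sat", "chol") %in% sp_names)) {
    cost["sat", "chol"] <- cost["chol", "sat"] <-
      params$coupling * (1 - params$chol_affinity)
  }
  ordered_flag <- as.integer(sp_names %in% params$ordered_species)

  seeds <- derive_seeds(params$seed, 4)
  base <- rep.int(seq_along(f) - 1L, cnt) # 0-based species codes
  init <- with_seed(seeds[1], list(up = sample(base), lo = sample(base)))

  record_every <- if (n_frames > 1) max(1L, params$sweeps %/% n_frames) else 0L
  res <- .kawasaki_mc(init$up, init$lo, lat$nbr - 1L, cost,
                      params$interleaflet_coupling, ordered_flag,
                      params$sweeps, seeds[2], record_every)

  # composition must be exactly conserved by the exchange dynamics
  for (r in seq_along(res$upper)) {
    for (lf in c("upper", "lower")) {
      got <- tabulate(res[[lf]][[r]] + 1L, nbins = length(f))
      if (!identical(got, as.integer(cnt)))
        stop("internal error: species composition not conserved by MC")
    }
  }

  keep <- seq_along(res$upper)
  if (n_frames > 1 && length(keep) > n_frames)
    keep <- tail(keep, n_frames)
  a <- params$lattice_spacing
  frames <- lapply(seq_along(keep), function(k) {
    r <- keep[k]
    jit <- with_seed(seeds[3] + r, matrix(runif(4 * n, -params$jitter,
                                                params$jitter) * a, ncol = 4))
    mk <- function(codes, jx, jy) {
      x <- wrap_box(lat$x + jx, lat$box[1])
      y <- wrap_box(lat$y + jy, lat$box[2])
      if (params$density_contrast > 0) {
        ord <- ordered_flag[codes + 1L] == 1L
        d <- order_field_drift(x, y, ord, lat$box, a,
                               params$density_contrast)
        x <- wrap_box(x + d$dx, lat$box[1])
        y <- wrap_box(y + d$dy, lat$box[2])
      }
      data.frame(id = seq_len(n),
                 species = sp_names[codes + 1L],
                 x = x, y = y, stringsAsFactors = FALSE)
    }
    bilayer_frame(mk(res$upper[[r]], jit[, 1], jit[, 2]),
                  mk(res$lower[[r]], jit[, 3], jit[, 4]),
                  box = lat$box, time = res$sweep[r] * time_per_sweep)
  })
  for (i in seq_along(frames)) attr(frames[[i]], "params") <- params
  if (n_frames == 1) frames[[length(frames)]] else frames
}
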