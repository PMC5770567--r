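test_that("Poisson points give a flat RDF within counting noise", {
  set.seed(51)
  pts <- data.frame(x = runif(2000, 0, 40), y = runif(2000, 0, 40))
  g <- rdf2d(pts, box = c(40, 40), bin_width = 0.2)
  sel <- g$r > 0.5
  sigma <- 1 / sqrt(pmax(g$count[sel], 1))
  expect_true(all(abs(g$g[sel] - 1) < 3 * sigma + 0.02))
  # ring-area-weighted mean of g over the profile is ~ 1
  w <- g$r
  expect_equal(sum(g$g * w) / sum(w), 1, tolerance = 0.02)
})

test_that("a single pair lands in one bin with hand-checked normalization", {
  pts <- data.frame(x = c(10, 13.1), y = c(10, 10))
  box <- c(40, 40)
  g <- rdf2d(pts, box = box, bin_width = 0.5)
  hit <- which(g$count > 0)
  expect_length(hit, 1)
  expect_identical(g$r[hit], 3.25) # bin (3, 3.5] holds r = 3.1
  # 2 ordered pairs / (N * rho * ring area)
  ring <- pi * (3.5^2 - 3^2)
  expect_equal(g$g[hit], 2 / (2 * (2 / prod(box)) * ring), tolerance = 1e-9)
  expect_error(rdf2d(pts, box = box, r_max = 30), "minimum-image")
})

test_that("correlation length is recovered from synthetic profiles", {
  set.seed(53)
  r <- seq(0.05, 10, by = 0.1)
  make_prof <- function(g) {
    out <- data.frame(r = r, g = g, count = rep(1000, length(r)))
    attr(out, "box") <- c(20, 20); attr(out, "n_sites") <- c(400, 400)
    class(out) <- c("radial_profile", "data.frame")
    out
  }
  g <- 0.8 * exp(-r / 2) + 1 + rnorm(length(r), 0, 0.01)
  fit <- fit_correlation_length(make_prof(g), fit_range = c(0.05, 10))
  expect_false(fit$refused)
  expect_equal(fit$xi, 2, tolerance = 0.05)
  expect_equal(fit$a0, 0.8, tolerance = 0.1)
  expect_equal(fit$a1, 1, tolerance = 0.02)
  # flat profile: fit refused, no fabricated xi
  flat <- make_prof(1 + rnorm(length(r), 0, 0.01))
  fit0 <- fit_correlation_length(flat, fit_range = c(0.05, 10))
  expect_true(fit0$refused)
  expect_true(is.na(fit0$xi))
})

test_that("xi estimator is nearly unbiased at low noise", {
  set.seed(54)
  r <- seq(0.05, 10, by = 0.1)
  xis <- replicate(100, {
    g <- 0.8 * exp(-r / 2) + 1 + rnorm(length(r), 0, 0.05)
    out <- data.frame(r = r, g = g, count = rep(1000, length(r)))
    class(out) <- c("radial_profile", "data.frame")
    f <- fit_correlation_length(out, fit_range = c(0.05, 10))
    if (f$refused) NA else f$xi
  })
  expect_lt(abs(mean(xis, na.rm = TRUE) - 2) / 2, 0.05)
})

test_that("xi grows with subcritical coupling", {
  xi_at <- function(J) {
    mean(sapply(1:5, function(s) {
      frs <- generate_lattice_gas(
        lattice_gas_params(lattice_side = 24, coupling = J, sweeps = 3000,
                           seed = s * 17), n_frames = 6)
      g <- rdf2d(tail(frs, 3), species = "unsat", bin_width = 0.4,
                 normalize = "all_sites")
      f <- fit_correlation_length(g, fit_range = c(0.8, 8))
      if (f$refused) 0 else f$xi
    }))
  }
  xi1 <- xi_at(0.3); xi2 <- xi_at(0.5)
  expect_gt(xi2, xi1)
})

test_that("structure factor is 1 for Poisson points and peaks for a lattice row", {
  set.seed(55)
  pts <- data.frame(x = runif(2000, 0, 40), y = runif(2000, 0, 40))
  sq <- structure_factor(pts, box = c(40, 40), max_modes = 25)
  expect_true(all(sq$S >= 0))
  expect_equal(mean(sq$S), 1, tolerance = 0.1)

  # single row of equally spaced points: Bragg peak S = n at q = 2 pi / d
  row <- data.frame(x = seq(0, 36, by = 4), y = rep(20, 10))
  sq2 <- structure_factor(row, box = c(40, 40), max_modes = 12)
  S2 <- attr(sq2, "S2d")
  qx <- attr(sq2, "qx"); qy <- attr(sq2, "qy")
  expect_equal(S2[which.min(abs(qx - 2 * pi / 4)), which.min(abs(qy))], 10,
               tolerance = 1e-9)
})

test_that("direct-sum structure factor equals the gridded FFT on lattice points", {
  # points exactly on grid nodes: DFT of the gridded density is the same sum
  set.seed(56)
  nx <- 16; ny <- 16
  box <- c(16, 16)
  occupied <- sample(nx * ny, 60)
  pts <- data.frame(x = (occupied - 1) %% nx,
                    y = (occupied - 1) %/% nx)
  sq <- structure_factor(pts, box = box, max_modes = 7)
  S2 <- attr(sq, "S2d"); qx <- attr(sq, "qx")
  Sfft <- bilayerdomains:::structure_factor_fft(pts, box, nx, ny)
  for (a in seq_along(qx)) {
    for (b in seq_along(qx)) {
      ja <- ((a - 8) %% nx) + 1 # mode index -> FFT index
      jb <- ((b - 8) %% ny) + 1
      expect_equal(S2[a, b], Sfft[ja, jb], tolerance = 1e-8)
    }
  }
})

test_that("striped configurations put the radial peak at 2 pi / period", {
  # stripes of period 8 nm along x
  set.seed(57)
  x <- runif(3000, 0, 32); y <- runif(3000, 0, 32)
  keep <- (x %% 8) < 4
  sq <- structure_factor(data.frame(x = x[keep], y = y[keep]),
                         box = c(32, 32), max_modes = 16)
  pk <- sq$q[which.max(sq$S)]
  expect_equal(pk, 2 * pi / 8, tolerance = attr(sq, "dq"))
})

test_that("correlation time flags static and uncorrelated sequences", {
  fr <- random_frame(300, box = c(20, 20), seed = 61)
  static <- lapply(0:10, function(t) { f <- fr; f$time <- t; f })
  ct <- density_time_correlation(static)
  expect_identical(ct$status, "static")
  expect_identical(ct$tau, Inf)

  iid <- lapply(0:10, function(t) {
    f <- random_frame(300, box = c(20, 20), seed = 100 + t); f$time <- t; f
  })
  ct2 <- density_time_correlation(iid)
  expect_identical(ct2$status, "unresolved")
  expect_error(density_time_correlation(static[1:5], n_lags = 9), "frames")
})

test_that("correlation time of Brownian tracers matches the cell-crossing time", {
  # grid cell 2 nm, D = 0.01 nm^2/ns: expected tau = l^2 / (4 D) = 100 ns
  taus <- sapply(1:10, function(s) {
    tr <- generate_brownian_trajectory(c(a = 600), c(a = 1e-7), dt = 30,
                                       n_frames = 250, box = c(40, 40),
                                       seed = 400 + s)
    density_time_correlation(tr, grid = c(20, 20), n_lags = 9)$tau
  })
  expect_equal(mean(taus), 100, tolerance = 0.25)
})

test_that("density maps conserve counts and report window contrast", {
  fr <- random_frame(500, box = c(20, 20), seed = 63)
  frames <- lapply(0:9, function(t) { f <- fr; f$time <- t * 10; f })
  maps <- density_map(frames, window_ns = 30, grid_spacing = 2)
  expect_length(maps, 3)
  for (m in maps) {
    expect_equal(sum(m$density) * m$cell_area, 500, tolerance = 1e-6)
  }
  # uniform static points: flat long-window map has low contrast;
  # persistent demixed state keeps high contrast at the longest window
  frs <- generate_lattice_gas(
    lattice_gas_params(lattice_side = 24, coupling = 0.8,
                       interleaflet_coupling = 0.5, sweeps = 60000,
                       seed = 64), n_frames = 10)
  long_map <- density_map(frs, species = "unsat",
                          window_ns = diff(range(sapply(frs, `[[`, "time"))),
                          grid_spacing = 2)
  expect_gt(map_contrast(long_map[[1]]), 2)
})
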