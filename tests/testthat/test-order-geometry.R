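test_that("chain order respects exact geometric limits and bounds", {
  # one straight chain along z and one in-plane
  up <- cbind(0, 0, 0:4 * 0.5)
  flat <- cbind(0:4 * 0.5, 0, 0)
  expect_equal(chain_order(list(list(up)))$mean, 1)
  expect_equal(chain_order(list(list(flat)))$mean, -0.5)
  # mixed lipid: average of its chains' site contributions
  both <- chain_order(list(list(up, flat)))
  expect_equal(both$mean, mean(c(rep(1, 3), rep(-0.5, 3))))
  # short chains are skipped and counted
  res <- chain_order(list(list(up), list(cbind(0, 0, 0:1))))
  expect_equal(res$n_skipped, 1)
  expect_equal(res$n_lipids, 1)
})

test_that("cholesterol-labelled lipids are excluded from frame chain order", {
  up <- data.frame(id = 1:3, species = c("sat", "chol", "sat"),
                   x = c(1, 2, 3), y = c(1, 1, 1))
  lo <- up
  straight <- lapply(1:3, function(i) list(cbind(0, 0, 0:4 * 0.5)))
  # make the chol chain in-plane: excluding it must leave S_z = 1
  straight[[2]] <- list(cbind(0:4 * 0.5, 0, 0))
  fr <- bilayer_frame(up, lo, box = c(5, 5),
                      chains = list(upper = straight, lower = straight))
  expect_equal(chain_order(fr)$mean, 1)
  expect_equal(chain_order(fr, excluded_species = character())$mean,
               mean(c(1, -0.5, 1)))
})

test_that("surface fitting preserves constants and the grid mean", {
  set.seed(71)
  sites <- data.frame(x = runif(400, 0, 20), y = runif(400, 0, 20), z = 5)
  sg <- fit_surface(sites, box = c(20, 20))
  expect_equal(max(abs(sg$z - 5)), 0, tolerance = 1e-9)
  # smoothing is mean-preserving
  z <- matrix(rnorm(40 * 40), 40, 40)
  zs <- bilayerdomains:::binomial_smooth(z)
  expect_equal(mean(zs), mean(z), tolerance = 1e-12)
})

test_that("a sampled sinusoid is reproduced with small attenuation", {
  set.seed(72)
  n <- 3000
  x <- runif(n, 0, 20); y <- runif(n, 0, 20)
  sites <- data.frame(x = x, y = y, z = sin(2 * pi * x / 20))
  sg <- fit_surface(sites, box = c(20, 20))
  amp <- (max(sg$z) - min(sg$z)) / 2
  expect_gt(amp, 0.95)
  expect_lt(amp, 1.02)
})

test_that("curvature is exact on a plane and a sphere cap", {
  pl <- generate_surface("plane", list(z0 = 2))
  cv <- curvature(pl)
  expect_true(all(cv$H == 0) && all(cv$c1 == 0) && all(cv$c2 == 0))

  sc <- generate_surface("sphere_cap", list(radius = 10), grid_spacing = 0.4)
  cvs <- curvature(sc)
  X <- matrix(sc$x, length(sc$x), length(sc$y))
  Y <- matrix(sc$y, length(sc$x), length(sc$y), byrow = TRUE)
  inner <- (X - 10)^2 + (Y - 10)^2 < 16 # away from the cap edge
  expect_true(all(abs(cvs$H[inner] - 0.1) / 0.1 < 0.02))
  # H = (c1 + c2)/2 holds identically, c1 >= c2
  expect_equal(cvs$H, (cvs$c1 + cvs$c2) / 2, tolerance = 1e-12)
  expect_true(all(cvs$c1 >= cvs$c2))
})

test_that("curvature matches the closed-form sinusoid field and flips sign", {
  ss <- generate_surface("sinusoid", list(amplitude = 0.5, wavelength = 20),
                         grid_spacing = 0.4)
  cv <- curvature(ss)
  rms <- sqrt(mean((cv$H - ss$H_true)^2)) / sqrt(mean(ss$H_true^2))
  expect_lt(rms, 0.02)
  flipped <- ss; flipped$z <- -ss$z
  expect_equal(curvature(flipped)$H, -cv$H, tolerance = 1e-12)
})

test_that("small-slope mean curvature approaches the Laplacian form", {
  ss <- generate_surface("sinusoid", list(amplitude = 0.05, wavelength = 20),
                         grid_spacing = 0.4)
  cv <- curvature(ss)
  # -(z_xx + z_yy)/2 with our bulge-positive orientation
  sh <- function(m, i) {
    n <- nrow(m); m[((seq_len(n) - 1 + i) %% n) + 1, , drop = FALSE]
  }
  zxx <- (sh(ss$z, 1) - 2 * ss$z + sh(ss$z, -1)) / 0.4^2
  lap <- -zxx / 2
  expect_lt(max(abs(cv$H - lap)) / max(abs(lap)), 0.01)
})

test_that("diffusion estimation requires unwrapped input", {
  tr <- generate_brownian_trajectory(c(a = 30), c(a = 1e-7), dt = 1,
                                     n_frames = 30, box = c(20, 20),
                                     seed = 73)
  tr$unwrapped <- NULL
  expect_error(lateral_diffusion(tr), "unwrap")
})

test_that("diffusion is invariant under uniform drift removal", {
  tr <- generate_brownian_trajectory(c(a = 300), c(a = 1e-7), dt = 1,
                                     n_frames = 200, box = c(40, 40),
                                     seed = 74)
  d0 <- lateral_diffusion(tr)$D
  drift <- tr
  for (t in seq_along(tr$times)) {
    drift$unwrapped[, 1, t] <- drift$unwrapped[, 1, t] - 0.001 * tr$times[t]
  }
  # removing the added drift restores the original estimate exactly
  undone <- drift
  for (t in seq_along(tr$times)) {
    undone$unwrapped[, 1, t] <- undone$unwrapped[, 1, t] + 0.001 * tr$times[t]
  }
  expect_equal(lateral_diffusion(undone)$D, d0, tolerance = 1e-12)
})

test_that("table-magnitude diffusion pair is recovered with ordering", {
  tr <- generate_brownian_trajectory(c(sat = 400, unsat = 400),
                                     c(sat = 4.1e-7, unsat = 4.6e-7),
                                     dt = 1, n_frames = 400,
                                     box = c(60, 60), seed = 75)
  d <- lateral_diffusion(tr)
  expect_equal(d$D[d$species == "sat"], 4.1e-7, tolerance = 0.05)
  expect_equal(d$D[d$species == "unsat"], 4.6e-7, tolerance = 0.05)
  expect_lt(d$D[d$species == "sat"], d$D[d$species == "unsat"])
})
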