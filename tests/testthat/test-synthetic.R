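test_that("parameter validation catches bad inputs", {
  expect_error(lattice_gas_params(species_fractions = c(sat = 0.7, unsat = 0.4)),
               "sum to 1")
  expect_error(lattice_gas_params(lattice_side = 9), "even")
  expect_error(lattice_gas_params(jitter = 0.5), "jitter")
  expect_error(generate_chains(10, target_Sz = 1.2), "target_Sz")
  expect_error(generate_brownian_trajectory(c(a = 5), c(a = 1e-7), dt = 0,
                                            n_frames = 3), "dt")
})

test_that("lattice gas conserves composition and is seed-deterministic", {
  p <- lattice_gas_params(lattice_side = 16, coupling = 0.4, sweeps = 500,
                          seed = 3)
  fr1 <- generate_lattice_gas(p)
  fr2 <- generate_lattice_gas(p)
  expect_identical(fr1$leaflets, fr2$leaflets)
  counts <- table(fr1$leaflets$upper$species)
  expect_identical(as.integer(counts[c("sat", "unsat")]),
                   as.integer(bilayerdomains:::species_counts(
                     p$species_fractions, 256)))
  # different seed, different configuration
  fr3 <- generate_lattice_gas(lattice_gas_params(lattice_side = 16,
                                                 coupling = 0.4,
                                                 sweeps = 500, seed = 4))
  expect_false(identical(fr1$leaflets$upper$species,
                         fr3$leaflets$upper$species))
})

test_that("uncoupled lattice gas is spatially random (same-species RDF = 1)", {
  frs <- generate_lattice_gas(
    lattice_gas_params(lattice_side = 32, coupling = 0, sweeps = 1000,
                       seed = 11), n_frames = 5)
  g <- rdf2d(frs, species = "sat", bin_width = 0.4, normalize = "all_sites")
  sel <- is.finite(g$g) & g$r > 0.8
  # 3 sigma with Poisson bin noise, averaged over frames
  sigma <- 1 / sqrt(pmax(g$count[sel], 1))
  expect_true(all(abs(g$g[sel] - 1) < pmax(3 * sigma, 0.05)))
})

test_that("ternary fractions are honoured and chol counts as ordered", {
  p <- lattice_gas_params(
    lattice_side = 16,
    species_fractions = c(sat = 0.35, unsat = 0.35, chol = 0.30),
    coupling = 0.3, sweeps = 300, seed = 5)
  fr <- generate_lattice_gas(p)
  expect_setequal(unique(fr$leaflets$upper$species),
                  c("sat", "unsat", "chol"))
  expect_setequal(p$ordered_species, c("sat", "chol"))
})

test_that("chain generator hits trivial and intermediate order targets", {
  expect_equal(chain_order(generate_chains(200, 1, seed = 1))$mean, 1)
  expect_equal(chain_order(generate_chains(200, -0.5, seed = 1))$mean, -0.5)
  expect_equal(chain_order(generate_chains(1e4, 0, seed = 2))$mean, 0,
               tolerance = 0.01)
  expect_equal(chain_order(generate_chains(1e4, 0.42, seed = 3))$mean, 0.42,
               tolerance = 0.01)
})

test_that("surface generator gives exact curvature references", {
  pl <- generate_surface("plane", list(z0 = 5))
  expect_true(all(pl$z == 5))
  expect_true(all(pl$H_true == 0))
  sc <- generate_surface("sphere_cap", list(radius = 10))
  expect_true(all(abs(sc$H_true[sc$mask] - 0.1) < 1e-12))
  expect_error(generate_surface("sinusoid",
                                list(amplitude = 4, wavelength = 20)),
               "steep")
})

test_that("Brownian steps satisfy the Einstein relation by construction", {
  tr <- generate_brownian_trajectory(c(a = 400), c(a = 1e-7), dt = 1,
                                     n_frames = 300, box = c(50, 50),
                                     seed = 7)
  d <- lateral_diffusion(tr)
  expect_equal(d$D, 1e-7, tolerance = 0.05)
  # D = 0: no displacement at all
  tr0 <- generate_brownian_trajectory(c(a = 20), c(a = 0), dt = 1,
                                      n_frames = 12, box = c(10, 10),
                                      seed = 1)
  expect_true(all(tr0$unwrapped[, , 1] == tr0$unwrapped[, , 12]))
  expect_equal(lateral_diffusion(tr0)$D, 0)
})

test_that("species with a 2:1 diffusion ratio are recovered", {
  tr <- generate_brownian_trajectory(c(fast = 400, slow = 400),
                                     c(fast = 2e-7, slow = 1e-7),
                                     dt = 1, n_frames = 400,
                                     box = c(50, 50), seed = 13)
  d <- lateral_diffusion(tr)
  ratio <- d$D[d$species == "fast"] / d$D[d$species == "slow"]
  expect_equal(ratio, 2, tolerance = 0.05)
})

test_that("frame bundles round-trip through the CSV + JSON format", {
  frs <- generate_lattice_gas(
    lattice_gas_params(lattice_side = 8, coupling = 0.2, sweeps = 100,
                       seed = 2), n_frames = 3)
  dir <- tempfile()
  write_frames(frs, dir, meta = list(generator = "lattice_gas"))
  back <- read_frames(dir)
  expect_length(back, 3)
  for (k in 1:3) {
    expect_equal(back[[k]]$leaflets$upper$x, frs[[k]]$leaflets$upper$x)
    expect_identical(back[[k]]$leaflets$lower$species,
                     frs[[k]]$leaflets$lower$species)
    expect_equal(back[[k]]$time, frs[[k]]$time)
    expect_equal(back[[k]]$box, frs[[k]]$box)
  }
  unlink(dir, recursive = TRUE)
})
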