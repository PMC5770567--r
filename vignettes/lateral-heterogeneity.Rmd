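---
title: "Distinguishing nanoscale domains from composition fluctuations in lipid bilayers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distinguishing nanoscale domains from composition fluctuations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilayerdomains)
```

## The scientific question

A mixed lipid bilayer cooled toward its miscibility transition develops
lateral heterogeneity long before it phase-separates. Transient, rough
clusters enriched in the saturated lipid (and cholesterol, when present)
appear and dissolve — *composition fluctuations* — and below the transition
they give way to persistent *domains* of a coexisting ordered phase (gel or
liquid-ordered). Snapshots of the two situations can look deceptively
similar; telling them apart requires quantitative observables. This package
implements the complete analysis chain that makes the distinction:

1. **Tessellation** — a periodic 2D Voronoi diagram of each leaflet gives
   per-lipid areas, the first neighbour shell, and shared cell-wall lengths.
2. **Ordered-cluster detection** — a site is *ordered* when the local
   concentration of the ordered species (site plus first shell) strictly
   exceeds its leaflet-wide mean; connected components of ordered sites on
   the periodic Delaunay graph are the clusters, measured by area,
   equivalent-circle radius $R = \sqrt{A/\pi}$, composition, and normalized
   boundary length $L = P / (2\sqrt{\pi A})$.
3. **Registration** — both leaflets' ordered/disordered states are
   rasterized and compared cell-wise; the overlap is the fraction of raster
   cells in the same state.
4. **Correlations** — the in-plane radial distribution function with an
   exponential fit $g(r) = a_0 e^{-r/\xi} + a_1$ for the correlation length;
   the static structure factor
   $S(\bar q) = \frac{1}{N}\left|\sum_n e^{-i \bar q\cdot\bar r_n}\right|^2$
   on the box-commensurate wave-vector grid, radially averaged; the
   correlation time $\tau$ from the local-density autocorrelation on a
   20×20 grid; and time-windowed density maps.
5. **Order and geometry** — the chain orientational order parameter
   $S_z = \langle \tfrac12 (3\cos^2\theta - 1)\rangle$ over internal chain
   segments ($n{-}1 \to n{+}1$ vectors, cholesterol excluded), leaflet
   surface fitting with mean curvature $H = (c_1 + c_2)/2$, and lateral
   diffusion by the Einstein relation.
6. **Classification** — the observables are combined into a reproducible
   phase verdict: `one_phase`, `near_critical`, or `two_phase`.

The diagnostic signatures are: fluctuations decay *exponentially* in $g(r)$,
have *rough* boundaries ($L$ well above 1) and *uncorrelated* leaflets
(overlap near the independence value), and *average out* in long-window
density maps; domains decay *linearly* (long-range correlations), have
*smooth* boundaries, *register* across leaflets (overlap above ~0.7), and
*persist*.

## The synthetic generator and what it emulates

The package replaces molecular-dynamics trajectories with a two-leaflet
Kawasaki lattice gas (`generate_lattice_gas()`), which reproduces the
*statistical* structure the analysis consumes:

* **Triangular lattice, jittered.** Fluid-bilayer packing is locally
  hexagonal; jittered triangular-lattice sites give hexagonal Voronoi cells.
  Default jitter 0.15 lattice units, spacing 0.8 nm (≈0.55 nm² per lipid).
* **Kawasaki (exchange) dynamics.** Lipid composition is conserved in a
  bilayer, so species swap between neighbouring sites rather than flipping;
  composition conservation is asserted after every run.
* **Contact energy.** Unlike pairs cost `coupling` $J$ (in $kT$). On the
  triangular lattice the Ising mapping puts the demixing threshold near
  $J_c \approx 0.55$ for the default 3:2 binary mixture; subcritical $J$
  produces growing composition fluctuations, $J$ above threshold produces
  full phase separation. The scale was calibrated by an internal coupling
  scan, not against any published table. A cholesterol-like third label
  gets a discounted contact cost with the saturated-like label
  (`chol_affinity`, default 0.75), so ternary mixtures demix into
  sat+chol-rich vs unsat-rich regions.
* **Interleaflet coupling** `interleaflet_coupling` $\Lambda$ ($kT$) rewards
  the same binary ordered/disordered state across leaflets at the same
  site. It acts on the relabelling, not on raw species, so it works for
  ternary mixtures.
* **Density contrast** (`density_contrast`, default 0.1). Ordered phases
  pack ~10% tighter than disordered ones. A uniform lattice cannot show
  this, so sites drift along a divergence-controlled displacement field
  (a spectral Poisson solve on the smoothed ordered-fraction deviation);
  the parameter is the fractional area contrast on a fully demixed
  configuration. The drift moves both species identically, so
  composition-normalized correlations are unaffected.

Companion generators provide exact references for the other estimators:
`generate_chains()` (straight rods whose polar-angle mixture hits a target
$S_z$ exactly in expectation), `generate_surface()` (plane, sphere cap,
sinusoid — each with its closed-form mean curvature), and
`generate_brownian_trajectory()` (2D Gaussian steps of variance $4D\,dt$,
wrapped and unwrapped).

**What the generator does not emulate:** real chain packing and tilt,
sterol flip-flop, hydrodynamics, undulation-curvature coupling, and any
quantitative mapping from $J$ to temperature in kelvin. Tests passing on
lattice-gas data validate the *estimators*, not force-field realism.

## Numerical choices

* **Periodic Voronoi.** Cells are built by incremental half-plane clipping
  against candidates from the 3×3 periodic images, sorted by distance, with
  the standard termination rule (next candidate farther than twice the
  farthest cell vertex). Tiling is asserted on every call
  ($\sum A_i = L_x L_y$ to 1e-6 relative). Exactly cocircular quadruples
  (perfect lattices) are disambiguated by a deterministic 1e-9 nm
  hash-derived jitter; edges shorter than 1e-8 nm (corner contacts) are
  dropped from the adjacency.
* **RDF.** Default bin width 0.1 nm, $r_{\max} = \min(L_x,L_y)/2$ (minimum
  image bound, enforced). On lattice-generated configurations every species
  inherits the lattice's translational order, so the species profile is
  divided by the all-sites profile (`normalize = "all_sites"`), which
  cancels the packing shells exactly and isolates the composition
  correlation; for fluid (off-lattice) data the textbook normalization is
  the default.
* **Correlation length.** Nonlinear least squares with multi-start over
  $\xi$; the fit is *refused* (no $\xi$ reported) when the exponential does
  not beat a constant in an F-test at the 5% level or $a_0 \le 0$ — a flat
  profile has no correlation length, and refusing beats fabricating.
* **Decay-shape comparison (classifier).** Comparing a line against the
  free-baseline exponential is degenerate: in the large-$\xi$ limit the
  exponential *is* a line, and it has an extra parameter to spend. The
  classifier therefore restricts the comparison to the monotone decay
  segment (from 0.8 nm to the running minimum of the lightly smoothed
  profile) and pins the exponential's baseline to the profile's tail level,
  giving both models equal complexity. The physics: a one-phase profile
  relaxes exponentially *to* the uncorrelated level, while a two-phase
  profile crosses *below* it on the way to the inter-domain undulation,
  which only the line can follow.
* **Structure factor.** Wave vectors $\bar q = 2\pi(n/L_x, m/L_y)$ —
  commensurate with the box, resolution $\Delta q = 2\pi/L$. A peak at $q$
  means a real-space period $2\pi/q$. (Conventions without the $2\pi$
  exist; peak positions shift accordingly.) The separable phase-sum
  evaluation equals a gridded FFT to 1e-8 on lattice-commensurate points,
  which is asserted in the tests.
* **Correlation time.** Cell-count autocorrelation, normalized to
  $C(0)=1$, fitted log-linearly through the origin over lags 1–9 (10
  frames). Static input is flagged `static` ($\tau = \infty$), uncorrelated
  input `unresolved` ($\tau$ below the frame spacing). For a diffusing
  tracer this estimator recovers the cell-traversal time $\ell^2/(4D)$ when
  the lag spacing resolves the decay (first lag near $C \approx 0.5$); a
  linear-scale fit would overweight the earliest lags and report roughly
  half that.
* **Surface fitting.** Gaussian-kernel interpolation (bandwidth = grid
  spacing, default 0.4 nm) onto a periodic grid, then 2 passes of the
  separable binomial (1-4-6-4-1)/16 filter. The filter's gain is
  $\cos^4(k\,dx/2)$ per pass: mean-preserving, constants pass exactly, a
  20 nm undulation sampled at 0.4 nm is attenuated by <2%.
* **Curvature.** Central differences with periodic wrap; principal
  curvatures from the Monge-gauge shape operator; sign convention: bulging
  toward $+z$ is positive $H$ (so $z \to -z$ negates $H$, asserted).
* **Diffusion.** Time-origin-averaged MSD on unwrapped coordinates, linear
  fit over the middle third of lags, lags capped at one third of the
  trajectory — longer lags average over too few independent increments and
  a single realization can bend visibly.
* **Boundary length.** The normalized boundary of *any* cluster resolved in
  Voronoi cells carries a staircase factor: cell walls zigzag around the
  ideal smooth contour, ≥ $2/\sqrt{3} \approx 1.155$ on a hexagonal
  tessellation (≈1.27 measured for a 661-site disc, independent of jitter
  and size). A disc therefore measures ≈1.27, not 1.0 — still far below
  rough-fluctuation values (>2), so the diagnostic contrast survives, but
  absolute values should be read with the factor in mind. The isoperimetric
  bound $L \ge 1$ holds always and is asserted for every cluster.

## Classifier thresholds

All thresholds live in `classifier_config()` and are deliberate
engineering choices, not fitted quantities: overlap 0.7 (the signature of
strong interleaflet correlation — independent leaflets sit at
$f^2 + (1-f)^2 \in [0.50, 0.57]$ for ordered fractions 0.31–0.46, so 0.7
is well clear of the null), persistence 0.8 (density-map contrast retained
from the shortest to the longest window), and $\xi$ above 3× the mean
inter-lipid spacing for a near-critical call. `two_phase` requires linear
decay preferred *and* overlap *and* persistence; missing evidence withholds
the verdict rather than guessing.

## Problem sizes

The shipped tests and examples run at desk scale, chosen to finish in
minutes while leaving the estimators' statistics resolvable: 32×32 lattices
(2048 lipids over two leaflets), 10³ sweeps for mixed states, 3×10⁴ near
the transition, 3×10⁵ for well-demixed morphologies; 20-seed ensembles for
the registration null; 10-seed ensembles for stochastic recovery checks.
The analysis window is the final 10% of frames by default
(`window_fraction`), mirroring the convention of analysing the equilibrated
tail of a trajectory.

## Known limitations

* The lattice gas is a stand-in: its coupling has no thermometer, and its
  boundary roughness at strong coupling is thermal-noise-limited rather
  than line-tension-limited.
* Near the demixing threshold the verdict is strongly seed-dependent at
  this box size — real near-critical behaviour, but it means single-seed
  verdicts near $J_c$ should not be over-interpreted.
* `read_trajectory()` adapts GRO/PDB text coordinates (one frame per file)
  plus the package's own CSV+JSON bundle; compressed binary trajectory
  formats are out of scope.
* Leaflets are analysed after projection onto the bilayer plane; there is
  no 3D tessellation, and curvature is measured per leaflet (or on the
  midplane by averaging the two surfaces), not coupled back into the
  in-plane analysis.

## A worked run

```{r example, eval = FALSE}
res_mix <- run_pipeline(list(
  synthetic = list(lattice_side = 32, coupling = 0, sweeps = 2000,
                   seed = 172, n_frames = 16),
  window_fraction = 0.25))
res_mix$verdict$label     # "one_phase"

res_dom <- run_pipeline(list(
  synthetic = list(lattice_side = 32, coupling = 0.8,
                   interleaflet_coupling = 0.5, sweeps = 3e5,
                   seed = 171, n_frames = 16),
  window_fraction = 0.25))
res_dom$verdict$label     # "two_phase"
res_dom$summary$overlap   # > 0.7: domains in register
```

The same contrasts, at the same problem sizes, are what the test suite
asserts.
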