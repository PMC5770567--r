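# bilayerdomains

Quantitative analysis of lateral heterogeneity in two-leaflet lipid
bilayers: are the nanoscale clusters you see **domains of a coexisting
phase** or **composition fluctuations** within a single phase?

The two look alike in snapshots but differ in measurable ways. This package
implements the full analysis chain that separates them, for anyone working
with coarse-grained membrane simulations (or synthetic stand-ins):

- **Periodic Voronoi tessellation** of each leaflet: per-lipid areas
  `A_L`, first-neighbour shells, shared cell-wall lengths.
- **Ordered-cluster detection**: a site is ordered when the local
  concentration of the ordered species (site + first shell) strictly
  exceeds its leaflet mean; clusters are connected components on the
  periodic Delaunay graph, with area, equivalent-circle radius
  `R = sqrt(A/pi)`, composition `C_i`, and normalized boundary length
  `L = P / (2 sqrt(pi A))` (1 for a disc, large for rough shapes).
- **Interleaflet registration**: rasterized ordered/disordered state maps
  compared cell-wise; independent leaflets with ordered fractions f give
  overlap `f^2 + (1-f)^2` (0.57 at f = 0.31, 0.50 at f = 0.46), identical
  maps give 1, complementary maps 0.
- **Correlations**: in-plane 2D RDF with exponential fit
  `g(r) = a0 exp(-r/xi) + a1` for the correlation length; static structure
  factor `S(q) = |sum_n exp(-i q.r_n)|^2 / N` on the box-commensurate grid,
  radially averaged; local-density correlation time `tau`; time-windowed
  density maps.
- **Order & geometry**: chain order parameter
  `S_z = <(3 cos^2(theta) - 1)/2>` over internal chain segments; leaflet
  surface fitting (0.4 nm grid, binomial smoothing) with mean curvature
  `H = (c1 + c2)/2`; lateral diffusion from the Einstein relation.
- **Phase classifier**: combines decay shape (linear = long-range domain
  correlations vs exponential = short-range fluctuations), overlap,
  persistence and `xi` into `one_phase` / `near_critical` / `two_phase`.
- **Synthetic generator**: a two-leaflet Kawasaki lattice gas with tunable
  intra- and interleaflet coupling spans ideal mixing, near-critical
  fluctuations, and full phase separation, so every estimator is testable
  without molecular dynamics; companion generators give exact references
  for `S_z`, curvature, and diffusion.

## Worked example

Simulate a phase-separated bilayer and analyse it:

```r
library(bilayerdomains)

res <- run_pipeline(list(
  synthetic = list(lattice_side = 32, coupling = 0.8,
                   interleaflet_coupling = 0.5, sweeps = 3e5,
                   seed = 171, n_frames = 16),
  window_fraction = 0.25))
print(res)
#> <bilayer_analysis> 4 frame(s) analysed, phase: two_phase
#>   A_L 0.554 nm^2 (ordered 0.538 / disordered 0.576)
#>   overlap 0.953, xi 36.5 nm, persistence 0.918
print(res$verdict)
#> <phase_verdict> two_phase
#>   decay: linear preferred (AICc lin -186.6 vs exp -179.0)
#>   overlap 0.953, persistence 0.918, xi 36.5 nm (spacing 1.18)
```

Reading the numbers: the mean area per lipid is 0.554 nm², smaller inside
the ordered clusters (0.538) than outside (0.576) — ordered phases pack
tighter. The ordered clusters are almost pure saturated lipid
(`res$summary$C_sat` = 0.995), the leaflets are strongly in register
(overlap 0.953, far above the ~0.5 independence value), the RDF decays
linearly rather than exponentially, and the density maps persist across
windows: domains of a coexisting phase, not fluctuations. Running the same
pipeline with `coupling = 0` returns `one_phase` with overlap at the
independence value.

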