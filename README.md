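# memblens

Analysis of planar lipid bilayers and cooperative membrane binding, aimed at
studies of how sterols — cholesterol and synthetic cholesterol analogs such
as imidazolium-based ones — integrate into and reorganize phospholipid
membranes. Given bilayer configurations or trajectories (GRO, PDB, DCD) plus
a topology mapping residue names to reference atoms, memblens computes:

* **Acyl-chain order parameters** `S = ⟨(3 cos²α − 1)/2⟩`, where `α` is the
  angle between every-second-carbon segment vectors and the *average leaflet
  tilt* (the normalized mean first-to-last carbon vector of the leaflet's
  phospholipid chains), with median aggregation across lipids and
  ordered/disordered phase classification at the strict `S > 0.7` boundary.
* **Sterol insertion depth** `Δz = ⟨z_C3⟩ − ⟨z_P⟩` per leaflet (negative =
  buried toward the bilayer center), **sterol tilt-angle distributions**
  against the leaflet normal, and **number-density profiles** of reference
  atoms along the normal.
* **Lateral segregation**: the fraction of DPPC neighbors among phospholipid
  neighbors around a chosen species (lateral minimum-image cutoff, same
  leaflet, sterols excluded from the denominator), as a time series with
  last-25% tail averaging and **Flyvbjerg–Petersen blocking** standard
  errors. Calibration levels: 0.4 = random mixing at 40% DPPC among
  phospholipids, 0.9 = complete segregation.
* **Cooperative binding**: Hill fits
  `y(c) = B_max·cⁿ/(Kⁿ + cⁿ)` to equilibrium isotherms (e.g. QCM-D annexin
  A2 binding), returning `n_Hill`, `K`, `B_max` with asymptotic standard
  errors and `R²` as a classed model object with the usual
  `print/summary/coef/predict/plot` methods.
* A **synthetic bilayer generator** with known ground truth — controllable
  chain order, lateral mixing state (random / patch / checkerboard), sterol
  depth and tilt, and AR(1)-like frame-to-frame mixing correlation — used
  throughout the test suite to validate every estimator.

See `vignettes/membrane-analysis.Rmd` for the models, conventions and design
choices in detail.

## Worked example

```r
library(memblens)

cfg <- synth_config(lattice_nx = 10, lattice_ny = 10,
                    composition = c(DPPC = 0.34, DLiPC = 0.5, CHOL = 0.16),
                    order_noise_sigma = 0.25, sterol_depth_nm = -0.9,
                    sterol_tilt_deg = 15, n_frames = 16,
                    frame_corr_rho = 0.6, seed = 42)
traj <- generate_trajectory(cfg)

compute_order(traj, species = "DPPC")
#> Chain order parameter: DPPC over 68 lipids, 16 frame(s)
#>   aggregate S: median = 0.9531, mean = 0.9531 (reporting median)
#>   phase: ordered (threshold S > 0.70)
#>   leaflet tilt: upper 0.29 deg, lower 0.26 deg

sterol_depth(traj, "CHOL")
#> Sterol insertion depth (CHOL), 16 frame(s); negative = buried:
#>   upper  dz = -0.9000 +/- 0.0000 nm (blocking SE)
#>   lower  dz = -0.9000 +/- 0.0000 nm (blocking SE)
#>   pooled dz = -0.9000 +/- 0.0000 nm (blocking SE)

segregation_series(traj, center_species = "DPPC")
#> DPPC-neighbor fraction around DPPC: 16 frames, cutoff 1.00 nm
#>   tail mean (last 4 frames) = 0.4026 +/- 0.0153 (naive SE)
#>   reference levels: 0.9 segregated, 0.4 random
```

The chain jitter of 0.25 rad leaves the bilayer well ordered (median S =
0.95, classified ordered); the imposed sterol depth (−0.9 nm) is recovered
exactly on this noise-free-in-z substrate; and the randomly mixed 0.4/0.6
DPPC/DLiPC composition sits on the 0.4 random-mixing reference line.

Fitting a cooperative isotherm (concentrations in µM, synthetic data from a
Hill curve with n = 1.9 plus noise):

```r
set.seed(7)
conc <- c(0.05, 0.1, 0.2, 0.4, 0.8, 1.6, 3.2, 6.4)
resp <- 1.0 * conc^1.9 / (0.45^1.9 + conc^1.9) + rnorm(8, 0, 0.02)
fit <- fit_hill(conc, resp)
fit
#> Hill binding-isotherm fit
#>   n_hill = 1.859 +/- 0.14, K = 0.4712 +/- 0.023, Bmax = 1.004 +/- 0.02
#>   R^2 = 0.9974; positive cooperativity (n_hill > 1)
hill_predict(fit, 0.45)
#> [1] 0.4806
```

`n_hill > 1` with a sigmoidal isotherm indicates positive cooperativity; the
generating coefficient 1.9 is recovered within one standard error.

End-to-end runs with TSV + JSON outputs go through `run_pipeline()` (see
`?run_pipeline`), or the thin CLI at `inst/scripts/memblens.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts","memblens.R",package="memblens"))')" \
    run --config run.yaml --out results/
```

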