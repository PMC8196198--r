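---
title: "Bilayer order, sterol insertion, lateral segregation and cooperative binding with memblens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bilayer order, sterol insertion, lateral segregation and cooperative binding with memblens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memblens)
```

## Scope

memblens quantifies how sterols (cholesterol and cholesterol analogs such as
the imidazolium-based CHIM) integrate into planar phospholipid bilayers and
reshape them: the orientational order of acyl chains, the depth at which a
sterol sits below the phosphate plane, its tilt relative to the membrane
normal, the lateral segregation of saturated (DPPC) from unsaturated (DLiPC)
phospholipids, and — on the wet-lab side — the cooperativity of
protein-membrane binding isotherms. The package analyzes configurations and
trajectories; it does not run molecular dynamics. A synthetic bilayer
generator with fully known ground truth serves as the test substrate, so
every estimator in the package is validated against configurations whose
order, mixing state, sterol depth/tilt and temporal correlation were imposed
by construction.

## The chain order parameter

For every acyl chain, segment vectors connect every second carbon,
$\mathbf{s}_i = \mathbf{r}_{i+2} - \mathbf{r}_i$. Let $\alpha_i$ be the angle
between $\mathbf{s}_i$ and the *average leaflet tilt* — the normalized mean
over all phospholipid chains in that leaflet of the first-to-last carbon
vector, each oriented along the leaflet's inward normal before averaging.
The per-segment order parameter is the frame average of the second Legendre
polynomial,

$$S = \left\langle \tfrac{1}{2}\left(3\cos^2\alpha - 1\right)\right\rangle,$$

the universal chain-order convention: $S = 1$ for segments parallel to the
reference, $0$ for an isotropic distribution, $-0.5$ for perpendicular
segments. Referencing $\alpha$ to the leaflet tilt rather than the raw
z axis makes $S$ insensitive to a collective chain tilt, which is a feature
of gel-like ordered phases.

Aggregation: per-lipid values are means over both acyl chains and all
segments; the reported aggregate is the **median across lipids** by default
(the mean is always reported alongside). A bilayer is classified **ordered**
when the aggregate strictly exceeds 0.7 and **disordered** otherwise — a
value of exactly 0.70 is disordered. The 0.7 boundary is where
DPPC/cholesterol mixtures show their nonlinear order increase; it is a
convention of the analysis, not a fitted quantity.

Two choices here were genuinely open and are exposed as options:

* "Every second carbon" is ambiguous between all overlapping segments
  ($i \to i+2$ for every $i$) and the odd, non-overlapping sublist.
  `compute_order(segment_mode = "all")` (default) maximizes samples;
  `"stride2"` gives the non-overlapping variant.
* Whether the median is taken across lipids, segments, or both is likewise
  ambiguous; memblens aggregates across lipids after averaging a lipid's
  segments, and reports per-segment profiles so other axes can be inspected.

The tilt reference is recomputed per frame and per leaflet, and sterols never
enter the tilt or the order statistics.

## Leaflet assignment

Leaflets are defined by the phosphate z position relative to the global
phosphate midplane (sterols by their reference carbon). This is adequate for
planar bilayers — the only geometry in scope — and is recomputed every frame
so flip-flop is tolerated. Ties (a reference atom exactly on the midplane) go
to the upper leaflet; this is a measure-zero tie-break chosen for
determinism. The assignment is invariant under rigid translations; boxes must
be orthorhombic (triclinic cells are rejected rather than silently
mis-imaging; planar bilayers under semi-isotropic pressure coupling live in
rectangular boxes).

## Sterol insertion depth, tilt and density profiles

The insertion depth is
$\Delta z = \langle z_{\mathrm{C3}}\rangle - \langle z_{\mathrm{P}}\rangle$
per leaflet, where C3 is the carbon bearing the sterol hydroxyl (or its
analog equivalent) and P the phosphate of the same leaflet's phospholipids.
The sign convention is **negative toward the bilayer center** in both
leaflets (lower-leaflet values are z-mirrored before averaging); the default
synthetic depth of -0.9 nm is typical of cholesterol's C3 below the
phosphate peak. Which two atoms define the sterol ring axis for the tilt is
not standardized; the topology spec makes the pair explicit and
user-settable (default C17 to C3, tail to head). Tilt angles are measured
against the outward leaflet normal and folded into [0°, 90°]; folding guards
against mis-oriented axis definitions. Number-density profiles of named
reference atoms are accumulated relative to the per-frame phosphate midplane
and normalized by box area x bin width x frames, so each profile integrates
exactly to the class's mean atom count. The default bin width of 0.1 nm
resolves phosphate peaks at typical box heights without starving counts.

## Lateral segregation

The segregation statistic is the fraction of DPPC lipids among the
*phospholipid* neighbors of a center lipid (sterols never enter the
denominator), averaged over centers, per frame. Neighbors are reference
atoms within a lateral (xy) minimum-image cutoff in the same leaflet. The
criterion itself is a documented choice: 1.0 nm captures the first
coordination shell at typical phospholipid packing (and, at the generator's
0.8 nm lattice spacing, reproduces 4-connected lattice neighbors). The
calibration is cutoff-robust where it matters: under uniformly random
placement the expected fraction equals the DPPC mole fraction among
phospholipids for *any* cutoff, which the tests verify at three cutoffs.
Two reference levels anchor interpretation, following the convention for a
2:3 DPPC/DLiPC mixture: **0.4 = random mixing** (DPPC is 40% of
phospholipids) and **0.9 = complete segregation**. The 0.9 level is
geometry-dependent — a perfect 20x20 patch in a periodic lattice scores
exactly (324 + 54 + 2)/400 = 0.95 under the nearest-neighbor criterion,
and finite patches with rougher boundaries score lower.

Time series are summarized by the mean over the **last 25% of frames**
(`tail_fraction = 0.25`), with a blocking-method standard error. Centers
with zero phospholipid neighbors have an undefined ratio; they are excluded
from the frame mean and counted in a diagnostics field. Both leaflets are
pooled by default.

## Blocking-method errors

Correlated time series make naive standard errors optimistic. memblens
implements Flyvbjerg-Petersen blocking: the series is repeatedly
pair-averaged, the naive SE is computed at each level, and the reported SE is
the plateau value — the first level whose successor stops increasing by more
than the level's own uncertainty $\mathrm{SE}_k/\sqrt{2(n_k-1)}$. If no
plateau is reached the maximum over levels is returned and flagged. For iid
data this reduces to $\sigma/\sqrt{N}$; for a process with geometric
autocorrelation $\rho^k$ it converges to
$\sigma/\sqrt{N}\cdot\sqrt{(1+\rho)/(1-\rho)}$, the closed form the tests
check at $\rho = 0.9$, $N = 2^{14}$ (tolerance 25%; the blocking SE itself
has ~8% sampling spread at that length, so tests average a few series).

## Cooperative (Hill) binding

QCM-D-style equilibrium isotherms are fitted with the Hill model

$$y(c) = \frac{B_{\max}\, c^{\,n}}{K^{\,n} + c^{\,n}}$$

by Levenberg-Marquardt least squares (`minpack.lm`), with data-driven starts
($B_{\max,0}$ = max response, $K_0$ = interpolated half-max concentration,
$n_0 = 1$), asymptotic (Jacobian-based) parameter standard errors and
$R^2 = 1 - SS_{res}/SS_{tot}$. $n > 1$ is reported as positive cooperativity
— the signature of sterol-dependent annexin A2 membrane binding, where
coefficients near 1.9 have been observed. Fitting is unweighted in linear
response space unless per-point standard deviations are supplied
(then $1/\mathrm{sd}^2$ weights); no transform is applied because none is
standard for these isotherms. Fixing $n$ (`n_fixed = 1`) gives the nested
Langmuir model. Non-convergence is reported via `converged = FALSE` with
diagnostics, not as an error. The fit is equivariant: rescaling
concentrations by $\lambda$ scales only $K$, rescaling responses by $\mu$
scales only $B_{\max}$ and its SE.

Real isotherm data points for the published annexin A2 measurements are not
available, so the tests validate *parameter recovery*: isotherms generated at
$n = 1.88$ with 3% Gaussian noise are refitted 200 times and the mean
recovered coefficient must sit within one standard error of the generating
value.

## The synthetic bilayer generator

`generate_frame()`/`generate_trajectory()` build two mirror-symmetric
leaflets of lipids on a square lattice (0.8 nm spacing, a typical
phospholipid nearest-neighbor distance):

* **Chains.** Each phospholipid carries two zigzag chains (0.127 nm rise per
  carbon, the all-trans projection). Each C-C step direction is the leaflet
  director (normal tilted by `leaflet_tilt_deg` toward +x) rotated by an
  independent Gaussian angle of sd `order_noise_sigma` about a random
  perpendicular axis. The alternating zigzag offset is applied per position
  with opposite phase on the two chains, so it cancels exactly both in every
  $i \to i+2$ segment and in the lipid-averaged first-to-last vector — at
  zero noise the computed order parameter is exactly 1 and the recovered
  tilt exactly the imposed one. Because consecutive segments share a step,
  the mapping from jitter to expected $S$ is validated against a Monte-Carlo
  oracle that simulates the same two-step construction directly.
* **Sterols** are minimal: the C3 reference carbon anchored
  `sterol_depth_nm` from the leaflet phosphate plane, a ring-centroid proxy
  and a C17 axis atom realizing `sterol_tilt_deg` with random azimuth. All
  in-scope statistics use only reference atoms, so no full sterol topology
  is needed.
* **Mixing modes**: `random` (uniform placement; largest-remainder counts
  conserve composition to within one lipid per species), `patch` (a central
  square or disc DPPC patch in the remaining phospholipid matrix, sterols
  interspersed at random) and `checkerboard` (two species at 1:1, exact
  alternation — every nearest neighbor is the other species).
* **Temporal correlation.** Frame-to-frame mixing noise is a
  random-transposition Markov chain on the per-leaflet species labels:
  composition is conserved exactly, and the number of swaps per frame is set
  so a site keeps its label with probability $\sqrt{\rho}$. The neighbor
  fraction is a pair statistic (center label x neighbor label), so its
  lag-1 autocorrelation is $\rho$ (`frame_corr_rho`), decaying geometrically
  with lag — the AR(1) structure whose integrated autocorrelation the
  blocking method must recover. `frame_corr_rho = 0` reshuffles every frame.
  Swaps are global-range: in `random` mode the chain is stationary; in
  `patch` mode it is a slow mixing relaxation (the patch erodes), which is
  used deliberately to emulate slow demixing but means patch trajectories
  are not stationary fluctuations around a fixed mean.
* Default composition is DPPC at 40% of phospholipids (2:3 DPPC/DLiPC),
  the reading consistent with a random-mixing level of 0.4.

What the generator does **not** emulate: force-field energetics, thermal
chain isomerization (jitter is white per frame), headgroup structure, area
fluctuations, leaflet flip-flop, curvature, and local (diffusive) lateral
dynamics — swaps teleport lipids. Tests passing on this substrate therefore
validate the *estimators* (geometry, counting, error analysis), not any
physical prediction about real membranes.

## Numerical conventions and edge cases

* Units: nm and degrees internally everywhere; PDB I/O converts to/from
  Angstrom at the boundary; GRO files are nm with 3 decimals (0.0005 nm
  round-trip precision), PDB 3 decimals in Angstrom.
* Positions are wrapped into [0, box) on load; all intramolecular vectors
  and lateral distances use the minimum image, so wrapped chains stay
  intact. Cutoffs must stay below half the lateral box.
* Degenerate inputs raise typed errors: all phosphates on one side of the
  midplane (degenerate bilayer), zero-length sterol axes, cutoffs at or
  beyond the half box, chains shorter than 3 carbons, triclinic boxes,
  non-positive or non-increasing concentrations.
* Trajectories shorter than 8 frames fall back from blocking to naive
  standard errors and say so (`se_method`).
* A leaflet without sterols is reported absent in depth results, not an
  error.

## Problem sizes

The test suite runs on deliberately small systems: lattices between 3x3 and
40x40 lipids per leaflet, chains of 4-16 carbons, trajectories up to 1024
frames, 50-seed Monte-Carlo averages for the mixing calibration, 200
replicate isotherms, and $2^{14}$-point series for the blocking closed form.
These sizes keep the full suite under a minute per file while leaving
Monte-Carlo tolerances (stated per test) comfortably above sampling noise.

## Limitations

* No MARTINI/coarse-grained naming, vesicles, curved membranes or
  electron-density profiles; number densities of named atoms only.
* XTC trajectories are not readable (no R-native reader); use DCD,
  multi-frame GRO or multi-model PDB.
* The neighbor criterion, sterol axis pair and leaflet rule for deep sterols
  are documented conventions, not measurements; conclusions that depend on
  them should be checked against the exposed options.
* Temperature and composition scans of real bilayers require actual MD
  sampling and are out of scope; the package only analyzes whatever
  configurations it is given.
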