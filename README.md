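# aggsurf

Geometry and surface analysis for self-assembled surfactant aggregates in
coarse-grained particle simulations.

Simulations of surfactants such as AOT produce trajectories in which
molecules assemble into micelles, vesicles, bicelles and lamellar bilayers.
`aggsurf` turns those trajectories into quantitative structural observables,
for simulators who need reproducible per-aggregate statistics and a defensible
equilibration cut:

- **Aggregate detection** — single-linkage clustering of tail-group beads
  under periodic boundaries at `r_cut = (5/4) σ_LJ` of the smallest tail bead
  (5.875 Å for regular 4.70 Å beads, 4.250 Å for tiny 3.40 Å beads), with
  unwrapping across the boundary and percolation flagging.
- **Shape metrics** — radius of gyration
  `R_g = sqrt(Σ m_i r_i² / Σ m_i)`; ellipsoid semiaxes `a ≥ b ≥ c` recovered
  algebraically from the principal moments of inertia
  (`A = M/5 (b² + c²)` and cyclic); coordinate-pair eccentricities
  `e_ab = sqrt(1 − b²/a²)`, `e_ac = sqrt(1 − c²/a²)` with
  spherical / prolate / oblate / triaxial classification.
- **Willard–Chandler surfaces** — Gaussian kernel density (bandwidth 4.0 Å,
  grid 2.0 Å, isovalue ρ_max/3) on a periodic supercell or under the minimum
  image convention; isosurface triangulation stitched across the periodic
  seam; per-component area and signed enclosed volume, hence surface area and
  volume per surfactant.
- **Bilayer geometry** — leaflet identification by mesh connectivity,
  vertex-wise nearest-neighbor thickness distributions, area per headgroup.
- **Equilibration detection** — marginal-standard-error-rule truncation
  `MSE(k) = (n−k)⁻² Σ_{i≥k} (Y_i − Ȳ_{n,k})²` plus an augmented
  Dickey–Fuller stationarity check at 99% confidence; binned means with
  bootstrap confidence intervals.
- **Synthetic structures** — deterministic generators for ellipsoidal
  micelles, vesicles, bicelles, box-percolating lamellae, monomers and
  dispersed mixtures with known ground truth, so the whole chain is testable
  without MD data.

I/O covers GRO coordinate files (nm ↔ Å at the boundary), a self-describing
JSON trajectory container, PLY/OBJ mesh export, and an
atomistic→coarse-grained center-of-geometry mapping utility.

## Worked example

Build a prolate synthetic micelle, detect it, and measure shape and surface:

```r
library(aggsurf)

g <- make_ellipsoid_micelle(60, 25, 25, n = 350, noise = 1, seed = 42)
aggs <- find_aggregates(g$frame)
a <- aggs[[1]]

sd_ <- shape_descriptors(a)
s <- aggregate_surface(a)
pm <- per_surfactant_metrics(s$area, s$volume, a$n)
```

Output for this run:

```
aggregation number: 350  percolating: FALSE
R_g = 31.25 A; semiaxes = (61.9, 22.9, 22.9) A
CPE: e_ab = 0.929, e_ac = 0.929 -> prolate
area = 16401 A^2, volume = 108789 A^3
area/N = 46.9 A^2, volume/N = 310.8 A^3, SA:V = 0.151 A^-1
```

All 350 surfactants land in one non-percolating aggregate. The recovered
semiaxes track the generator's (60, 25, 25) Å ground truth; the two
eccentricities are equal and large, which is the prolate signature
(`e_ab ≈ e_ac ≫ 0`), and the analytic value for a 60:25 axis ratio is
`sqrt(1 − (25/60)²) = 0.909`. The surface metrics come from the
Willard–Chandler isosurface of the aggregate's bead density.

For whole-trajectory analyses use `run_isotropic_pipeline()` (clustering →
shape → surfaces → property timeseries → MSER/ADF convergence report) and
`run_bilayer_pipeline()` (leaflet splitting → thickness and area-per-headgroup
distributions for frames after `t_min`); both accept an `output_dir` to write
CSV/JSON reports alongside the resolved parameters.

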