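---
title: "Characterizing coarse-grained surfactant aggregates: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing coarse-grained surfactant aggregates: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggsurf)
```

## The problem

Coarse-grained (CG) molecular simulations of surfactants such as AOT
(sodium bis(2-ethylhexyl) sulfosuccinate) produce trajectories in which
molecules self-assemble into micelles, bicelles, vesicles or lamellar
bilayers. Characterizing those structures quantitatively requires a chain of
geometric analyses: detecting which molecules belong to which aggregate under
periodic boundary conditions, measuring each aggregate's size and shape,
constructing an instantaneous interface to measure surface area and enclosed
volume, splitting bilayers into leaflets, and deciding when the simulated
observables have equilibrated. `aggsurf` implements that chain as composable
R functions, together with deterministic generators of synthetic structures
with known ground truth so that every stage can be validated without running
molecular dynamics.

## Aggregate detection

Two surfactants belong to the same aggregate when any pair of their
*tail-group* beads lies within a cutoff `r_cut` under the minimum image
convention; aggregates are the connected components (single linkage) of this
contact relation. The cutoff is

\[ r_\mathrm{cut} = \tfrac{5}{4}\,\sigma_\mathrm{LJ}, \]

where \(\sigma_\mathrm{LJ}\) is the Lennard-Jones zero-crossing distance of
the *smallest* tail bead in the topology. For regular (R-class,
\(\sigma = 4.70\) Å) tail beads this gives 5.875 Å; for tiny (T-class,
\(\sigma = 3.40\) Å) beads 4.250 Å. Scaling the cutoff with \(\sigma\)
respects the different equilibrium tail-tail distances of models built at
different mapping resolutions. The partition always covers every surfactant
(monomers are singleton clusters); the reporting threshold (aggregation
number \(\ge 5\) by default) filters *outputs* only, because normalized
aggregation numbers need the full partition in the denominator.

Clustering uses a cell list with cells at least `r_cut` wide, and falls back
to an exact all-pairs scan for small systems; the two paths are
interchangeable and the suite checks the partition against independent
brute-force and graph-library oracles.

Each aggregate is then *unwrapped*: molecules are first made whole, then a
breadth-first traversal of the molecule contact graph assigns integer lattice
shifts so every contact uses its minimum image. If a consistent assignment
does not exist, the cluster is connected to its own periodic image — it
percolates the box (e.g. a lamella) — and it is flagged instead of unwrapped.
Percolating aggregates are excluded from shape and per-aggregate surface
analysis, where a center of mass is undefined.

## Shape metrics

For a non-percolating aggregate each surfactant is reduced to one point (the
mass-weighted mean of its beads, with the summed bead mass); a bead-resolved
variant is available via `surfactant_points(..., resolution = "bead")`. The
radius of gyration is

\[ R_g = \sqrt{ \frac{\sum_i m_i |\vec r_i|^2}{\sum_i m_i} } \]

with \(\vec r_i\) the displacement of surfactant \(i\) from the mass-weighted
center. The inertia tensor's ascending eigenvalues \(A \le B \le C\) are
matched to a uniform solid ellipsoid with semiaxes \(a \ge b \ge c\):

\[ A = \tfrac{M}{5}(b^2 + c^2), \quad B = \tfrac{M}{5}(a^2 + c^2), \quad
   C = \tfrac{M}{5}(a^2 + b^2), \]

inverted algebraically (`principal_semiaxes()`), and summarized by the
coordinate-pair eccentricities

\[ e_{ab} = \sqrt{1 - b^2/a^2}, \qquad e_{ac} = \sqrt{1 - c^2/a^2}. \]

Spheres sit near the origin of the \((e_{ab}, e_{ac})\) plane, prolate
ellipsoids on the diagonal, oblate ones along the \(e_{ac}\) axis, triaxial
ones in between. The published analyses classify this map graphically;
`classify_ellipsoid()` makes the regions explicit with two tolerances,
`sphere_tol = 0.15` ("close to zero") and `split_tol = 0.10` (maximum
\(e_{ac} - e_{ab}\) still counted as prolate). Both are configurable; the
defaults were chosen once to separate the four synthetic shape classes and
are deliberately coarse — eccentricities are extremely sensitive near
sphericity, where \(e^2 \approx 2\,\Delta I / I\) amplifies small moment
differences.

`experimental_rg()` converts an experimentally determined oblate axis ratio
\(\varepsilon\) and minor semiaxis \(c\) into a comparable radius of
gyration, \(R_g = (c/\sqrt5)\sqrt{1 + 2\varepsilon^2}\).

## Willard–Chandler surfaces

The instantaneous interface of an aggregate is the level set of the Gaussian
kernel density of all its surfactant beads (heads and tails; solvent and
ions never contribute), with bandwidth \(h = 4.0\) Å, evaluated on a grid of
spacing 2.0 Å, at the isovalue \(\rho_\mathrm{max}/3\). The density is left
unnormalized because the isovalue is relative to the field maximum, so any
common factor cancels. "Bandwidth" is interpreted as the Gaussian standard
deviation in \(\exp(-r^2/2h^2)\), the standard KDE convention. Kernels are
truncated at \(4h\); the omitted tail is \(\sim e^{-8}\) per contribution,
which sums to at most a few \(10^{-3}\) relative at the dimmest retained
nodes and far less near the isovalue — the suite bounds it against an
untruncated periodic double-loop sum.

Periodic boundaries are handled in two selectable ways: a 3×3×3 *supercell*
(every bead contributes through its 27 replicas, each clipped to the central
grid) or the *minimum image* convention (each bead contributes through its
nearest image). Whenever the box is wider than twice the truncation radius
the two modes produce identical fields; the package measures their enclosed
volume difference on a synthetic micelle battery as part of its acceptance
checks (it is ~0, comfortably below the few-percent level reported for
GPU-oriented supercell reimplementations of this analysis).

The isosurface is extracted by marching tetrahedra on a Kuhn (six-tetrahedron)
subdivision of each grid cell, with vertices linearly interpolated along
tetrahedron edges. This subdivision was chosen over classic table-based
marching cubes because it is translation-consistent and has no ambiguous
cases: the resulting mesh is always a closed 2-manifold (every edge shared by
exactly two triangles), which the volume computation requires. Vertices are
keyed by grid edge, so the mesh is stitched seamlessly across the periodic
boundary; a component that wraps the box (a lamella leaflet) remains a single
connected component on the torus. Triangles are oriented outward from the
dense phase.

Per-component area is the sum of triangle areas. Volumes come from the
divergence theorem (flux of \((0,0,z)\)) after each component is *unfolded*:
a face-by-face traversal assigns lattice offsets so the component's geometry
is contiguous; an inconsistent offset identifies the axes along which the
component percolates. Enclosed volume is reported per component as a signed
quantity — outward-oriented outer surfaces are positive, a vesicle's inner
surface (oriented into the lumen) is negative — so the total is the
*material* (shell) volume, and the largest single-component magnitude is also
reported as the lumen-inclusive outer volume. Both are emitted because either
convention can be meant by "volume per surfactant" for a closed bilayer
shell; for convex micelles they coincide.

A geometric subtlety worth stating explicitly: the isosurface of a sharp,
slab-like bead distribution does not sit on the outermost beads. For a
uniform slab of thickness \(T\) the level \(\rho_\mathrm{max}/3\) is crossed
a distance \(\delta \approx 0.44\,h\) *outside* each face (`wc_slab_offset()`
solves the closed-form crossing). Measured thicknesses and shell volumes of
idealized synthetic structures therefore exceed their nominal bead-span
values by \(2\delta\); the tests compare pipeline output against the
offset-corrected closed forms rather than pretending the offset does not
exist. On thermally broadened real interfaces the same convention places the
surface close to the headgroups.

## Bilayers

A box-percolating bilayer yields one isosurface component per leaflet. The
two largest components by area are taken as the leaflets (extra components,
e.g. a coexisting micelle, are counted and warned about) and ordered by mean
height. Thickness is the pooled distribution, over every vertex of each
leaflet, of the minimum-image distance to the nearest vertex of the other
leaflet; the area per headgroup divides the combined leaflet area by the
number of surfactants. `run_bilayer_pipeline()` applies this per frame for
times beyond a configurable `t_min` (30 ns by default, matching the box-area
convergence of the lamellar systems this analysis targets) and pools the
distributions.

## Equilibration detection

Per-aggregate properties (surface area per surfactant, volume per
surfactant, area-to-volume ratio, \(R_g\), aggregation number) are reduced to
one system series per property by averaging across the aggregates coexisting
at each time step (aggregation number \(\ge 5\) only). The marginal standard
error rule picks the truncation index

\[ \mathrm{MSE}(k) = \frac{1}{(n-k)^2} \sum_{i=k}^{n-1}
   \left(Y_i - \bar Y_{n,k}\right)^2, \]

minimized over \(k \in [0, \lfloor 3n/4 \rfloor]\) with ties broken toward
smaller \(k\); the \((n-k)^{-2}\) prefactor rewards keeping data while the
sum penalizes deviation from the retained mean. The upper cap keeps the
prefactor from degenerating as \(k \to n\); an optional batch size supports
block-averaged (MSER-5 style) variants, but the unbatched rule is the
default. A suffix-sum implementation reproduces the direct two-pass
evaluation exactly, which the suite asserts.

Stationarity of the retained segment is verified with an augmented
Dickey–Fuller test: the regression includes a constant and no trend, the
augmentation lag is selected by AIC up to \(\lfloor (n-1)^{1/3} \rfloor\),
and the null (unit root) is rejected when the statistic falls below the
MacKinnon response-surface critical value at the requested confidence (99%
by default). These regression conventions are stated here as assumptions:
the variant used by the equilibration tooling this mirrors is not fully
specified in the literature it comes from. The implementation was checked
against `statsmodels.tsa.adfuller` during development and behaves as
expected on white noise (stationary) versus random walks (non-stationary) in
at least 95% of seeded replicates. Constant series short-circuit to a
degenerate "stationary" verdict with a warning rather than an error, since a
constant observable is the equilibrated limit.

The system convergence time is the maximum truncation time across
properties. For reporting, `bin_timeseries()` provides fixed-width bin means
(100 ns default) with seeded percentile-bootstrap 95% confidence intervals.

## Synthetic structures and what they do (not) show

The generators build idealized structures from head-to-tail surfactant
chains anchored on analytic surfaces:

- `make_ellipsoid_micelle()`: heads quasi-uniform on an ellipsoid, tails
  walking radially inward (clamped at the core). Head placement uses a
  deterministic Fibonacci lattice rather than iid sampling: near sphericity
  the recovered eccentricities scale like the square root of the relative
  moment anisotropy, and iid placement at a few hundred surfactants yields
  spurious \(e \sim 0.4\); the lattice keeps anisotropy at the \(10^{-3}\)
  level so ground-truth recovery is meaningful at realistic aggregation
  numbers.
- `make_vesicle()`: two concentric leaflets, heads outward/inward, chains
  spanning just short of mid-shell (a half-bead stagger avoids an artificial
  density spike where opposing tails meet).
- `make_bicelle()`: a disc-shaped bilayer patch with a semicircular rim,
  sunflower-lattice anchors.
- `make_lamella()`: two jittered square lattices of opposing chains spanning
  the full box cross-section, offset by half a cell so the tail contact
  graph percolates; optional in-phase sinusoidal corrugation.
- `make_dispersed_system()`: places components with guaranteed clearance and
  returns the ground-truth partition; `make_monomers()` scatters singletons.

The default synthetic surfactant has two head beads (S-class) and four tail
beads. Tail beads default to the R size class: the derived cutoff
(5.875 Å) then matches the geometry of an ideal flat bilayer at
~50 Å² per headgroup, whose zig-zag inter-leaflet contact distances
(~4.9 Å) would fall outside the 4.250 Å cutoff of T-class tails. Positional
noise is isotropic Gaussian displacement per bead — the simplest stand-in
for thermal jitter.

These fixtures validate the *analysis chain*, not the physics: they have no
energetics, no solvent, no bead-size excluded volume, and their interfaces
are sharp rather than thermally broadened. Passing tests demonstrate that
the geometry pipeline recovers known ground truth under controlled
conditions; they say nothing about force-field accuracy on real systems.

## Numerical choices and edge cases

- Internal unit is Ångström everywhere; GRO files (nm) are converted at the
  boundary, since every analysis constant (4.0 Å bandwidth, 2.0 Å grid,
  cutoffs) is naturally expressed in Å.
- Only orthorhombic boxes are supported; triclinic GRO box lines raise an
  explicit unsupported-format error.
- The density grid uses the spacing closest to the requested one that
  divides each box edge exactly, so the grid is genuinely periodic.
- Grid nodes with values exactly at the isovalue count as "inside"; the
  consistent rule keeps the mesh manifold.
- Rank-deficient inertia tensors (collinear aggregates) warn and return
  moments; moment triples violating the ellipsoid triangle condition raise
  an error rather than returning imaginary semiaxes.
- Aggregates with fewer than three surfactants get \(R_g\) but no ellipsoid
  descriptors (`NA` class).
- MSER requires at least 4 points; the ADF test at least 20 — shorter
  retained segments leave the stationarity verdict `NA`.
- Problem sizes used by the test suite and acceptance script (hundreds of
  surfactants, boxes of 10–40 nm, 20-aggregate batteries) were chosen to
  exercise every code path — periodic wrapping, percolation, nested
  components — at a few minutes' total runtime.

## Limitations

- The inertia-to-semiaxes inversion assumes a uniform solid ellipsoid; for
  hollow or shell-like aggregates the recovered axes are systematically
  scaled, though axis *ratios* (hence eccentricities and classification)
  remain accurate for the near-axisymmetric shapes that dominate in
  practice.
- Volumes of components that percolate along the flux axis (z) are undefined
  and reported as `NA`; xy-percolating lamella leaflets are handled.
- Aggregate identity is not tracked across frames (no fusion/fission
  lineage); analyses are per-frame, matching the statistics the pipeline
  reports.
- The binary-trajectory adapter contract is intentionally thin: any reader
  that yields `cg_frame` objects (e.g. via per-frame GRO exports) can feed
  `cg_trajectory()`; no binary parser is bundled.
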