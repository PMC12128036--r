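Package: aggsurf
Title: Aggregate Geometry and Surface Analysis for Coarse-Grained Surfactant Self-Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes self-assembled surfactant aggregates in coarse-grained
    particle simulations. Detects aggregates by single-linkage clustering of tail
    beads under periodic boundary conditions, unwraps them and flags percolation;
    computes per-aggregate radius of gyration, ellipsoid semiaxes from moments of
    inertia and coordinate-pair eccentricities with spherical, prolate, oblate or
    triaxial classification; builds Willard-Chandler instantaneous interfaces
    from a Gaussian kernel density on a periodic supercell and measures surface
    area and enclosed volume; splits bilayer meshes into leaflets and reports
    thickness and area per headgroup; detects equilibration of property
    timeseries by marginal-standard-error-rule truncation with an augmented
    Dickey-Fuller stationarity check. Ships deterministic generators for
    synthetic micelles, vesicles, bicelles, lamellae and dispersed mixtures with
    known ground truth, plus GRO readers and writers and an atomistic-to-CG
    mapping utility.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
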