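---
title: "Methods: core-sample morphometrics and phylogenetic allometry of jaw-joint trabecular bone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: core-sample morphometrics and phylogenetic allometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condylocore)
```

## The scientific problem

The mandibular condyle of the temporomandibular joint (TMJ) is loaded in
compression during mastication, so its internal trabecular (spongy) bone is
a natural candidate for carrying a signal of feeding ecology. The
alternative is that trabecular architecture simply scales with body size.
Distinguishing the two requires (i) a measurement protocol that removes
size from the raw geometry, (ii) mechanical performance measures from a
standardized specimen, and (iii) comparative statistics that account for
shared phylogenetic history and can re-introduce size explicitly.

`condylocore` implements that chain: standardized virtual core sampling of
triangle meshes, stress–strain reduction of compression records, and a
phylogenetic generalized least squares (PGLS) engine with an isometry
classification rule. Synthetic generators supply every input with known
ground truth, so each stage is testable without any archived scan data.

## Core sampling and morphometrics

A core is a cylinder aligned with the dorso-ventral axis through a
user-supplied anchor point. Its height is the extent of the mesh along that
axis through the anchor — operationally, the maximum height of the
articular structure at the sampling site — and its diameter is fixed at 50%
of the height. The 2:1 aspect means a single uniform scale factor
`s = 10 / h` standardizes any core to the 10 mm x 5 mm specimen, with
volumes scaling by `s^3` and areas by `s^2`.

The Boolean intersection of the trabecular solid with the cylinder uses a
voxel backend: the mesh is voxelized by parity ray casting (a `+z` ray per
voxel column; transversal surface crossings sorted, interior filled by
parity), the cylinder inequality is applied to voxel centers, and the
boundary of the surviving voxel set is extracted as a closed triangle mesh.
The anchor recipe, the voxel backend, and flat capping where trabeculae
meet the cylinder wall are all package conventions: the physical protocol
used interactive CAD tools and does not specify them. Voxelization was
chosen over exact mesh Booleans for robustness on thin trabecular struts;
its error is controlled by the pitch (default `h/200`) and the tests verify
convergence to analytic volumes (block, half-space, cylinder) within 1%.

Two numerical properties are worth knowing:

* The signed-tetrahedron volume of a voxel-boundary mesh equals the voxel
  count times `pitch^3` exactly, so volume error comes only from boundary
  voxel classification, O(pitch).
* The surface area of a voxelized (staircase) surface overestimates smooth
  lateral surfaces by up to 4/π. Relative structural complexity is
  therefore comparable *between cores processed at the same pitch* — which
  is how the measure is used — but is not an estimate of the smooth-surface
  area. Analytic validation of the area measure uses triangulated smooth
  cylinders instead.

Morphometrics are the enclosed volume (relative fill volume, mm³) and the
total surface area (relative structural complexity, mm²). Whether the flat
cut faces and caps belong in the surface total is ambiguous in the source
protocol; the headline value includes them, and
`measure_morphometrics()` also returns `surface_area_internal` with an
estimate of the cut-face area removed. Meshes with inward orientation
(negative signed volume) are flipped with a warning.

## Compression-test reduction

Stress is force over the standardized contact face, `A = pi * 2.5^2`
(19.63 mm² to the printed precision); strain is displacement over the
10 mm gauge height; displacement is re-zeroed at the first sample while
the 10 N preload is retained in the force channel (the protocol
standardizes initial load, not the zeroing convention).

The elastic modulus is the slope of the linear (elastic) region. No
published algorithm identifies that region, so the package's documented
rule is: slide a strain window of fixed width (default 0.01, at least 5
samples) along the curve, fit ordinary least squares in each, and take the
window maximizing R², reporting its endpoints for audit. Two guards
matter: only full-width windows compete (a truncated tail window with few
points can win on spurious R²), and exact R² ties — which occur on
noiseless piecewise-linear records — are broken toward the steepest slope,
i.e. the initial elastic segment. Maximum compressive strength is the peak
stress, reported both as stress (MPa) and force (N, `sigma_max * A`);
force is the headline to match the published measurement table. Replicates
(five prints per species in the physical protocol) are combined by
arithmetic mean with the standard deviation retained; the combiner is a
package convention.

The synthetic load-curve generator states the tested world: constant
crosshead rate 0.6 mm/min, sampling at 4 Hz, 10 N preload, and a piecewise
linear backbone — elastic rise at stiffness `E*A/h0` up to the yield
strain, a gentle hardening ramp (30% of elastic stiffness) to the peak
force, then softening at 50% of elastic stiffness. A perfectly flat yield
plateau cannot both start at the yield force and reach a distinct peak, so
the "plateau" is this shallow ramp; every segment is exactly linear, and
the elastic segment is the steepest, which is what makes the maximal-R²
rule consistent. Gaussian force noise (sd per config) is added
peak-preservingly: the designed peak sample is pinned at the true peak,
the first sample at the preload, and samples are clipped to
`[0, F_peak]` — so recovered strength is exact by construction and the
round-trip tests isolate modulus-estimator error. With the protocol's
4 Hz x 0.6 mm/min sampling, a 0.01-strain window holds 40 points, and the
single-record modulus standard error at 2 N noise is about 1.5%; the
replicate-averaged estimate is comfortably within 2% of truth.

## The comparative engine

`bm_covariance()` builds the Brownian-motion covariance from scratch by
accumulating each branch length over the tip pairs descending from it:
`C[i, j]` is the shared root-to-MRCA path length, `C[i, i]` the tip depth.
`pgls_fit()` whitens response and design with the Cholesky factor of `C`
(no explicit inverse), fits by QR, and reports coefficient standard
errors, two-sided t probabilities on `n - p` degrees of freedom, and the
Gaussian log-likelihood. Singular covariances (zero-length branches from
resolved polytomies) receive the documented `1e-8` diagonal jitter, with a
message. No Pagel's lambda or Ornstein–Uhlenbeck transformation is
applied: the analyses this package reproduces report plain
Brownian-motion PGLS, and the uniform branch-length configuration
(`set_uniform_branch_lengths()`) is the supplied sensitivity check.

The ecology battery fits each covariate in its own single-predictor model
(one regression coefficient per covariate row, as in the published
tables), never a joint multiple regression. Response variants for volume,
structural complexity, and strength are: size-included,
`ln(trait * size)`; and size-corrected, the PGLS residuals of the
size-included variant on `ln(size)` — by centroid size and by body mass.
"Corrected" is not defined in the source; phylogenetic residuals are this
package's documented convention, chosen because they make the
centroid-size- and body-mass-corrected versions genuinely different
columns, as the published tables show they must be. Response scales are a
package choice too: ln for the three size-variant traits (their
size-included versions span orders of magnitude), raw MPa for elastic
modulus — which, being size-independent by definition, runs once against
the eleven covariates plus relative surface area and relative fill volume
(13 predictors). Ordinal covariates are treated as numeric scores;
P values are uncorrected for multiple testing, matching the reporting
style of the tables being mirrored.

## Allometry and the isometry rule

`fit_allometry()` regresses `ln(trait)` on `ln(size)` under `C` and builds
Student-t confidence intervals for the slope at 95% and 99% with
`df = n - 2`. The published intervals imply a multiplier near 2.5 standard
errors, matching no standard level at df = 38; the conventional t
multiplier is used here and documented as such. Expected slopes follow
dimensional arguments — volume 1, surface area 2/3, strength 1, modulus
0 — with both size measures treated as 3-dimensional quantities.
Classification: expectation below the CI lower limit, positive allometry;
above the upper limit, negative; inside, isometric. A `1e-8`-scale
tolerance guards the comparison so the degenerate zero-width CI of
noiseless data cannot flip a call on float error. For the modulus, the
slope's own P value provides the complementary no-relationship check.

## What the synthetic world does and does not establish

The generators state one concrete world:

* **Meshes** — a smooth random plane-wave field (24 waves, frequencies
  0.6–1.4 x `complexity_scale`) thresholded at the `fill_fraction`
  quantile, so solid fraction and strut fineness are independently
  controllable; fill fraction is exact up to grid granularity by
  construction. A structure whose largest 6-connected component is under
  1% of the grid is rejected as degenerate dust. Real trabecular bone is
  anisotropic, plate-and-rod structured, and CT-derived; none of that is
  emulated, so green geometry tests establish correctness of the measuring
  instruments, not biofidelity.
* **Trees** — pure-birth (Yule, rate 1) trees; traits evolve by Brownian
  motion with `ln trait = intercept + slope * ln size + residual`.
* **Ecology** — eleven covariates with zero true effect on every trait
  (ordinal scores from small integer ranges, continuous fields Brownian on
  the tree, suborder as the root bipartition), matching the null findings
  the engine is expected to reproduce; the distributions are conventions,
  not published facts. Power checks are composed in the tests by injecting
  an effect into a trait directly, rather than through an effect-size dial
  inside the generator.
* **Pipeline defaults** — 40 species; true slopes vs ln centroid size of
  1 (volume), 1.42 (complexity), 0 (modulus), 1 (strength), i.e. the
  published point estimates; centroid size and body mass co-scaling
  isometrically (both 3-dimensional size measures) with total ln-scale
  spread 0.18 across the tree; trait magnitudes anchored to the measured
  ranges (volume ~140 mm³, complexity ~450 mm², modulus ~200 MPa,
  strength ~250 N); 5 replicate load curves per species at 2 N noise. The
  geometry stage runs on a configurable subset (default 2 species) purely
  for runtime — a pure-R voxel Boolean over 40 porous meshes would
  dominate the run — while mechanics and comparative stages cover all
  species.

Determinism is part of the contract: every generator takes an explicit
integer seed, saves and restores global RNG state, and the pipeline writes
an MD5 manifest that is byte-identical across repeated runs of the same
configuration.

## Known limitations

* Structural complexity from voxel cores is pitch-dependent (staircase
  area); compare only at matched pitch.
* The modulus estimator assumes an elastic region at least one window
  wide; specimens whose yield force is barely above preload (shallow,
  short elastic ramps) push the estimate upward under noise.
* PGLS assumes plain Brownian motion; no model selection across
  covariance transformations is offered.
* The mesh generator's porosity field is isotropic and single-scale; it
  cannot emulate oriented trabecular fabric.
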