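---
title: "Modeling the spectrin cortex: mechanics, myosin and the imaging pipeline"
author: "spectrinmesh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the spectrin cortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectrinmesh)
```

## The model

The actin-spectrin membrane skeleton is represented as a planar graph.
Nodes stand for crosslinkers and anchors: short actin filaments (free,
force-driven), focal adhesions (kinematically prescribed or fixed), and
stress-fiber connectors. Edges stand for filament bundles and carry one or
two mechanical elements:

* a **spring** element stores energy
  $U_s = \sum_j \tfrac{1}{2} k_s (d_j - d_0)^2$ when the edge length $d_j$
  deviates from its resting length $d_0$ — spectrin tetramers are pure
  springs with $d_0 = 180$ nm, the tetramer contour length;
* a **cable** element stores energy $U_c = \sum_j \tfrac{1}{2} k_c d_j^2$,
  so it always contracts — it models actomyosin contractility in stress
  fibers, focal-adhesion cables and myosin linkers/rods.

The force on node $l$ is the analytic gradient
$\bar F(\bar r_l) = -\partial U / \partial \bar r_l$ of the summed energy,
and motion is overdamped: adhesion complexes exert a viscous resistance
$\xi \bar v_l$, so positions obey
$\partial \bar r_l / \partial t = \bar F_l / \xi$, integrated with the
explicit Euler method. Inertia, thermal noise and out-of-plane deformation
are neglected; spectrin elasticity is linear (no unfolding plateau).

Two further mechanisms give the model its interesting behaviour:

1. **Detachment.** A compressed spectrin spring pushes its end nodes apart.
   When this expanding force $k_{s,S}(d_{0,S} - d_j)$ exceeds a threshold
   $F_{th}$, the actin–spectrin interface fails and the edge is removed,
   permanently. Only compression detaches by default — low-strain failure
   of the interface rather than bundle fragmentation. A configuration
   switch (`detachStretched`) extends the criterion to over-stretched
   edges; it is off by default because compression-only is the modeled
   failure mode, and the switch merely surfaces the alternative reading.
2. **Myosin.** Myosin is never colocalized with spectrin nodes, so myosin
   ends bind to the *centroid* of a spectrin triangle and their force is
   split equally among the three triangle nodes (the centroid Jacobian is
   $I/3$ per node); the attachment is virtual, not an extra degree of
   freedom. Stiff *linkers* connect the stress-fiber ends to the nearest
   free triangle; softer *rods* connect pairs of free triangles whose
   centroid separation lies in $(d_{min}, d_{max})$. When a host triangle
   loses a side, the myosin end re-targets a uniformly random free triangle
   within that annulus (around its other end) or is removed if none
   exists; linkers shorter than $d_{min}$ detach. Rods additionally turn
   over stochastically: per time step one addition attempt with probability
   $\Delta t\,\varphi_a$ and one removal of a uniformly chosen rod with
   probability $\Delta t\,\varphi_r$ (a literal Bernoulli draw per step,
   not Poisson thinning). A triangle is *free* when its three spectrin
   sides are attached and no myosin is currently bound to it — the
   occupancy exclusion prevents unphysical stacking of motors on one
   triangle.

### The per-timestep algorithm

Each step executes, in this order: per-edge forces; detachment of
over-threshold spectrin edges (their force no longer moves nodes this
step); Euler position update of free nodes; the focal-adhesion schedule
(prescribed vertical speed $v_A$ until $t_s$, zero afterwards); myosin
re-targeting after triangle breakage; the stochastic rod addition; the
stochastic rod removal. The order matters — it changes the event
statistics — and is fixed.

## Parameters

Units are nanometres and seconds; forces are in units of the reference
stiffness times nm, with the spectrin spring constant as the reference
($k_{s,S} = 1$). The resting length 180 nm is the tetramer contour length;
$d_{0,F}$ is computed from the as-built relaxed fiber geometry. Every other
constant is declared configuration: the defaults below were chosen **once**
so that the four scenarios reproduce the qualitative behaviours the model
is meant to show (cable-driven stretching, boundary-localized detachment
under constraint, myosin-driven interior bundle reduction with near-rest
final edge lengths, short rod lifetimes against persistent linkers), which
is also how the original modeling study says its parameters were set. They
were not revisited afterwards.

| parameter | default | meaning |
|---|---|---|
| `ksS` | 1 | spectrin spring constant (reference) |
| `d0S` | 180 nm | spectrin resting length |
| `kc` | 0.05 | generic cable (FA cables, mesh-fiber coupling) |
| `ksF`, `kcF` | 5, 0.05 | stress-fiber spring and cable |
| `kcL`, `kcM` | 0.1, 0.08 | myosin linker / rod cables (linkers stiffer) |
| `Fth` | 10 | detachment threshold (10 nm compression at `ksS = 1`) |
| `dMin`, `dMax` | 100, 600 nm | myosin attachment annulus |
| `phiA`, `phiR` | 0.02 /s | rod addition / removal rates |
| `xi` | 1 | drag coefficient |
| `dt` | 0.02 s | Euler step |
| `vA`, `tS` | 1 nm/s, 300 s | focal-adhesion schedule |
| `Ttot` | 600 s | run duration |

**Stability.** The parameter validity enforces
$\Delta t < \xi / (2\,k_{max})$ against the stiffest single element, but a
chain of stiff springs can still have a Hessian eigenvalue up to about
$4k$; the run loop therefore also monitors total energy and aborts with an
error naming `dt` if it grows ten-fold above its initial value. At the
defaults, $\Delta t = 0.02$ sits a factor of five below the single-element
bound.

**Equilibration.** "No significant change" is made concrete as: maximum
per-step node displacement below `tol = 1e-3` nm. This is a declared
choice; at the default drag and stiffness it corresponds to residual
forces of order $10^{-1}$ of the detachment threshold divided by $10^3$.

**Degenerate geometry.** A spring edge whose endpoints coincide has no
defined direction; this raises an error instead of picking a random
direction, because it signals a modeling problem (cables at zero length
are fine: their force is zero).

## Scenarios

`buildScenario()` assembles the four canonical configurations studied:

* `pure_lattice` — the 20 x 10-node triangular lattice alone (about a
  3.4 x 1.4 µm patch), optionally with Gaussian node perturbation. The
  triangular lattice is the isotropic, space-tiling starting configuration;
  it also matches the erythrocyte meshwork.
* `lattice_plus_fa_cables` — the figure-style geometry in which the
  relaxed mesh is stretched horizontally through pure cables anchored at
  two fixed adhesions. The published schematic does not specify the cable
  wiring; here one adhesion sits 500 nm to the left and one to the right
  of the lattice, cabled to every boundary-column node. With detachment
  on, compressed edges fail preferentially near the free top and bottom
  rows.
* `lattice_plus_stress_fibers` — two contractile fibers (spring + cable
  chains, terminal edges built `faOffset` = 50 nm longer than rest to seed
  the polymerization-driven instability) fence the mesh above and below;
  each fiber connector couples to the nearest lattice node by a generic
  cable, a wiring choice the source figures leave open.
* `full_with_myosin` — the mesh-fiber coupling is instead only through 4
  stiff myosin linkers at the fiber extremes, plus 5 initial rods and
  stochastic turnover; focal adhesions move vertically toward each other
  for the first half of the run.

```{r scenario, fig.width = 7, fig.height = 4}
cfg <- list(
  scenario = "full_with_myosin", seed = 1,
  params = list(dt = 0.02, Ttot = 120),
  run = list(snapshotEvery = NA)
)
tr <- simulateScenario(cfg)
plot(finalNetwork(tr))
table(events(tr)$event)
```

## What the synthetic generators emulate — and what they do not

Every generator returns ground truth next to pixels, and draws all
randomness from the seeded stream, so each imaging operator can be
validated by round-trip. The defaults describe a realistic
expansion-microscopy acquisition: Gaussian PSF of sigma 100 nm at
acquisition scale, 4x expansion, Gaussian read noise at 2% of dynamic
range or Poisson shot noise at ~50 photons per unit intensity. One epitope
per spectrin edge midpoint mimics a C-terminal label.

They deliberately do **not** emulate: vectorial/asymmetric PSFs, gel
expansion distortion fields, labeling stochasticity and steric exclusion,
sample drift, or bleaching. Passing round-trip tests therefore shows the
operators are correct on well-behaved inputs at realistic noise, not that
they are robust to every artifact of real microscopy.

## Imaging operator choices

* **Cluster segmentation** keeps the top 5% intensity quantile
  (the P~0.95~ definition), despeckles (3x3 median) and smooths (3x3 mean)
  the *binary mask* — filtering after thresholding, matching the stated
  tool order — then measures connected components. The aspect ratio is the
  axis ratio of the second-moment ellipse (with the 1/12 single-pixel
  term), the particle-analysis definition. The threshold is a raw-intensity
  quantile by default rather than an 8-bit histogram threshold; the two
  passages describing bit depth disagree, and the quantile reading is the
  one that fixes the foreground fraction exactly.
* **Background subtraction** is a morphological top-hat with a 50 px disc
  behind the same interface as rolling-ball/sliding-paraboloid tools; only
  the removal of large-scale background matters downstream.
* **Intensity distribution** down-samples to 1 µm² pixels (block average),
  converts to 8-bit by per-image min-max scaling (the conversion mapping
  is otherwise unspecified), and compares normal vs log-normal fits by sum
  of squared differences between empirical bin frequencies and model bin
  probabilities.
* **Orientation** uses a derivative-of-Gaussian gradient at 0.5 px and a
  5 px Gaussian tensor window. The small derivative scale keeps fine
  structures contrasty and the gradient samples nearly independent, so an
  isotropic noise field reports mean coherency below 0.1 while perfect
  stripes report above 0.9. Angles are degrees in (-90, 90] from the +x
  axis toward +y (rows); the dominant direction comes from the summed
  tensor, and histograms can be aligned to a reference channel's dominant
  direction (the actin convention).
* **Local maxima** for NND and periodicity: a pixel is a peak when it
  attains the maximum of its 3x3 neighbourhood and exceeds 10% of the
  dynamic range — both knobs are exposed. Line profiles are additionally
  smoothed (Gaussian, 2 px) before 1D peak picking, which suppresses shot-
  noise bumps on band shoulders.
* **NND** optionally uses periodic (torus) distances, which removes the
  boundary bias when checking against the infinite-domain Poisson
  expectation $\mathbb{E}[NND] = 0.5/\sqrt{\lambda}$.
* **Inverted FRET** blurs both channels with sigma 1 µm, divides donor by
  FRET inside the mask, min-max normalizes to [0, 1] (NaN outside), and
  reports the coefficient of variation of the normalized values.
  Zero-denominator pixels are flagged and excluded; saturated acceptor
  pixels (top of the declared bit range) are excluded from the pixel
  table. A constant ratio cannot be normalized and is reported as uniform
  0 with a warning.
* **FRAP**: `I(t) = I0 + Imax (1 - e^{-kt})` by Levenberg–Marquardt with
  data-driven starts; half-time is ln(2)/k. The mobile fraction is the
  plateau `I0 + Imax` of the pre-bleach-normalized curve — reported
  without formula in the experimental convention, so this definition is
  declared here.
* **Cross-correlation** shifts along x only (the 1-D convention of the
  colocalization plugin), ±50 px by default; the curve peaks at +s when
  the second channel is the first translated by +s pixels.
* **Normalized cluster area** thresholds the whole stack at the quantile
  of the *initial* frames and uses the binary-mask mean as the area proxy,
  normalized to those frames.

## Problem sizes

The test suite and the acceptance script use the study-scale
configurations directly: the 20 x 10 lattice (541 spectrin edges) for
relaxation, 120 s constrained runs and 600 s full-myosin runs (30,000
Euler steps) across 5 seeds for the lifetime ordering, 512² images for
isotropy and distribution-fitting checks, and 100-curve FRAP recovery
studies. A full 600 s run takes roughly half a minute on one core.

## Known limitations

* The mesoscopic 2D network cannot speak to membrane mechanics, 3D
  barrel-like axonal organisation, or spectrin-repeat unfolding; it is a
  linear-element model by construction.
* Detached spectrin never re-attaches; the modeled transition is one-way
  within a run.
* The published parameter table for the original model was not available
  to this implementation; the defaults here are an independent calibration
  to the qualitative outcomes, so quantitative event counts (e.g. number
  of detachments) should be read as model-family behaviour, not as a
  reproduction of specific published values.
* The experimental microscopy numbers (cluster areas, NND values,
  autocorrelation coefficients, FRAP fractions) derive from unreleased
  data; the imaging operators are validated against synthetic ground
  truth instead.
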