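# spectrinmesh

Mechanical network modeling and quantitative imaging of the spectrin-based
cell cortex.

## The problem

The spectrin meshwork under the plasma membrane adopts different
organisations: the isotropic triangular lattice of erythrocytes, the
periodic ~180–190 nm arrays of axons, and — in fibroblasts — dense periodic
clusters fenced by actin stress fibers that coexist with a diffuse mesh.
This package is for researchers studying how actomyosin forces drive the
transition between these topologies. It provides (i) a simulator of the
spectrin cortex as a 2D spring/cable network with detachment and myosin
turnover, (ii) the quantitative microscopy operators used to characterise
spectrin organisation in images, and (iii) synthetic-data generators with
known ground truth that link the two, so the entire analysis chain can be
validated without experimental data.

## The model

Nodes are short actin filaments (free), focal adhesions (prescribed/fixed)
and stress-fiber connectors; edges carry mechanical elements:

- spring: `U_s = Σ k_s (d_j − d_0)² / 2` (spectrin tetramers, `d_0 = 180`
  nm; stress-fiber backbone)
- cable: `U_c = Σ k_c d_j² / 2`, always contractile (stress-fiber
  contractility, focal-adhesion cables, myosin linkers and rods)

Motion is overdamped, `∂r̄_l/∂t = F̄_l/ξ` with `F̄ = −∂U/∂r̄_l`, integrated by
explicit Euler. A compressed spectrin edge detaches when its expanding
force `k_s(d_0 − d)` exceeds `F_th`. Myosin binds triangle centroids
(forces split 1/3 per node), re-targets free triangles within
`(d_min, d_max)` when its host triangle breaks, and rods turn over with
per-step probabilities `Δt·φ_a`, `Δt·φ_r`. FRAP recovery uses the
one-phase association `I(t) = I0 + Imax(1 − e^(−kt))`; cluster
segmentation uses the top-5% intensity quantile (P_0.95); orientation uses
the structure tensor; tension mapping uses the inverted donor/FRET ratio.

## Worked example

Simulate the full scenario — triangular spectrin lattice fenced by two
contractile stress fibers, coupled through myosin linkers, with stochastic
myosin rods and focal adhesions pulled together for the first 300 s:

```r
library(spectrinmesh)

cfg <- list(scenario = "full_with_myosin", seed = 1, params = list(dt = 0.02))
tr <- simulateScenario(cfg)
tr
#> Trajectory: 11 snapshots over 600 s, 54 events
#>    myosin_add=4 myosin_rebind=2 myosin_remove=9 spectrin_detach=39

aggregate(lifetime ~ kind, myosinLifetimes(tr), median)
#>     kind lifetime
#> 1 linker   600.00
#> 2    rod    77.36

bundlesPerNode(finalNetwork(tr))$histogram
#>  0  1  2  3  4  5  6  7  8
#>  0  0  2 16 51 38 93  0  0

h <- edgeLengthHistogram(finalNetwork(tr))
sprintf("mean spectrin length %.1f nm (sd %.1f)", h$mean, h$sd)
#> "mean spectrin length 180.7 nm (sd 2.2)"
```

Reading the output: over 600 s, 39 compressed spectrin bundles detached
and the myosin rod population turned over (median rod lifetime 77 s) while
the stress-fiber linkers persisted for the whole run (lifetime 600 s,
censored). The bundles-per-node histogram has shifted away from the intact
lattice coordination of 6 toward 4–5 — the signature of the transition
toward the sparser, periodic-like organisation — while the surviving edges
sit at the 180 nm resting length (mean 180.7 nm). `plot(finalNetwork(tr))`
draws the final network.

A YAML config with the same content can be run from the shell through the
thin CLI at `inst/cli/spectrinmesh.R` (`simulate`, `generate`, `analyze`
subcommands), producing a run directory with `events.csv`, network
snapshots (JSON) and observable tables; identical config + seed gives
byte-identical outputs.

The imaging side works the same way on images; for example, recovering
periodicity from a synthetic expanded-microscopy array:

```r
set.seed(1)
g <- genPeriodicArray(200, 10, sceneSpec(fov = 10, pixelSize = 0.02,
  psfSigma = 100, noise = "poisson", expansion = 4))
lp <- lineScanPeriodicity(g$image, rbind(c(0.3, 5), c(9.7, 5)),
  expansionFactor = 4)
c(real = lp$meanSpacingReal, extrapolated = lp$meanSpacingExtrapolated)
#>         real extrapolated
#>          800          200
```

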