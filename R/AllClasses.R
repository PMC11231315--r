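## S4 containers for the network model and the imaging operators.

NODE_KINDS <- c("short_actin", "focal_adhesion", "sf_connector")
EDGE_KINDS <- c("spectrin", "stress_fiber", "cable", "myosin_linker", "myosin_rod")
KINEMATICS <- c("free", "prescribed", "fixed")
EVENT_KINDS <- c("spectrin_detach", "myosin_add", "myosin_remove", "myosin_rebind")

#' Mechanical parameters of the spectrin network model
#'
#' Holds every mechanical constant, rate and schedule of the spring/cable
#' network. Units are nanometres and seconds throughout; forces are expressed
#' in multiples of a reference stiffness times nanometres, with the spectrin
#' spring constant `ksS` acting as the reference scale.
#'
#' @slot ksS spectrin spring constant (force/nm).
#' @slot d0S spectrin resting length (nm), 180 by default (tetramer contour
#'   length).
#' @slot kc generic cable constant (force/nm) used for focal-adhesion cables
#'   and mesh-to-fiber couplings.
#' @slot ksF,kcF stress-fiber spring and cable constants.
#' @slot d0F stress-fiber resting length (nm); `NA` means "computed from the
#'   as-built relaxed fiber geometry".
#' @slot kcL,kcM myosin linker and myosin rod cable constants (linkers are
#'   stiffer than rods).
#' @slot Fth detachment force threshold: a spectrin edge whose expanding
#'   (compressive) spring force exceeds `Fth` is removed.
#' @slot dMin,dMax admissible myosin attachment length bounds (nm).
#' @slot phiA,phiR myosin rod addition and removal rates (1/s).
#' @slot xi drag coefficient (force*s/nm).
#' @slot dt integration time step (s); must satisfy the explicit-Euler
#'   stability bound `dt < xi / (2 * max spring constant)`.
#' @slot vA focal-adhesion prescribed speed (nm/s).
#' @slot tS schedule switch time (s): prescribed focal adhesions move until
#'   `tS` and are fixed afterwards.
#' @slot Ttot total simulated duration (s).
#' @slot seed RNG seed for every stochastic element of a run.
#' @seealso [modelParams()] for the user-facing constructor with defaults.
#' @exportClass ModelParams
setClass("ModelParams",
  representation(
    ksS = "numeric", d0S = "numeric", kc = "numeric",
    ksF = "numeric", kcF = "numeric", d0F = "numeric",
    kcL = "numeric", kcM = "numeric",
    Fth = "numeric", dMin = "numeric", dMax = "numeric",
    phiA = "numeric", phiR = "numeric",
    xi = "numeric", dt = "numeric",
    vA = "numeric", tS = "numeric", Ttot = "numeric",
    seed = "integer"
  )
)

setValidity("ModelParams", function(object) {
  msg <- character()
  num <- c(
    ksS = object@ksS, d0S = object@d0S, kc = object@kc, ksF = object@ksF,
    kcF = object@kcF, kcL = object@kcL, kcM = object@kcM, Fth = object@Fth,
    dMin = object@dMin, dMax = object@dMax, phiA = object@phiA,
    phiR = object@phiR, xi = object@xi, dt = object@dt, vA = object@vA,
    tS = object@tS, Ttot = object@Ttot
  )
  if (any(!is.finite(num)) && !is.na(object@d0F)) {
    msg <- c(msg, "all parameters must be finite")
  }
  if (any(num < 0, na.rm = TRUE)) {
    msg <- c(msg, sprintf(
      "all constants must be >= 0 (offending: %s)",
      paste(names(num)[which(num < 0)], collapse = ", ")
    ))
  }
  if (!is.na(object@dMin) && object@dMin >= object@dMax) {
    msg <- c(msg, "dMin must be < dMax")
  }
  if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
  kmax <- max(object@ksS, object@ksF, if (is.na(object@d0F)) 0 else 0)
  if (object@dt >= object@xi / (2 * kmax)) {
    msg <- c(msg, sprintf(
      "dt = %g violates the explicit-Euler stability bound dt < xi/(2*kmax) = %g",
      object@dt, object@xi / (2 * kmax)
    ))
  }
  if (object@tS > object@Ttot) msg <- c(msg, "tS must be <= Ttot")
  if (object@dt * max(object@phiA, object@phiR) > 1) {
    msg <- c(msg, "dt*phi exceeds 1: per-step myosin event probability overflows")
  }
  if (length(msg)) msg else TRUE
})

#' Cytoskeletal network state
#'
#' The simulator's central object: a planar graph of mechanical elements.
#' Nodes are short actin filaments (free), focal adhesions (prescribed or
#' fixed) and stress-fiber connectors; edges are spectrin tetramers (spring
#' only), stress-fiber segments (spring + cable), generic cables, and myosin
#' linkers/rods (cable only) whose ends may attach to the centroid of a
#' spectrin triangle. The triangle table indexes every triangle of the
#' initial spectrin lattice; a triangle is *intact* while its three spectrin
#' edges remain attached and *free* when additionally no myosin is bound to
#' it.
#'
#' @slot nodes data.frame with columns `id`, `kind`, `x`, `y`, `kinematics`,
#'   `vy` (prescribed vertical velocity, nm/s).
#' @slot edges data.frame with columns `id`, `kind`, `n1`, `n2` (node ids, NA
#'   when the endpoint is a triangle attachment), `t1`, `t2` (triangle ids or
#'   NA), `ks`, `kc`, `d0`, `state` ("attached"/"removed"), `tAttach`,
#'   `tRemove`.
#' @slot triangles data.frame with columns `id`, `a`, `b`, `c` (node ids) and
#'   `e1`, `e2`, `e3` (the spectrin edge ids forming the sides).
#' @slot params a [ModelParams-class] object.
#' @slot time current simulation time (s).
#' @exportClass Network
setClass("Network",
  representation(
    nodes = "data.frame",
    edges = "data.frame",
    triangles = "data.frame",
    params = "ModelParams",
    time = "numeric"
  )
)

setValidity("Network", function(object) {
  nd <- object@nodes
  ed <- object@edges
  tr <- object@triangles
  msg <- character()
  need_n <- c("id", "kind", "x", "y", "kinematics", "vy")
  need_e <- c(
    "id", "kind", "n1", "n2", "t1", "t2", "ks", "kc", "d0",
    "state", "tAttach", "tRemove"
  )
  if (!all(need_n %in% names(nd))) {
    return(paste("nodes must have columns:", paste(need_n, collapse = ", ")))
  }
  if (!all(need_e %in% names(ed))) {
    return(paste("edges must have columns:", paste(need_e, collapse = ", ")))
  }
  if (nrow(nd) && !all(nd$id == seq_len(nrow(nd)))) {
    msg <- c(msg, "node ids must be contiguous 1..N")
  }
  if (nrow(ed) && !all(ed$id == seq_len(nrow(ed)))) {
    msg <- c(msg, "edge ids must be contiguous 1..E")
  }
  if (!all(nd$kind %in% NODE_KINDS)) msg <- c(msg, "unknown node kind")
  if (!all(ed$kind %in% EDGE_KINDS)) msg <- c(msg, "unknown edge kind")
  if (!all(nd$kinematics %in% KINEMATICS)) msg <- c(msg, "unknown kinematics")
  if (any(!is.finite(nd$x)) || any(!is.finite(nd$y))) {
    msg <- c(msg, "node positions must be finite")
  }
  fa <- nd$kind == "focal_adhesion"
  if (any(nd$kinematics[fa] == "free")) {
    msg <- c(msg, "focal_adhesion nodes must be prescribed or fixed, never free")
  }
  sp <- ed$kind == "spectrin"
  if (any(sp)) {
    ok <- nd$kind[ed$n1[sp]] == "short_actin" & nd$kind[ed$n2[sp]] == "short_actin"
    if (any(!ok)) msg <- c(msg, "spectrin edges must connect two short_actin nodes")
    if (any(ed$kc[sp] != 0)) msg <- c(msg, "spectrin edges carry a spring element only")
  }
  myo <- ed$kind %in% c("myosin_linker", "myosin_rod")
  if (any(ed$ks[myo] != 0)) msg <- c(msg, "myosin edges carry a cable element only")
  if (any(ed$ks[ed$kind == "cable"] != 0)) {
    msg <- c(msg, "cable edges carry a cable element only")
  }
  ref <- c(ed$n1, ed$n2)
  if (any(!is.na(ref) & (ref < 1 | ref > nrow(nd)))) {
    msg <- c(msg, "dangling edge endpoint (node id out of range)")
  }
  reft <- c(ed$t1, ed$t2)
  if (any(!is.na(reft) & (reft < 1 | reft > max(0, nrow(tr))))) {
    msg <- c(msg, "dangling triangle attachment")
  }
  both_na1 <- is.na(ed$n1) & is.na(ed$t1)
  both_na2 <- is.na(ed$n2) & is.na(ed$t2)
  if (any(both_na1 | both_na2)) msg <- c(msg, "edge endpoint missing")
  if (length(msg)) msg else TRUE
})

#' Simulation trajectory
#'
#' Time-ordered snapshots of a [Network-class] plus the event log produced by
#' detachment, myosin rebinding and stochastic myosin turnover.
#'
#' @slot snapshots list of [Network-class] objects.
#' @slot snapshotTimes numeric vector of snapshot times (s).
#' @slot events data.frame with columns `time`, `event` (one of
#'   spectrin_detach, myosin_add, myosin_remove, myosin_rebind), `edge`,
#'   `x`, `y` (event location, nm).
#' @slot final the final [Network-class].
#' @slot config the run configuration echoed as a list.
#' @exportClass Trajectory
setClass("Trajectory",
  representation(
    snapshots = "list",
    snapshotTimes = "numeric",
    events = "data.frame",
    final = "Network",
    config = "list"
  )
)

setValidity("Trajectory", function(object) {
  ev <- object@events
  msg <- character()
  if (nrow(ev) && is.unsorted(ev$time)) msg <- c(msg, "event times must be non-decreasing")
  if (nrow(ev) && !all(ev$event %in% EVENT_KINDS)) msg <- c(msg, "unknown event kind")
  if (length(object@snapshots) != length(object@snapshotTimes)) {
    msg <- c(msg, "snapshots and snapshotTimes differ in length")
  }
  if (length(msg)) msg else TRUE
})

#' 2D microscopy image carrier
#'
#' A single-channel image with its physical pixel size, an optional bit-depth
#' tag (used to decide the saturation level), and an optional binary cell
#' mask of the same shape.
#'
#' @slot data numeric matrix of intensities (rows = y, columns = x).
#' @slot pixelSize physical pixel size in micrometres per pixel.
#' @slot bitDepth nominal bit depth (8 or 16) or NA for floating point data.
#' @slot mask logical matrix (same shape) or a 0-row placeholder when absent.
#' @exportClass CortexImage
setClass("CortexImage",
  representation(
    data = "matrix",
    pixelSize = "numeric",
    bitDepth = "numeric",
    mask = "matrix"
  ),
  prototype(
    pixelSize = 0.1, bitDepth = NA_real_,
    mask = matrix(logical(0), 0, 0)
  )
)

setValidity("CortexImage", function(object) {
  msg <- character()
  if (length(object@pixelSize) != 1 || !is.finite(object@pixelSize) ||
    object@pixelSize <= 0) {
    msg <- c(msg, "pixelSize must be a single positive number")
  }
  if (nrow(object@mask) &&
    !identical(dim(object@mask), dim(object@data))) {
    msg <- c(msg, "mask must have the same shape as the image")
  }
  if (length(msg)) msg else TRUE
})

#' Per-pixel orientation and coherency from the structure tensor
#'
#' @slot orientation matrix of local orientations in degrees, in (-90, 90];
#'   NA where the orientation is undefined (zero gradient energy).
#' @slot coherency matrix of coherency values in 0..1.
#' @slot dominantDirection scalar dominant direction of the whole image
#'   (degrees), from the summed structure tensor.
#' @exportClass OrientationMap
setClass("OrientationMap",
  representation(
    orientation = "matrix",
    coherency = "matrix",
    dominantDirection = "numeric"
  )
)

setValidity("OrientationMap", function(object) {
  co <- object@coherency
  if (any(co < -1e-9 | co > 1 + 1e-9, na.rm = TRUE)) {
    return("coherency must lie in [0, 1]")
  }
  TRUE
})

#' One-phase-association FRAP fit
#'
#' The recovery model is `I(t) = I0 + Imax * (1 - exp(-k t))` with half-time
#' `ln(2)/k`. Mobile fraction is the plateau `I0 + Imax` of the curve
#' normalized to the pre-bleach intensity.
#'
#' @slot times,intensities the fitted data.
#' @slot I0,Imax,k fitted parameters (k in 1/s).
#' @slot halfTime `log(2)/k` (s).
#' @slot mobileFraction plateau `I0 + Imax`.
#' @slot converged logical.
#' @exportClass FrapFit
setClass("FrapFit",
  representation(
    times = "numeric", intensities = "numeric",
    I0 = "numeric", Imax = "numeric", k = "numeric",
    halfTime = "numeric", mobileFraction = "numeric",
    converged = "logical"
  )
)

#' Synthetic-acquisition scene specification
#'
#' Describes how a ground-truth scene is rendered into pixels: field of view,
#' pixel size, Gaussian PSF width, noise model and the expansion-microscopy
#' scale factor.
#'
#' @slot fov field of view (micrometres, square).
#' @slot pixelSize micrometres per pixel.
#' @slot psfSigma Gaussian PSF sigma in nanometres at acquisition scale.
#' @slot noise one of "none", "gaussian", "poisson".
#' @slot noiseSigma Gaussian noise sigma as a fraction of dynamic range.
#' @slot poissonScale expected photon count at unit intensity for Poisson
#'   noise.
#' @slot expansion expansion factor (>= 1); physical distances are multiplied
#'   by it before rendering.
#' @slot seed RNG seed.
#' @exportClass SceneSpec
setClass("SceneSpec",
  representation(
    fov = "numeric", pixelSize = "numeric", psfSigma = "numeric",
    noise = "character", noiseSigma = "numeric", poissonScale = "numeric",
    expansion = "numeric", seed = "integer"
  )
)

setValidity("SceneSpec", function(object) {
  msg <- character()
  if (object@psfSigma < 0) msg <- c(msg, "psfSigma must be >= 0")
  if (object@expansion < 1) msg <- c(msg, "expansion factor must be >= 1")
  if (!object@noise %in% c("none", "gaussian", "poisson")) {
    msg <- c(msg, "noise must be none, gaussian or poisson")
  }
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (length(msg)) msg else TRUE
})
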