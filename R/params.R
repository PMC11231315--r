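#' Construct the mechanical parameter set
#'
#' Builds a validated [ModelParams-class]. Units are nm and s; force is in
#' units of the reference stiffness times nm, with the spectrin spring
#' constant `ksS = 1` as the reference. The spectrin resting length of 180 nm
#' is the tetramer contour length; every other default is a declared modeling
#' assumption (see the methods vignette), chosen once so that the four
#' canonical scenarios reproduce the qualitative network behaviours: the
#' stress-fiber cable instability, compression-driven spectrin detachment
#' near the constrained boundaries, and sparse myosin turnover.
#'
#' @param ksS spectrin spring constant (reference stiffness). Default 1.
#' @param d0S spectrin resting length (nm). Default 180.
#' @param kc generic cable constant for focal-adhesion cables and
#'   mesh-to-fiber couplings. Default 0.05.
#' @param ksF,kcF stress-fiber spring and cable constants. Defaults 5, 0.05.
#' @param d0F stress-fiber resting length; `NA` (default) means computed as
#'   the as-built relaxed segment length when fibers are added.
#' @param kcL,kcM myosin linker / rod cable constants. Linkers are stiffer
#'   than rods. Defaults 0.1 and 0.08.
#' @param Fth detachment force threshold. Default 10 (with `ksS = 1` a
#'   spectrin edge detaches when compressed more than 10 nm below rest).
#' @param dMin,dMax myosin attachment length bounds (nm). Defaults 100, 600.
#' @param phiA,phiR myosin rod addition / removal rates (1/s). Defaults 0.02.
#' @param xi drag coefficient (force*s/nm). Default 1.
#' @param dt time step (s). Default 0.02, comfortably inside the stability
#'   bound `xi / (2 * ksF) = 0.1`.
#' @param vA focal-adhesion speed (nm/s). Default 1.
#' @param tS schedule switch time (s). Default 300 (first half of a 600 s
#'   run).
#' @param Ttot total duration (s). Default 600.
#' @param seed RNG seed. Default 1L.
#' @return a [ModelParams-class] object.
#' @examples
#' p <- modelParams()
#' p
#' @export
modelParams <- function(ksS = 1, d0S = 180, kc = 0.05,
                        ksF = 5, kcF = 0.05, d0F = NA_real_,
                        kcL = 0.1, kcM = 0.08,
                        Fth = 10, dMin = 100, dMax = 600,
                        phiA = 0.02, phiR = 0.02,
                        xi = 1, dt = 0.02,
                        vA = 1, tS = 300, Ttot = 600, seed = 1L) {
  new("ModelParams",
    ksS = ksS, d0S = d0S, kc = kc, ksF = ksF, kcF = kcF, d0F = d0F,
    kcL = kcL, kcM = kcM, Fth = Fth, dMin = dMin, dMax = dMax,
    phiA = phiA, phiR = phiR, xi = xi, dt = dt, vA = vA, tS = tS,
    Ttot = Ttot, seed = as.integer(seed)
  )
}

paramsToList <- function(p) {
  sl <- slotNames("ModelParams")
  stats::setNames(lapply(sl, function(s) slot(p, s)), sl)
}

paramsFromList <- function(x) {
  defaults <- paramsToList(modelParams())
  unknown <- setdiff(names(x), names(defaults))
  if (length(unknown)) {
    stop("unknown model parameter(s): ", paste(unknown, collapse = ", "))
  }
  args <- utils::modifyList(defaults, x)
  ## a shortened run keeps the schedule switch inside it unless set explicitly
  if (is.null(x$tS)) args$tS <- min(args$tS, args$Ttot)
  args$seed <- as.integer(args$seed)
  do.call(new, c(list("ModelParams"), args))
}

setMethod("show", "ModelParams", function(object) {
  cat("ModelParams (units nm, s; reference stiffness ksS)\n")
  cat(sprintf(
    "  spectrin: ksS=%g  d0S=%g nm   threshold Fth=%g\n",
    object@ksS, object@d0S, object@Fth
  ))
  cat(sprintf(
    "  stress fiber: ksF=%g kcF=%g d0F=%s   cables kc=%g\n",
    object@ksF, object@kcF,
    if (is.na(object@d0F)) "(as built)" else format(object@d0F), object@kc
  ))
  cat(sprintf(
    "  myosin: kcL=%g kcM=%g  attach (%g, %g) nm  phiA=%g phiR=%g /s\n",
    object@kcL, object@kcM, object@dMin, object@dMax,
    object@phiA, object@phiR
  ))
  cat(sprintf(
    "  dynamics: xi=%g dt=%g s  vA=%g nm/s  tS=%g s  T=%g s  seed=%d\n",
    object@xi, object@dt, object@vA, object@tS, object@Ttot, object@seed
  ))
})
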