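#' Build one of the canonical simulation scenarios
#'
#' Assembles the initial network for the four studied configurations:
#' \describe{
#'   \item{`pure_lattice`}{the triangular spectrin lattice alone, optionally
#'     with every node displaced by isotropic Gaussian noise of
#'     `perturbSigma` nm (consumes the current RNG stream).}
#'   \item{`lattice_plus_fa_cables`}{the lattice stretched horizontally by
#'     cables anchored at two fixed focal adhesions.}
#'   \item{`lattice_plus_stress_fibers`}{the lattice fenced by two
#'     contractile stress fibers (spring + cable chains ending at focal
#'     adhesions, terminal edges built `faOffset` too long), coupled to the
#'     mesh by cables; adhesions optionally follow the vertical schedule.}
#'   \item{`full_with_myosin`}{as above but the mesh-fiber coupling is by
#'     stiff myosin linkers, plus `nRodsInit` myosin rods placed at random
#'     admissible locations inside the mesh (turnover is then handled by
#'     [runSimulation()]).}
#' }
#'
#' @param scenario scenario name (see above).
#' @param params a [ModelParams-class].
#' @param nRows,nCols lattice dimensions (default 10 x 20 nodes, about a
#'   3.4 x 1.4 micrometre patch at 180 nm spacing).
#' @param nSegments stress-fiber segments per fiber.
#' @param faOffset terminal stress-fiber edge extra length (nm).
#' @param standoff focal-adhesion cable standoff (nm).
#' @param sfOffset fiber clearance above/below the lattice (nm); NULL for
#'   one row height.
#' @param prescribedFA focal adhesions move vertically toward each other at
#'   `vA` until `tS` (stress-fiber scenarios only).
#' @param nRodsInit initial myosin rod count (full scenario).
#' @param perturbSigma initial isotropic node displacement sd (nm).
#' @return a [Network-class] ready for [runSimulation()].
#' @export
buildScenario <- function(scenario = c(
                            "pure_lattice", "lattice_plus_fa_cables",
                            "lattice_plus_stress_fibers", "full_with_myosin"
                          ),
                          params = modelParams(), nRows = 10, nCols = 20,
                          nSegments = 8, faOffset = 50, standoff = 500,
                          sfOffset = NULL, prescribedFA = NULL,
                          nRodsInit = 5, perturbSigma = 0) {
  scenario <- match.arg(scenario)
  net <- buildTriangularLattice(nRows, nCols, params)
  if (perturbSigma > 0) {
    nd <- net@nodes
    nd$x <- nd$x + stats::rnorm(nrow(nd), 0, perturbSigma)
    nd$y <- nd$y + stats::rnorm(nrow(nd), 0, perturbSigma)
    net@nodes <- nd
  }
  if (scenario == "pure_lattice") {
    return(net)
  }
  if (scenario == "lattice_plus_fa_cables") {
    return(addFocalAdhesionCables(net, standoff = standoff))
  }
  if (is.null(prescribedFA)) {
    prescribedFA <- scenario == "full_with_myosin"
  }
  net <- addStressFibers(net,
    nSegments = nSegments, faOffset = faOffset,
    sfOffset = sfOffset, prescribed = prescribedFA
  )
  if (scenario == "lattice_plus_stress_fibers") {
    return(addFiberCouplingCables(net))
  }
  ## full_with_myosin
  net <- addMyosinLinkers(net)
  for (i in seq_len(nRodsInit)) {
    res <- addMyosinRod(net)
    net <- res$network
  }
  net
}
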