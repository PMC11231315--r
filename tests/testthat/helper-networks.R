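# Shared fixtures, built in code.

# A small heterogeneous network containing every element type (spectrin
# springs, stress-fiber spring+cable chains, focal-adhesion cables, myosin
# linker and rod with triangle attachments), with randomly perturbed node
# positions so that no edge is at rest.
randomTestNetwork <- function(seed = 1, perturb = 25) {
  set.seed(seed)
  p <- modelParams()
  net <- buildTriangularLattice(3, 5, p)
  net <- addStressFibers(net, nSegments = 4, faOffset = 40)
  net <- addMyosinLinkers(net)
  res <- addMyosinRod(net)
  net <- res$network
  nd <- net@nodes
  nd$x <- nd$x + rnorm(nrow(nd), 0, perturb)
  nd$y <- nd$y + rnorm(nrow(nd), 0, perturb)
  net@nodes <- nd
  net
}

# Central finite-difference gradient of totalEnergy: the independent force
# oracle (netForce must equal -dU/dr analytically).
finiteDifferenceForces <- function(net, h = 1e-3) {
  nd <- net@nodes
  F <- matrix(0, nrow(nd), 2)
  for (i in seq_len(nrow(nd))) {
    for (dim in 1:2) {
      col <- c("x", "y")[dim]
      plus <- net
      plus@nodes[[col]][i] <- plus@nodes[[col]][i] + h
      minus <- net
      minus@nodes[[col]][i] <- minus@nodes[[col]][i] - h
      F[i, dim] <- -(totalEnergy(plus) - totalEnergy(minus)) / (2 * h)
    }
  }
  F
}

# Minimal two-node spring system for closed-form relaxation checks.
twoNodeSpring <- function(d_i, ks = 1, d0 = 180, xi = 1, dt = NULL) {
  if (is.null(dt)) dt <- xi / (100 * ks)
  p <- modelParams(ksS = ks, d0S = d0, xi = xi, dt = dt)
  nd <- data.frame(
    id = 1:2, kind = "short_actin", x = c(0, d_i), y = 0,
    kinematics = "free", vy = 0, stringsAsFactors = FALSE
  )
  ed <- data.frame(
    id = 1L, kind = "spectrin", n1 = 1L, n2 = 2L,
    t1 = NA_integer_, t2 = NA_integer_, ks = ks, kc = 0, d0 = d0,
    state = "attached", tAttach = 0, tRemove = NA_real_,
    stringsAsFactors = FALSE
  )
  tr <- data.frame(
    id = integer(), a = integer(), b = integer(), c = integer(),
    e1 = integer(), e2 = integer(), e3 = integer()
  )
  new("Network", nodes = nd, edges = ed, triangles = tr, params = p, time = 0)
}

# smallest angular distance between two orientations (degrees, mod 180)
angDiff <- function(a, b) {
  d <- abs(a - b) %% 180
  min(d, 180 - d)
}
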