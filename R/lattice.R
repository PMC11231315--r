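## mesh construction: triangular spectrin lattice, stress fibers,
## focal-adhesion cables, myosin linkers and rods.

emptyNodes <- function() {
  data.frame(
    id = integer(), kind = character(), x = numeric(), y = numeric(),
    kinematics = character(), vy = numeric(), stringsAsFactors = FALSE
  )
}

emptyEdges <- function() {
  data.frame(
    id = integer(), kind = character(), n1 = integer(), n2 = integer(),
    t1 = integer(), t2 = integer(), ks = numeric(), kc = numeric(),
    d0 = numeric(), state = character(), tAttach = numeric(),
    tRemove = numeric(), stringsAsFactors = FALSE
  )
}

emptyEvents <- function() {
  data.frame(
    time = numeric(), event = character(), edge = integer(),
    x = numeric(), y = numeric(), stringsAsFactors = FALSE
  )
}

#' Build the triangular spectrin lattice
#'
#' Constructs `nRows x nCols` short-actin nodes on an equilateral triangular
#' grid with spacing `d0S` and connects nearest neighbours by spectrin spring
#' edges at their resting length. The triangle table enumerating every
#' elementary lattice triangle (the attachment sites for myosin) is built at
#' the same time. At rest the lattice is force free.
#'
#' @param nRows,nCols lattice dimensions (both >= 2).
#' @param params a [ModelParams-class]; `d0S` sets the spacing.
#' @return a [Network-class].
#' @examples
#' net <- buildTriangularLattice(4, 5, modelParams())
#' net
#' @export
buildTriangularLattice <- function(nRows, nCols, params = modelParams()) {
  if (nRows < 2 || nCols < 2) {
    stop("configuration error: nRows and nCols must both be >= 2")
  }
  d0 <- params@d0S
  idx <- function(i, j) (i - 1L) * nCols + j
  i <- rep(seq_len(nRows), each = nCols)
  j <- rep(seq_len(nCols), nRows)
  x <- (j - 1) * d0 + ((i - 1) %% 2) * d0 / 2
  y <- (i - 1) * d0 * sqrt(3) / 2
  nd <- data.frame(
    id = seq_len(nRows * nCols), kind = "short_actin", x = x, y = y,
    kinematics = "free", vy = 0, stringsAsFactors = FALSE
  )
  from <- integer()
  to <- integer()
  for (ii in seq_len(nRows)) {
    ## in-row edges
    if (nCols >= 2) {
      from <- c(from, idx(ii, seq_len(nCols - 1)))
      to <- c(to, idx(ii, seq_len(nCols - 1) + 1L))
    }
    ## cross edges to the row above; odd rows sit at zero x-offset
    if (ii < nRows) {
      jj <- seq_len(nCols)
      if (ii %% 2 == 1) {
        j2a <- jj
        j2b <- jj - 1L
      } else {
        j2a <- jj
        j2b <- jj + 1L
      }
      ok_a <- j2a >= 1 & j2a <= nCols
      ok_b <- j2b >= 1 & j2b <= nCols
      from <- c(from, idx(ii, jj[ok_a]), idx(ii, jj[ok_b]))
      to <- c(to, idx(ii + 1L, j2a[ok_a]), idx(ii + 1L, j2b[ok_b]))
    }
  }
  sw <- from > to
  tmp <- from[sw]
  from[sw] <- to[sw]
  to[sw] <- tmp
  stopifnot(!anyDuplicated(paste(from, to)))
  ed <- data.frame(
    id = seq_along(from), kind = "spectrin", n1 = from, n2 = to,
    t1 = NA_integer_, t2 = NA_integer_, ks = params@ksS, kc = 0, d0 = d0,
    state = "attached", tAttach = 0, tRemove = NA_real_,
    stringsAsFactors = FALSE
  )
  tr <- enumerateTriangles(nd, ed)
  new("Network",
    nodes = nd, edges = ed, triangles = tr, params = params, time = 0
  )
}

## All mutually connected node triples among the spectrin edges, with the
## edge ids of their three sides.
enumerateTriangles <- function(nd, ed) {
  n <- nrow(nd)
  adj <- vector("list", n)
  for (k in seq_len(nrow(ed))) {
    a <- ed$n1[k]
    b <- ed$n2[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  ekey <- stats::setNames(ed$id, paste(ed$n1, ed$n2))
  lookup <- function(a, b) ekey[[paste(min(a, b), max(a, b))]]
  A <- integer()
  B <- integer()
  C <- integer()
  for (k in seq_len(nrow(ed))) {
    a <- ed$n1[k]
    b <- ed$n2[k]
    common <- intersect(adj[[a]], adj[[b]])
    common <- common[common > b] # a < b < c: count each triangle once
    for (cc in common) {
      A <- c(A, a)
      B <- c(B, b)
      C <- c(C, cc)
    }
  }
  if (!length(A)) {
    return(data.frame(
      id = integer(), a = integer(), b = integer(), c = integer(),
      e1 = integer(), e2 = integer(), e3 = integer()
    ))
  }
  data.frame(
    id = seq_along(A), a = A, b = B, c = C,
    e1 = vapply(seq_along(A), function(q) lookup(A[q], B[q]), integer(1)),
    e2 = vapply(seq_along(A), function(q) lookup(A[q], C[q]), integer(1)),
    e3 = vapply(seq_along(A), function(q) lookup(B[q], C[q]), integer(1))
  )
}

#' Triangle centroids and availability
#'
#' `triangleCentroids` returns the attachment point of every lattice
#' triangle: the arithmetic mean of its three node positions. A triangle is
#' *intact* while its three spectrin sides are attached, and *free* when it
#' is intact and carries no myosin.
#'
#' @param net a [Network-class].
#' @return `triangleCentroids`: a matrix with columns x, y (one row per
#'   triangle); `intactTriangles` / `freeTriangles`: logical vectors indexed
#'   by triangle id.
#' @export
triangleCentroids <- function(net) {
  tr <- net@triangles
  nd <- net@nodes
  cbind(
    x = (nd$x[tr$a] + nd$x[tr$b] + nd$x[tr$c]) / 3,
    y = (nd$y[tr$a] + nd$y[tr$b] + nd$y[tr$c]) / 3
  )
}

#' @rdname triangleCentroids
#' @export
intactTriangles <- function(net) {
  tr <- net@triangles
  att <- net@edges$state == "attached"
  att[tr$e1] & att[tr$e2] & att[tr$e3]
}

#' @rdname triangleCentroids
#' @export
freeTriangles <- function(net) {
  occ <- rep(FALSE, nrow(net@triangles))
  ed <- net@edges
  myo <- ed$kind %in% c("myosin_linker", "myosin_rod") & ed$state == "attached"
  occ[stats::na.omit(c(ed$t1[myo], ed$t2[myo]))] <- TRUE
  intactTriangles(net) & !occ
}

## endpoint positions of every edge (triangle ends evaluated at centroids)
edgeEndpointPositions <- function(net) {
  ed <- net@edges
  nd <- net@nodes
  cen <- triangleCentroids(net)
  p1 <- cbind(
    ifelse(is.na(ed$n1), cen[ed$t1, 1], nd$x[ed$n1]),
    ifelse(is.na(ed$n1), cen[ed$t1, 2], nd$y[ed$n1])
  )
  p2 <- cbind(
    ifelse(is.na(ed$n2), cen[ed$t2, 1], nd$x[ed$n2]),
    ifelse(is.na(ed$n2), cen[ed$t2, 2], nd$y[ed$n2])
  )
  list(p1 = p1, p2 = p2)
}

#' Current edge lengths
#'
#' Euclidean length of every edge; ends bound to a spectrin triangle are
#' evaluated at the triangle centroid.
#'
#' @param net a [Network-class].
#' @return numeric vector, one entry per edge (attached or not).
#' @export
edgeLengthsOf <- function(net) {
  ep <- edgeEndpointPositions(net)
  sqrt(rowSums((ep$p1 - ep$p2)^2))
}

#' Add contractile stress fibers above and below the lattice
#'
#' One horizontal fiber chain is placed `sfOffset` above the lattice and one
#' below. Internal nodes are `sf_connector`s; terminal nodes are focal
#' adhesions. Each fiber edge carries a spring (`ksF`) and a cable (`kcF`)
#' element with resting length equal to the as-built relaxed segment length;
#' the edge adjacent to each focal adhesion is built `faOffset` longer than
#' that resting length, seeding the contraction instability that mimics
#' actin polymerization forces at the adhesion.
#'
#' @param net a [Network-class] with the lattice built.
#' @param nSegments number of segments per fiber (>= 2).
#' @param faOffset extra length (nm) of the terminal, focal-adhesion-adjacent
#'   edges.
#' @param sfOffset vertical clearance (nm) between the fiber and the lattice
#'   bounding box; defaults to one lattice row height. Must be positive.
#' @param prescribed if TRUE the focal adhesions are given prescribed
#'   vertical kinematics (speed `vA` toward each other until `tS`);
#'   otherwise they are fixed anchors.
#' @return the augmented [Network-class] (with `d0F` filled in if it was NA).
#' @export
addStressFibers <- function(net, nSegments = 8, faOffset = 50,
                            sfOffset = NULL, prescribed = FALSE) {
  if (nSegments < 2) stop("configuration error: nSegments must be >= 2")
  nSegments <- as.integer(nSegments)
  p <- net@params
  if (is.null(sfOffset)) sfOffset <- p@d0S * sqrt(3) / 2
  if (sfOffset <= 0) {
    stop("geometry error: stress fiber would overlap the lattice bounding box")
  }
  sa <- net@nodes$kind == "short_actin"
  xmin <- min(net@nodes$x[sa])
  xmax <- max(net@nodes$x[sa])
  ymin <- min(net@nodes$y[sa])
  ymax <- max(net@nodes$y[sa])
  nConn <- nSegments - 1L
  if (nConn == 1L) {
    cx <- (xmin + xmax) / 2
    L <- (xmax - xmin) / 2
  } else {
    cx <- seq(xmin, xmax, length.out = nConn)
    L <- (xmax - xmin) / (nConn - 1L)
  }
  if (is.na(p@d0F)) {
    p@d0F <- L
    net@params <- p
  }
  addFiber <- function(net, yf, vy) {
    nd <- net@nodes
    ed <- net@edges
    n0 <- nrow(nd)
    conn <- data.frame(
      id = n0 + seq_len(nConn), kind = "sf_connector", x = cx, y = yf,
      kinematics = "free", vy = 0, stringsAsFactors = FALSE
    )
    faL <- data.frame(
      id = n0 + nConn + 1L, kind = "focal_adhesion",
      x = min(cx) - (L + faOffset), y = yf,
      kinematics = if (prescribed) "prescribed" else "fixed",
      vy = if (prescribed) vy else 0, stringsAsFactors = FALSE
    )
    faR <- faL
    faR$id <- n0 + nConn + 2L
    faR$x <- max(cx) + (L + faOffset)
    nd <- rbind(nd, conn, faL, faR)
    chain <- c(faL$id, conn$id, faR$id)
    e0 <- nrow(ed)
    nseg <- length(chain) - 1L
    newE <- data.frame(
      id = e0 + seq_len(nseg), kind = "stress_fiber",
      n1 = chain[-length(chain)], n2 = chain[-1],
      t1 = NA_integer_, t2 = NA_integer_,
      ks = p@ksF, kc = p@kcF, d0 = p@d0F,
      state = "attached", tAttach = net@time, tRemove = NA_real_,
      stringsAsFactors = FALSE
    )
    net@nodes <- nd
    net@edges <- rbind(ed, newE)
    net
  }
  net <- addFiber(net, ymax + sfOffset, vy = -p@vA) # top fiber moves down
  net <- addFiber(net, ymin - sfOffset, vy = +p@vA) # bottom fiber moves up
  validObject(net)
  net
}

#' Attach the lattice to fixed focal adhesions by cables
#'
#' Mimics the configuration in which the relaxed spectrin mesh is stretched
#' horizontally by contractile cables anchored at substrate adhesions: one
#' fixed focal adhesion is placed to the left and one to the right of the
#' lattice, and a pure cable edge (constant `kc`) runs from each
#' boundary-column short-actin node to the nearest adhesion.
#'
#' @param net a [Network-class] with the lattice built.
#' @param standoff horizontal distance (nm) from the lattice edge to each
#'   adhesion.
#' @return the augmented [Network-class].
#' @export
addFocalAdhesionCables <- function(net, standoff = 500) {
  nd <- net@nodes
  p <- net@params
  sa <- nd$kind == "short_actin"
  xmin <- min(nd$x[sa])
  xmax <- max(nd$x[sa])
  ymid <- mean(range(nd$y[sa]))
  tol <- p@d0S * 0.6 # boundary columns (odd/even rows are offset by d0/2)
  left <- which(sa & nd$x <= xmin + tol)
  right <- which(sa & nd$x >= xmax - tol)
  n0 <- nrow(nd)
  fa <- data.frame(
    id = n0 + 1:2, kind = "focal_adhesion",
    x = c(xmin - standoff, xmax + standoff), y = ymid,
    kinematics = "fixed", vy = 0, stringsAsFactors = FALSE
  )
  net@nodes <- rbind(nd, fa)
  e0 <- nrow(net@edges)
  mk <- function(ids, faId) {
    data.frame(
      id = integer(length(ids)), kind = "cable", n1 = ids, n2 = faId,
      t1 = NA_integer_, t2 = NA_integer_, ks = 0, kc = p@kc, d0 = 0,
      state = "attached", tAttach = net@time, tRemove = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  newE <- rbind(mk(left, n0 + 1L), mk(right, n0 + 2L))
  newE$id <- e0 + seq_len(nrow(newE))
  net@edges <- rbind(net@edges, newE)
  validObject(net)
  net
}

#' Couple stress-fiber connectors to the lattice by cables
#'
#' Used by the stress-fiber scenario without myosin: each `sf_connector` is
#' joined to the nearest short-actin node by a pure cable edge of constant
#' `kc`, transmitting the fiber contraction to the mesh.
#'
#' @param net a [Network-class] with stress fibers present.
#' @return the augmented [Network-class].
#' @export
addFiberCouplingCables <- function(net) {
  nd <- net@nodes
  conn <- which(nd$kind == "sf_connector")
  if (!length(conn)) stop("no stress fibers present")
  sa <- which(nd$kind == "short_actin")
  p <- net@params
  e0 <- nrow(net@edges)
  target <- vapply(conn, function(i) {
    d2 <- (nd$x[sa] - nd$x[i])^2 + (nd$y[sa] - nd$y[i])^2
    sa[which.min(d2)]
  }, integer(1))
  newE <- data.frame(
    id = e0 + seq_along(conn), kind = "cable", n1 = conn, n2 = target,
    t1 = NA_integer_, t2 = NA_integer_, ks = 0, kc = p@kc, d0 = 0,
    state = "attached", tAttach = net@time, tRemove = NA_real_,
    stringsAsFactors = FALSE
  )
  net@edges <- rbind(net@edges, newE)
  validObject(net)
  net
}

#' Add myosin linkers from the stress fibers to the mesh
#'
#' For each extreme stress-fiber connector (the `sf_connector` adjacent to a
#' focal adhesion), a myosin linker cable (constant `kcL`) is created from
#' that node to the centroid of the nearest free spectrin triangle; the
#' triangle becomes occupied. The cable force acting at a centroid is split
#' equally among the three triangle nodes.
#'
#' @param net a [Network-class] with stress fibers present.
#' @return the augmented [Network-class].
#' @export
addMyosinLinkers <- function(net) {
  nd <- net@nodes
  ed <- net@edges
  p <- net@params
  sf <- ed[ed$kind == "stress_fiber", ]
  if (!nrow(sf)) stop("construction error: no stress fibers present")
  faIds <- nd$id[nd$kind == "focal_adhesion"]
  extremes <- unique(c(
    sf$n2[sf$n1 %in% faIds], sf$n1[sf$n2 %in% faIds]
  ))
  extremes <- extremes[nd$kind[extremes] == "sf_connector"]
  for (nid in extremes) {
    free <- which(freeTriangles(net))
    if (!length(free)) stop("construction error: no free spectrin triangle available")
    cen <- triangleCentroids(net)
    d2 <- (cen[free, 1] - nd$x[nid])^2 + (cen[free, 2] - nd$y[nid])^2
    tid <- free[which.min(d2)]
    e0 <- nrow(net@edges)
    net@edges <- rbind(net@edges, data.frame(
      id = e0 + 1L, kind = "myosin_linker", n1 = nid, n2 = NA_integer_,
      t1 = NA_integer_, t2 = tid, ks = 0, kc = p@kcL, d0 = 0,
      state = "attached", tAttach = net@time, tRemove = NA_real_,
      stringsAsFactors = FALSE
    ))
  }
  validObject(net)
  net
}

#' Add one myosin rod between two free spectrin triangles
#'
#' Picks uniformly at random (from the current RNG stream) one admissible
#' pair of free triangles whose centroid separation lies strictly between
#' `dMin` and `dMax`, and joins their centroids by a myosin rod cable
#' (constant `kcM`). If no admissible pair exists the addition is a no-op
#' and is signalled through the `added` flag.
#'
#' @param net a [Network-class].
#' @return a list with elements `network` (possibly augmented), `added`
#'   (logical) and `edgeId` (the new edge id or NA).
#' @export
addMyosinRod <- function(net) {
  free <- which(freeTriangles(net))
  if (length(free) < 2) {
    return(list(network = net, added = FALSE, edgeId = NA_integer_))
  }
  cen <- triangleCentroids(net)[free, , drop = FALSE]
  dm <- as.matrix(stats::dist(cen))
  p <- net@params
  adm <- which(upper.tri(dm) & dm > p@dMin & dm < p@dMax, arr.ind = TRUE)
  if (!nrow(adm)) {
    return(list(network = net, added = FALSE, edgeId = NA_integer_))
  }
  pick <- adm[sample.int(nrow(adm), 1L), ]
  tid1 <- free[pick[1]]
  tid2 <- free[pick[2]]
  e0 <- nrow(net@edges)
  net@edges <- rbind(net@edges, data.frame(
    id = e0 + 1L, kind = "myosin_rod", n1 = NA_integer_, n2 = NA_integer_,
    t1 = tid1, t2 = tid2, ks = 0, kc = p@kcM, d0 = 0,
    state = "attached", tAttach = net@time, tRemove = NA_real_,
    stringsAsFactors = FALSE
  ))
  list(network = net, added = TRUE, edgeId = e0 + 1L)
}
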