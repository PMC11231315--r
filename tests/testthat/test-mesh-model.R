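# Construction of the triangular lattice, stress fibers and myosin.

test_that("triangular lattice matches a brute-force geometric recount", {
  p <- modelParams()
  for (dims in list(c(3, 3), c(4, 5), c(6, 4))) {
    net <- buildTriangularLattice(dims[1], dims[2], p)
    nd <- nodes(net)
    ed <- edges(net)
    # brute force: neighbours are exactly the pairs at distance d0S
    dm <- as.matrix(dist(cbind(nd$x, nd$y)))
    expectedEdges <- sum(abs(dm - p@d0S) < 1e-6) / 2
    expect_equal(nrow(ed), expectedEdges)
    expect_false(anyDuplicated(paste(ed$n1, ed$n2)) > 0)
    # triangles: triples pairwise at d0S
    nTri <- 0
    n <- nrow(nd)
    for (a in 1:(n - 2)) {
      for (b in (a + 1):(n - 1)) {
        if (abs(dm[a, b] - p@d0S) > 1e-6) next
        for (cc in (b + 1):n) {
          if (abs(dm[a, cc] - p@d0S) < 1e-6 && abs(dm[b, cc] - p@d0S) < 1e-6) {
            nTri <- nTri + 1
          }
        }
      }
    }
    expect_equal(nrow(triangles(net)), nTri)
    # connected: breadth-first search reaches every node
    adj <- lapply(seq_len(n), function(i) {
      c(ed$n2[ed$n1 == i], ed$n1[ed$n2 == i])
    })
    seen <- rep(FALSE, n)
    queue <- 1L
    seen[1] <- TRUE
    while (length(queue)) {
      i <- queue[1]
      queue <- queue[-1]
      nb <- adj[[i]][!seen[adj[[i]]]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    expect_true(all(seen))
  }
})

test_that("rest lattice has all edges at d0S and zero net force", {
  p <- modelParams(d0S = 180)
  net <- buildTriangularLattice(3, 3, p)
  expect_equal(edgeLengthsOf(net), rep(180, nrow(edges(net))), tolerance = 1e-12)
  expect_lt(max(abs(netForce(net))), 1e-9)
  expect_equal(totalEnergy(net), 0, tolerance = 1e-12)
})

test_that("lattice dimensions below 2 are a configuration error", {
  expect_error(buildTriangularLattice(1, 5), "configuration")
  expect_error(buildTriangularLattice(3, 0), "configuration")
})

test_that("stress fibers: construction, rest state and instability seed", {
  p <- modelParams()
  net <- buildTriangularLattice(4, 8, p)
  # faOffset = 0: fiber fully at rest
  net0 <- addStressFibers(net, nSegments = 6, faOffset = 0)
  sf <- edges(net0)[edges(net0)$kind == "stress_fiber", ]
  len <- edgeLengthsOf(net0)[sf$id]
  expect_equal(len, rep(modelParamsOf(net0)@d0F, nrow(sf)), tolerance = 1e-9)
  # spring part at rest; cable still contracts, directed along the fiber
  expect_equal(sum(nodes(net0)$kind == "focal_adhesion"), 4)

  # faOffset > 0: nonzero initial force on the adjacent connector, along x
  net1 <- addStressFibers(net, nSegments = 6, faOffset = 50)
  nd <- nodes(net1)
  ed <- edges(net1)
  faIds <- nd$id[nd$kind == "focal_adhesion"]
  sfE <- ed[ed$kind == "stress_fiber", ]
  extreme <- setdiff(unique(c(
    sfE$n1[sfE$n2 %in% faIds], sfE$n2[sfE$n1 %in% faIds]
  )), faIds)[1]
  # oracle: finite difference of the total energy
  Ffd <- finiteDifferenceForces(net1)
  Fan <- netForce(net1)
  expect_gt(abs(Fan[extreme, 1]), 1e-6) # pulled along the fiber axis
  expect_lt(abs(Fan[extreme, 2]), abs(Fan[extreme, 1]) * 1e-6)
  expect_equal(unname(Fan[extreme, ]), unname(Ffd[extreme, ]),
    tolerance = 1e-5)

  expect_error(
    addStressFibers(net, nSegments = 6, sfOffset = -10),
    "geometry"
  )
})

test_that("myosin linkers attach at the centroid of the nearest free triangle", {
  p <- modelParams()
  net <- buildTriangularLattice(4, 8, p)
  net <- addStressFibers(net, nSegments = 5, faOffset = 40)
  netL <- addMyosinLinkers(net)
  ed <- edges(netL)
  link <- ed[ed$kind == "myosin_linker", ]
  expect_gt(nrow(link), 0)
  cen <- triangleCentroids(netL)
  nd <- nodes(netL)
  tr <- triangles(netL)
  for (i in seq_len(nrow(link))) {
    tid <- link$t2[i]
    # attachment point equals mean of the three node positions
    expect_equal(
      unname(cen[tid, 1]),
      mean(nd$x[c(tr$a[tid], tr$b[tid], tr$c[tid])])
    )
    # nearest-triangle selection matches exhaustive scan (among triangles
    # free at that construction step: all linkers target distinct triangles)
    nid <- link$n1[i]
    d2 <- (cen[, 1] - nd$x[nid])^2 + (cen[, 2] - nd$y[nid])^2
    taken <- link$t2[seq_len(i - 1)]
    d2[taken] <- Inf
    expect_equal(tid, which.min(d2))
  }
})

test_that("linker cable force at a centroid is split equally among the 3 nodes", {
  p <- modelParams()
  net <- buildTriangularLattice(4, 8, p)
  net <- addStressFibers(net, nSegments = 5, faOffset = 0)
  net <- addMyosinLinkers(net)
  ed <- edges(net)
  link <- ed[ed$kind == "myosin_linker", ][1, ]
  tr <- triangles(net)[link$t2, ]
  # isolate the linker: keep only that edge attached
  ed$state <- ifelse(ed$id == link$id, "attached", "removed")
  net@edges <- ed
  F <- netForce(net)
  nids <- c(tr$a, tr$b, tr$c)
  # each triangle node receives exactly one third of the cable force
  cen <- triangleCentroids(net)[link$t2, ]
  nd <- nodes(net)
  dvec <- c(nd$x[link$n1] - cen[1], nd$y[link$n1] - cen[2])
  fcab <- p@kcL * sqrt(sum(dvec^2)) # cable force magnitude at the centroid
  for (nid in nids) {
    expect_equal(sqrt(sum(F[nid, ]^2)), fcab / 3, tolerance = 1e-9)
  }
  # and the stress-fiber end carries the full, opposite force
  expect_equal(F[link$n1, ], -3 * F[nids[1], ], tolerance = 1e-9)
})

test_that("myosin rod addition respects length bounds, occupancy and seeding", {
  p <- modelParams()
  net <- buildTriangularLattice(5, 8, p)
  set.seed(11)
  res <- addMyosinRod(net)
  expect_true(res$added)
  rod <- edges(res$network)[res$edgeId, ]
  len <- edgeLengthsOf(res$network)[res$edgeId]
  expect_gt(len, p@dMin)
  expect_lt(len, p@dMax)
  # occupancy flags equal the triangles referenced by live myosin (rescan)
  occ <- which(!freeTriangles(res$network) & intactTriangles(res$network))
  expect_setequal(occ, c(rod$t1, rod$t2))
  # seeded determinism of repeated placements
  place <- function(seed) {
    set.seed(seed)
    n2 <- net
    ids <- integer()
    for (k in 1:5) {
      r <- addMyosinRod(n2)
      n2 <- r$network
      ids <- c(ids, edges(n2)$t1[r$edgeId], edges(n2)$t2[r$edgeId])
    }
    ids
  }
  expect_identical(place(99), place(99))
  # no-op when no free triangle pair exists: a 2x2 lattice has two
  # triangles whose centroids sit d0/sqrt(3) = 104 nm apart, below dMin
  tiny <- buildTriangularLattice(2, 2, modelParams(dMin = 150))
  set.seed(1)
  r0 <- addMyosinRod(tiny)
  expect_false(r0$added)
  expect_identical(r0$network, tiny)
})

test_that("node count is only changed by explicit add operations", {
  p <- modelParams()
  net <- buildTriangularLattice(4, 6, p)
  n0 <- nrow(nodes(net))
  set.seed(3)
  r <- addMyosinRod(net)
  expect_equal(nrow(nodes(r$network)), n0) # rods add no nodes
  net2 <- addStressFibers(net, nSegments = 4)
  # two fibers: (nSegments - 1) connectors + 2 adhesions each
  expect_equal(nrow(nodes(net2)), n0 + 2 * (3 + 2))
  expect_true(validObject(net2))
})
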