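# Microscopy operators on synthetic inputs with known truth.

test_that("cluster segmentation keeps the top cutoff fraction", {
  set.seed(1)
  img <- cortexImage(matrix(runif(256 * 256), 256), pixelSize = 0.1)
  s <- segmentClusters(img, cutoff = 0.05)
  npix <- 256 * 256
  expect_lt(abs(s$foregroundFraction - 0.05), 2 / sqrt(npix)) # quantile rounding
  expect_error(segmentClusters(cortexImage(matrix(1, 10, 10))), "degenerate")
})

test_that("segmentation shape descriptors: disk and 2:1 ellipse", {
  set.seed(2)
  n <- 200
  mkblob <- function(ry, rx) {
    m <- matrix(0, n, n)
    for (r in 1:n) {
      w <- which(((r - 100) / ry)^2 + ((seq_len(n) - 100) / rx)^2 <= 1)
      m[r, w] <- 1
    }
    m + matrix(runif(n * n), n) * 0.01
  }
  disk <- segmentClusters(cortexImage(mkblob(20, 20), pixelSize = 0.1),
    cutoff = 0.04
  )
  expect_equal(nrow(disk$clusters), 1)
  expect_lt(abs(disk$clusters$aspectRatio - 1), 0.1)
  # area of the disk: pi * (20 * 0.1)^2 = 12.6 um2
  expect_equal(disk$clusters$areaUm2, pi * 4, tolerance = 0.1)
  ell <- segmentClusters(cortexImage(mkblob(20, 40), pixelSize = 0.1),
    cutoff = 0.08
  )
  expect_equal(nrow(ell$clusters), 1)
  expect_equal(ell$clusters$aspectRatio, 2, tolerance = 0.1)
})

test_that("intensity distribution: normalization and model selection", {
  set.seed(3)
  spec <- sceneSpec(fov = 64, pixelSize = 0.5)
  f <- genLognormalField(4, 0.5, spec)
  d <- intensityDistribution(f)
  expect_equal(sum(d$freq), 1, tolerance = 1e-12)
  expect_equal(d$better, "lognormal")
  # normally distributed field chooses the normal model
  n <- 128
  g <- cortexImage(matrix(rnorm(n * n, 100, 10), n),
    pixelSize = 1, mask = matrix(TRUE, n, n)
  )
  expect_equal(intensityDistribution(g)$better, "normal")
  # constant image inside the mask occupies a single bin
  cimg <- cortexImage(matrix(5, 32, 32), pixelSize = 1,
    mask = matrix(TRUE, 32, 32))
  expect_equal(sum(intensityDistribution(cimg)$freq > 0), 1)
  # missing mask is an error
  expect_error(intensityDistribution(cortexImage(matrix(runif(64), 8))), "mask")
})

test_that("structure tensor recovers stripe orientation and isotropy", {
  n <- 256
  X <- outer(rep(1, n), 1:n)
  Y <- outer(1:n, rep(1, n))
  mk <- function(deg) { # stripes whose long axis lies at `deg`
    gradDir <- (deg + 90) * pi / 180
    cortexImage(sin(2 * pi * (X * cos(gradDir) + Y * sin(gradDir)) / 10))
  }
  om30 <- orientationCoherency(mk(30))
  expect_lt(angDiff(om30@dominantDirection, 30), 1)
  expect_gt(mean(om30@coherency), 0.9)
  # intensity rescaling leaves orientation and coherency unchanged
  img30 <- mk(30)
  om30b <- orientationCoherency(
    cortexImage(pixelData(img30) * 37 + 2)
  )
  expect_equal(om30b@orientation, om30@orientation, tolerance = 1e-6)
  expect_equal(om30b@coherency, om30@coherency, tolerance = 1e-6)
  # rotation equivariance across a sweep of angles
  for (a in c(-60, 0, 45, 80)) {
    om <- orientationCoherency(mk(a))
    expect_lt(angDiff(om@dominantDirection, a), 1.5)
  }
  # i.i.d. noise: near-isotropic
  set.seed(4)
  omN <- orientationCoherency(cortexImage(matrix(rnorm(512^2), 512)))
  expect_lt(mean(omN@coherency), 0.1)
})

test_that("orientation histogram aligns to the reference dominant direction", {
  n <- 256
  X <- outer(rep(1, n), 1:n)
  Y <- outer(1:n, rep(1, n))
  mk <- function(deg) {
    gradDir <- (deg + 90) * pi / 180
    cortexImage(sin(2 * pi * (X * cos(gradDir) + Y * sin(gradDir)) / 10))
  }
  omA <- orientationCoherency(mk(40)) # "actin" reference
  omB <- orientationCoherency(mk(40)) # aligned channel
  h <- orientationHistogram(omB, reference = omA)
  expect_equal(sum(h$freq), 1, tolerance = 1e-9)
  expect_lt(abs(h$angle[which.max(h$freq)]), 3) # peak at ~0 deg
})

test_that("NND: pairs, grids and the Poisson-process expectation", {
  nn2 <- nearestNeighborDistances(rbind(c(0, 0), c(500, 0)))
  expect_equal(unname(nn2$nnd), c(500, 500))
  # square grid of spacing s: all NND = s
  g <- expand.grid(x = seq(0, 4) * 2, y = seq(0, 4) * 2)
  nng <- nearestNeighborDistances(g)
  expect_true(all(abs(nng$nnd - 2) < 1e-12))
  expect_error(nearestNeighborDistances(rbind(c(0, 0))), "2 points")
  # homogeneous Poisson process: mean NND ~ 0.5/sqrt(lambda) within 3 SE
  set.seed(5)
  L <- 10
  lambda <- 25
  npts <- rpois(1, lambda * L^2)
  pts <- cbind(runif(npts) * L, runif(npts) * L)
  nn <- nearestNeighborDistances(pts, torusPeriod = L)
  se <- sd(nn$nnd) / sqrt(npts)
  expect_lt(abs(nn$mean - 0.5 / sqrt(lambda)), 3 * se)
})

test_that("line-scan periodicity: sinusoid and expansion extrapolation", {
  # pure sinusoid of period P along x -> mean spacing = P
  n <- 400
  px <- 0.02
  P <- 0.8 # um
  prof <- sin(2 * pi * (seq_len(n) - 0.5) * px / P)
  img <- cortexImage(matrix(prof, n, n, byrow = TRUE), pixelSize = px)
  lp <- lineScanPeriodicity(img, rbind(c(0.1, 4), c(7.9, 4)))
  expect_equal(lp$meanSpacingReal, P * 1000, tolerance = 0.02)
  # peaks at 760 nm spacing with expansion 4 extrapolate to 190 nm
  g <- genPeriodicArray(190, 8, sceneSpec(
    fov = 8, pixelSize = 0.02, psfSigma = 100, noise = "none", expansion = 4
  ))
  lp2 <- lineScanPeriodicity(g$image, rbind(c(0.2, 4), c(7.8, 4)),
    expansionFactor = 4
  )
  expect_equal(lp2$meanSpacingReal, 760, tolerance = 0.02)
  expect_equal(lp2$meanSpacingExtrapolated, 190, tolerance = 0.02)
  expect_error(
    lineScanPeriodicity(img, rbind(c(0.1, 4), c(0.2, 4))),
    "peaks"
  )
})

test_that("inverted FRET: normalization, bimodality and acceptor pairing", {
  set.seed(6)
  tm <- matrix(0.2, 128, 128)
  tm[, 65:128] <- 0.8
  fp <- genFretPair(tm, sceneSpec(noiseSigma = 0.01), "anticorrelated")
  iv <- invertedFret(fp$donor, fp$fret, fp$mask, acceptor = fp$acceptor)
  v <- pixelData(iv$invFret)
  inside <- is.finite(v)
  expect_equal(min(v[inside]), 0)
  expect_equal(max(v[inside]), 1)
  # bimodal with the generated mode order: low-tension zone lower invFRET
  left <- mean(v[, 1:48], na.rm = TRUE)
  right <- mean(v[, 81:128], na.rm = TRUE)
  expect_lt(left, right)
  # anti-correlated acceptor scenario: negative correlation in the table
  expect_lt(cor(iv$pixelTable$invFret, iv$pixelTable$acceptor), -0.5)
  # constant ratio degenerates to uniform 0 with a warning
  same <- cortexImage(matrix(10, 32, 32), pixelSize = 0.1)
  expect_warning(iv0 <- invertedFret(same, same), "degenerate")
  expect_true(all(pixelData(iv0$invFret) == 0))
})

test_that("FRAP fit recovers parameters and the half-time identity", {
  fc <- genFrapCurve(I0 = 0.2, Imax = 0.6, k = 0.05, noiseSigma = 0,
    times = seq(0, 300, 3))
  ff <- frapFit(fc$time, fc$intensity)
  expect_equal(ff@I0, 0.2, tolerance = 1e-6)
  expect_equal(ff@Imax, 0.6, tolerance = 1e-6)
  expect_equal(ff@k, 0.05, tolerance = 1e-6)
  expect_equal(ff@halfTime, log(2) / 0.05, tolerance = 1e-6)
  expect_equal(ff@mobileFraction, 0.8, tolerance = 1e-6)
  # I(0) = I0 exactly in the forward model
  expect_equal(fc$intensity[fc$time == 0], 0.2)
  # noisy recovery study: median k within 5%
  set.seed(7)
  ks <- replicate(100, {
    fcn <- genFrapCurve(0.2, 0.6, 0.05, noiseSigma = 0.02,
      times = seq(0, 300, 3))
    frapFit(fcn$time, fcn$intensity)@k
  })
  expect_lt(abs(median(ks) - 0.05) / 0.05, 0.05)
  expect_error(frapFit(1:3, 1:3), "5 post-bleach")
})

test_that("cross-correlation shift: identity, translation, and null", {
  set.seed(8)
  a <- matrix(rnorm(128 * 128), 128)
  A <- cortexImage(a)
  cc <- crossCorrelationShift(A, A, maxShift = 20)
  expect_equal(cc$rZero, 1)
  expect_equal(cc$peakShift, 0)
  # channel translated by +7 px peaks at +7
  b <- cbind(matrix(0, 128, 7), a[, 1:(128 - 7)])
  cc7 <- crossCorrelationShift(A, cortexImage(b), maxShift = 20)
  expect_equal(cc7$peakShift, 7)
  # independent noise channels stay near zero at all shifts
  d <- matrix(rnorm(512 * 512), 512)
  e <- matrix(rnorm(512 * 512), 512)
  ccN <- crossCorrelationShift(cortexImage(d), cortexImage(e), maxShift = 50)
  expect_lt(max(abs(ccN$r)), 0.05)
  expect_error(
    crossCorrelationShift(cortexImage(matrix(1, 8, 8)), A),
    "shapes|constant"
  )
})

test_that("mask autocorrelation: identity, complement and flip noise", {
  set.seed(9)
  m <- matrix(runif(64 * 64) > 0.5, 64)
  expect_equal(maskAutocorrelation(list(m, m))$r, 1)
  expect_equal(maskAutocorrelation(list(m, !m))$r, -1)
  # per-pixel flip probability p: expected r = 1 - 2p for a q = 0.5 mask
  p <- 0.2
  nrep <- 40
  rs <- replicate(nrep, {
    m1 <- matrix(runif(64 * 64) > 0.5, 64)
    flip <- matrix(runif(64 * 64) < p, 64)
    m2 <- xor(m1, flip)
    maskAutocorrelation(list(m1, m2))$r
  })
  se <- sd(rs) / sqrt(nrep)
  expect_lt(abs(mean(rs) - (1 - 2 * p)), 3 * se)
  # empty mask flagged
  z <- matrix(FALSE, 8, 8)
  expect_true(maskAutocorrelation(list(z, m[1:8, 1:8]))$degenerate)
})

test_that("normalized cluster area tracks the generated schedule", {
  set.seed(10)
  # static stack: constant series of 1
  st0 <- genClusterTimelapse(rep(1, 5), sceneSpec(noiseSigma = 0.005))
  na0 <- normalizedClusterArea(st0$stack)
  expect_equal(na0$normalizedArea, rep(1, 5), tolerance = 0.05)
  # dissolving cluster: monotone decrease matching the schedule within 5%
  sched <- seq(1, 0.4, length.out = 8)
  st <- genClusterTimelapse(sched, sceneSpec(noiseSigma = 0.005))
  na <- normalizedClusterArea(st$stack)
  expect_true(all(diff(na$normalizedArea) < 0.02))
  expect_equal(na$normalizedArea, sched, tolerance = 0.05)
  expect_error(
    normalizedClusterArea(list(matrix(0, 8, 8), matrix(0, 8, 8))),
    "initial"
  )
})

test_that("background subtraction flattens a smooth gradient", {
  n <- 128
  bg <- outer(seq(0, 5, length.out = n), seq(0, 5, length.out = n), "+")
  spot <- matrix(0, n, n)
  spot[60:68, 60:68] <- 10
  img <- cortexImage(bg + spot, pixelSize = 0.1)
  out <- backgroundSubtract(img, radius = 20)
  # the spot survives, the large-scale ramp is mostly gone
  expect_gt(max(pixelData(out)[60:68, 60:68]), 5)
  corner <- pixelData(out)[1:20, 1:20]
  expect_lt(mean(corner), 1)
})
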