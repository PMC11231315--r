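## Quantitative microscopy operators. All operate on CortexImage carriers
## (matrix rows = y, columns = x; physical position of pixel (r, c) is
## ((c - 0.5), (r - 0.5)) * pixelSize micrometres).

#' Large-scale background subtraction
#'
#' Removes slowly varying background by morphological top-hat filtering
#' (grayscale opening with a disc of the given radius, subtracted from the
#' image), the same large-scale background removal effected by rolling-ball
#' style tools.
#'
#' @param img a [CortexImage-class].
#' @param radius structuring-element radius in pixels (default 50).
#' @return background-subtracted [CortexImage-class].
#' @export
backgroundSubtract <- function(img, radius = 50) {
  x <- img@data
  rng <- range(x)
  if (diff(rng) == 0) return(img)
  xn <- (x - rng[1]) / diff(rng)
  brush <- EBImage::makeBrush(2 * radius + 1, shape = "disc")
  bg <- EBImage::opening(xn, brush)
  img@data <- pmax(xn - bg, 0) * diff(rng)
  img
}

#' Segment high-intensity clusters at the top intensity quantile
#'
#' Implements the P_0.95 cluster definition: pixels in the top `cutoff`
#' fraction (default 5%) of the intensity distribution are set to
#' foreground, the remaining 95% to background. The binary mask is then
#' despeckled (3x3 median) and smoothed (3x3 mean, re-binarised at 0.5),
#' and connected components are measured: area (converted to square
#' micrometres) and aspect ratio of the second-moment best-fit ellipse.
#'
#' @param img a single-channel [CortexImage-class] (background subtraction,
#'   if wanted, is applied upstream).
#' @param cutoff foreground fraction (default 0.05).
#' @param minArea drop components smaller than this many pixels (default 1,
#'   i.e. keep all).
#' @return list with `mask` (binary [CortexImage-class]), `clusters`
#'   (data.frame: id, areaUm2, aspectRatio, cx, cy in micrometres),
#'   `threshold`, and `foregroundFraction` (pre-filter fraction above
#'   threshold).
#' @export
segmentClusters <- function(img, cutoff = 0.05, minArea = 1) {
  x <- img@data
  if (diff(range(x)) == 0) {
    stop("degenerate-threshold error: image is constant")
  }
  thr <- stats::quantile(x, 1 - cutoff, names = FALSE)
  m <- (x > thr) * 1
  frac <- mean(m)
  ## despeckle then smooth, both on the binary mask
  m <- EBImage::medianFilter(m, 1)
  kern <- matrix(1 / 9, 3, 3)
  m <- (EBImage::filter2(m, kern) >= 0.5) * 1
  lab <- EBImage::bwlabel(m)
  nlab <- max(lab)
  clusters <- data.frame(
    id = integer(), areaUm2 = numeric(), aspectRatio = numeric(),
    cx = numeric(), cy = numeric()
  )
  if (nlab > 0) {
    px <- img@pixelSize
    idx <- which(lab > 0, arr.ind = TRUE)
    lv <- lab[lab > 0]
    rows <- split(idx[, 1], lv)
    cols <- split(idx[, 2], lv)
    feats <- lapply(seq_len(nlab), function(k) {
      r <- rows[[k]]
      ccol <- cols[[k]]
      n <- length(r)
      if (n < minArea) return(NULL)
      ## second-moment ellipse with the 1/12 single-pixel variance term
      vr <- stats::var(r) * (n - 1) / n + 1 / 12
      vc <- stats::var(ccol) * (n - 1) / n + 1 / 12
      vrc <- if (n > 1) stats::cov(r, ccol) * (n - 1) / n else 0
      tr2 <- (vr + vc) / 2
      det4 <- sqrt(max(((vr - vc) / 2)^2 + vrc^2, 0))
      l1 <- tr2 + det4
      l2 <- max(tr2 - det4, .Machine$double.eps)
      data.frame(
        id = k, areaUm2 = n * px^2, aspectRatio = sqrt(l1 / l2),
        cx = (mean(ccol) - 0.5) * px, cy = (mean(r) - 0.5) * px
      )
    })
    feats <- feats[!vapply(feats, is.null, logical(1))]
    if (length(feats)) clusters <- do.call(rbind, feats)
    clusters$id <- seq_len(nrow(clusters))
  }
  list(
    mask = cortexImage(m, pixelSize = img@pixelSize, bitDepth = 8),
    clusters = clusters, threshold = thr, foregroundFraction = frac
  )
}

#' Fluorescence intensity distribution per square micrometre
#'
#' Down-samples the image to 1 x 1 micrometre pixels (block/bilinear
#' average), converts to 8-bit by min-max scaling, histograms the values
#' inside the cell mask as relative frequencies, and fits both a normal and
#' a log-normal model to the per-square-micrometre intensities, reporting
#' which has the lower fit error (sum of squared differences between the
#' empirical relative frequencies and the model bin probabilities).
#'
#' @param img a [CortexImage-class] carrying a cell mask.
#' @return list with `values` (8-bit intensities inside the mask), `breaks`,
#'   `freq` (relative frequencies, summing to 1), `fits` (the two fitted
#'   models), `sse` (named fit errors) and `better` ("lognormal" or
#'   "normal").
#' @export
intensityDistribution <- function(img) {
  msk <- cellMask(img)
  if (is.null(msk) || !any(msk)) stop("cell mask absent or empty")
  f <- 1 / img@pixelSize # pixels per micrometre
  x <- img@data
  if (abs(f - round(f)) < 1e-9 && round(f) >= 1) {
    x1 <- blockMean(x, round(f))
    m1 <- blockMean(msk * 1, round(f)) >= 0.5
  } else {
    w <- max(1, round(nrow(x) * img@pixelSize))
    h <- max(1, round(ncol(x) * img@pixelSize))
    x1 <- EBImage::resize(x, w = w, h = h)
    m1 <- EBImage::resize(msk * 1, w = w, h = h) >= 0.5
  }
  if (!any(m1)) stop("cell mask empty after down-sampling")
  rng <- range(x1)
  v8 <- if (diff(rng) == 0) {
    matrix(0, nrow(x1), ncol(x1))
  } else {
    round((x1 - rng[1]) / diff(rng) * 255)
  }
  vals <- v8[m1]
  breaks <- seq(-0.5, 255.5, by = 1)
  h <- hist(vals, breaks = breaks, plot = FALSE)
  freq <- h$counts / sum(h$counts)
  sse <- c(lognormal = NA_real_, normal = NA_real_)
  fits <- list(lognormal = NULL, normal = NULL)
  pos <- vals[vals > 0]
  if (length(unique(pos)) > 2 && stats::sd(vals) > 0) {
    fits$normal <- tryCatch(
      fitdistrplus::fitdist(as.numeric(vals), "norm"),
      error = function(e) NULL
    )
    fits$lognormal <- tryCatch(
      fitdistrplus::fitdist(as.numeric(pos), "lnorm"),
      error = function(e) NULL
    )
    mids <- h$mids
    if (!is.null(fits$normal)) {
      p <- coef(fits$normal)
      pr <- stats::pnorm(mids + 0.5, p[1], p[2]) - stats::pnorm(mids - 0.5, p[1], p[2])
      sse["normal"] <- sum((freq - pr)^2)
    }
    if (!is.null(fits$lognormal)) {
      p <- coef(fits$lognormal)
      pr <- stats::plnorm(mids + 0.5, p[1], p[2]) - stats::plnorm(pmax(mids - 0.5, 0), p[1], p[2])
      sse["lognormal"] <- sum((freq - pr)^2)
    }
  }
  better <- if (all(is.na(sse))) NA_character_ else names(which.min(sse))
  list(values = vals, breaks = breaks, freq = freq, fits = fits,
    sse = sse, better = better)
}

## Gaussian blur whose kernel never exceeds the image extent.
safeGblur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  radius <- 2 * ceiling(3 * sigma) + 1
  rmax <- min(dim(x)) - 1
  if (rmax %% 2 == 0) rmax <- rmax - 1
  if (radius > rmax) radius <- max(rmax, 3)
  EBImage::gblur(x, sigma = sigma, radius = radius)
}

blockMean <- function(x, f) {
  nr <- floor(nrow(x) / f)
  nc <- floor(ncol(x) / f)
  x <- x[seq_len(nr * f), seq_len(nc * f), drop = FALSE]
  ## average f x f blocks
  y <- rowsum(x, rep(seq_len(nr), each = f)) / f
  t(rowsum(t(y), rep(seq_len(nc), each = f)) / f)
}

#' Detect local intensity maxima
#'
#' A pixel is a maximum when it attains the maximum of its neighbourhood
#' (square window of half-width `halfWindow`) and exceeds a prominence
#' threshold expressed as a fraction of the image dynamic range.
#'
#' @param img a [CortexImage-class].
#' @param halfWindow neighbourhood half-width in pixels (default 1: 3x3).
#' @param prominence minimum height above the image minimum, as a fraction
#'   of the dynamic range (default 0.1).
#' @return data.frame with columns `row`, `col` (pixels), `x`, `y`
#'   (micrometres) and `value`.
#' @export
findLocalMaxima <- function(img, halfWindow = 1, prominence = 0.1) {
  x <- img@data
  rng <- range(x)
  mx <- maxFilter(x, halfWindow)
  ok <- x >= mx & x > rng[1] + prominence * diff(rng)
  idx <- which(ok, arr.ind = TRUE)
  ## suppress plateau duplicates: keep one pixel per connected plateau
  if (nrow(idx) > 1) {
    lab <- EBImage::bwlabel(ok * 1)
    keep <- !duplicated(lab[ok])
    idx <- idx[keep, , drop = FALSE]
  }
  data.frame(
    row = idx[, 1], col = idx[, 2],
    x = (idx[, 2] - 0.5) * img@pixelSize,
    y = (idx[, 1] - 0.5) * img@pixelSize,
    value = x[idx]
  )
}

maxFilter <- function(x, hw) {
  out <- x
  nr <- nrow(x)
  nc <- ncol(x)
  for (dr in -hw:hw) {
    for (dc in -hw:hw) {
      if (dr == 0 && dc == 0) next
      rs <- pmin(pmax(seq_len(nr) + dr, 1), nr)
      cs <- pmin(pmax(seq_len(nc) + dc, 1), nc)
      out <- pmax(out, x[rs, cs, drop = FALSE])
    }
  }
  out
}

#' Nearest-neighbour distances between points or detected maxima
#'
#' @param pts either a two-column matrix/data.frame of coordinates, or a
#'   [CortexImage-class] from which local maxima are first extracted with
#'   [findLocalMaxima()] (coordinates then in micrometres).
#' @param torusPeriod optional period `c(Lx, Ly)` (or a scalar) for
#'   distances computed with periodic boundary conditions, removing the
#'   edge bias when comparing against infinite-domain point-process
#'   expectations.
#' @param ... passed to [findLocalMaxima()] for image input.
#' @return list with `nnd` (per-point nearest-neighbour distance, input
#'   units), `mean`, `sd`, `points`.
#' @export
nearestNeighborDistances <- function(pts, torusPeriod = NULL, ...) {
  if (is(pts, "CortexImage")) {
    mx <- findLocalMaxima(pts, ...)
    pts <- cbind(mx$x, mx$y)
  }
  pts <- as.matrix(pts)[, 1:2, drop = FALSE]
  if (nrow(pts) < 2) stop("need at least 2 points for NND")
  if (is.null(torusPeriod)) {
    dm <- as.matrix(stats::dist(pts))
  } else {
    if (length(torusPeriod) == 1) torusPeriod <- rep(torusPeriod, 2)
    dx <- abs(outer(pts[, 1], pts[, 1], "-"))
    dy <- abs(outer(pts[, 2], pts[, 2], "-"))
    dx <- pmin(dx, torusPeriod[1] - dx)
    dy <- pmin(dy, torusPeriod[2] - dy)
    dm <- sqrt(dx^2 + dy^2)
  }
  diag(dm) <- Inf
  nnd <- unname(apply(dm, 1, min))
  list(nnd = nnd, mean = mean(nnd), sd = stats::sd(nnd), points = pts)
}

#' Peak-to-peak periodicity along a line scan
#'
#' Samples the intensity profile along a polyline (bilinear interpolation),
#' detects local maxima, and reports consecutive peak-to-peak distances at
#' acquisition scale ("real") and divided by the expansion factor
#' ("extrapolated" specimen-scale distances).
#'
#' @param img a [CortexImage-class].
#' @param polyline two-column matrix of vertices in micrometres (x, y).
#' @param expansionFactor expansion-microscopy factor (default 1).
#' @param samplingStep profile sampling step in pixels (default 0.5).
#' @param minSeparation minimum peak separation in micrometres (default 2
#'   pixels).
#' @param prominence peak height threshold as a fraction of the profile
#'   dynamic range (default 0.1).
#' @param profileSmooth Gaussian sigma (in pixels) used to smooth the
#'   sampled profile before peak detection (default 2; 0 disables).
#' @return list with `profile` (data.frame: s (um), intensity), `peaks`
#'   (arc-length positions, um), `spacingReal` (nm), `spacingExtrapolated`
#'   (nm), `meanSpacingReal`, `meanSpacingExtrapolated`.
#' @export
lineScanPeriodicity <- function(img, polyline, expansionFactor = 1,
                                samplingStep = 0.5, minSeparation = NULL,
                                prominence = 0.1, profileSmooth = 2) {
  polyline <- as.matrix(polyline)
  px <- img@pixelSize
  if (is.null(minSeparation)) minSeparation <- 2 * px
  ## arc-length sample points
  segs <- diff(polyline)
  segLen <- sqrt(rowSums(segs^2))
  stotal <- sum(segLen)
  s <- seq(0, stotal, by = samplingStep * px)
  cums <- c(0, cumsum(segLen))
  seg <- findInterval(s, cums, rightmost.closed = TRUE)
  seg[seg > nrow(segs)] <- nrow(segs)
  frac <- (s - cums[seg]) / segLen[seg]
  xy <- polyline[seg, , drop = FALSE] + segs[seg, , drop = FALSE] * frac
  prof <- bilinearSample(img@data, xy[, 1] / px + 0.5, xy[, 2] / px + 0.5)
  if (profileSmooth > 0) {
    sigS <- profileSmooth / samplingStep # in samples
    half <- ceiling(3 * sigS)
    kern <- exp(-((-half):half)^2 / (2 * sigS^2))
    kern <- kern / sum(kern)
    prof <- as.numeric(stats::filter(c(
      rep(prof[1], half), prof, rep(prof[length(prof)], half)
    ), kern, sides = 2))[(half + 1):(half + length(prof))]
  }
  ## 1D local maxima with minimum separation and prominence
  rng <- range(prof)
  thr <- rng[1] + prominence * diff(rng)
  w <- max(1L, as.integer(round(minSeparation / (samplingStep * px))))
  n <- length(prof)
  isMax <- vapply(seq_len(n), function(i) {
    lo <- max(1, i - w)
    hi <- min(n, i + w)
    prof[i] >= max(prof[lo:hi]) && prof[i] > thr
  }, logical(1))
  ## one peak per plateau
  pk <- which(isMax)
  if (length(pk) > 1) pk <- pk[c(TRUE, diff(pk) > w)]
  if (length(pk) < 2) stop("fewer than 2 peaks detected along the line scan")
  pos <- s[pk]
  spacing <- diff(pos) * 1000 # nm
  list(
    profile = data.frame(s = s, intensity = prof),
    peaks = pos, spacingReal = spacing,
    spacingExtrapolated = spacing / expansionFactor,
    meanSpacingReal = mean(spacing),
    meanSpacingExtrapolated = mean(spacing) / expansionFactor
  )
}

## bilinear interpolation at fractional pixel centres (cx, cy in pixel
## units where pixel (r, c) is centred at (c - 0.5 + 1... ) -- here we use
## continuous coordinates u = column, v = row with pixel centres at
## integers.
bilinearSample <- function(x, u, v) {
  nr <- nrow(x)
  nc <- ncol(x)
  u <- pmin(pmax(u, 1), nc)
  v <- pmin(pmax(v, 1), nr)
  c0 <- pmin(floor(u), nc - 1)
  r0 <- pmin(floor(v), nr - 1)
  fu <- u - c0
  fv <- v - r0
  x[cbind(r0, c0)] * (1 - fu) * (1 - fv) +
    x[cbind(r0, c0 + 1)] * fu * (1 - fv) +
    x[cbind(r0 + 1, c0)] * (1 - fu) * fv +
    x[cbind(r0 + 1, c0 + 1)] * fu * fv
}

#' Pearson cross-correlation under lateral shifts
#'
#' Pearson correlation between two channels when the second is shifted
#' along x by -`maxShift`..+`maxShift` pixels. With the sign convention
#' used here the curve peaks at +s when `chB` equals `chA` translated by
#' +s pixels (towards larger x).
#'
#' @param chA,chB equal-shape [CortexImage-class] channels.
#' @param maxShift maximum lateral shift in pixels (default 50).
#' @return list with `shift` (px), `r` (Pearson coefficients),
#'   `rZero` (r at zero shift), `peakShift`.
#' @export
crossCorrelationShift <- function(chA, chB, maxShift = 50) {
  a <- chA@data
  b <- chB@data
  if (!identical(dim(a), dim(b))) stop("channel shapes differ")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("constant channel: correlation undefined")
  }
  shifts <- -maxShift:maxShift
  r <- vapply(shifts, function(s) {
    nc <- ncol(a)
    if (abs(s) >= nc) return(NA_real_)
    if (s >= 0) {
      av <- a[, 1:(nc - s), drop = FALSE]
      bv <- b[, (1 + s):nc, drop = FALSE]
    } else {
      av <- a[, (1 - s):nc, drop = FALSE]
      bv <- b[, 1:(nc + s), drop = FALSE]
    }
    stats::cor(as.vector(av), as.vector(bv))
  }, numeric(1))
  list(
    shift = shifts, r = r, rZero = r[shifts == 0],
    peakShift = shifts[which.max(r)]
  )
}

#' Autocorrelation of a mask time series
#'
#' Pearson correlation between each pair of consecutive binary masks in a
#' stack; frames whose mask is constant (empty or full) yield NA and are
#' flagged.
#'
#' @param stack list of logical/0-1 matrices, or a 3D array with frames in
#'   the third dimension.
#' @return data.frame with columns `frame` (index of the first frame of the
#'   pair), `r`, `degenerate`.
#' @export
maskAutocorrelation <- function(stack) {
  frames <- stackToList(stack)
  if (length(frames) < 2) stop("need at least 2 frames")
  out <- lapply(seq_len(length(frames) - 1L), function(i) {
    a <- as.numeric(frames[[i]])
    b <- as.numeric(frames[[i + 1]])
    deg <- stats::sd(a) == 0 || stats::sd(b) == 0
    data.frame(
      frame = i, r = if (deg) NA_real_ else stats::cor(a, b),
      degenerate = deg
    )
  })
  do.call(rbind, out)
}

stackToList <- function(stack) {
  if (is.array(stack) && length(dim(stack)) == 3) {
    lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  } else if (is.list(stack)) {
    lapply(stack, function(f) if (is(f, "CortexImage")) f@data else f)
  } else {
    stop("stack must be a list or 3D array")
  }
}

#' Normalized cluster area over a time lapse
#'
#' Applies a fixed intensity threshold computed from the initial frames
#' (the top `cutoff` quantile) to every frame, despeckles and smooths the
#' binary masks, and uses the mask mean as a proxy of cumulative cluster
#' area, normalized to the initial frames.
#'
#' @param stack list of matrices/[CortexImage-class] or 3D array.
#' @param cutoff foreground fraction used on the initial frames (default
#'   0.05).
#' @param nInitial number of initial frames defining the threshold and the
#'   normalisation (default 1).
#' @return data.frame with columns `frame`, `maskMean`, `normalizedArea`.
#' @export
normalizedClusterArea <- function(stack, cutoff = 0.05, nInitial = 1) {
  frames <- stackToList(stack)
  thr <- stats::quantile(unlist(frames[seq_len(nInitial)]), 1 - cutoff,
    names = FALSE
  )
  kern <- matrix(1 / 9, 3, 3)
  mm <- vapply(frames, function(f) {
    m <- (f > thr) * 1
    m <- EBImage::medianFilter(m, 1)
    m <- (EBImage::filter2(m, kern) >= 0.5) * 1
    mean(m)
  }, numeric(1))
  base <- mean(mm[seq_len(nInitial)])
  if (base == 0) stop("initial frames contain no above-threshold pixels")
  data.frame(
    frame = seq_along(frames), maskMean = mm,
    normalizedArea = mm / base
  )
}
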