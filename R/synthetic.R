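## Synthetic acquisition: every generator returns pixels plus machine-
## readable ground truth, and draws all randomness from the caller's RNG
## stream (seed it once per study).

#' Construct a scene specification
#'
#' @param fov field of view in micrometres (square image).
#' @param pixelSize micrometres per pixel.
#' @param psfSigma Gaussian PSF sigma in nanometres at acquisition scale
#'   (default 100, the expansion-microscopy-resolved regime).
#' @param noise "none", "gaussian" or "poisson".
#' @param noiseSigma Gaussian noise sigma as a fraction of the dynamic
#'   range (default 0.02).
#' @param poissonScale expected photons at unit intensity (default 50).
#' @param expansion expansion factor; specimen-scale distances are
#'   multiplied by it before rendering (default 1).
#' @param seed stored for provenance; generators use the current RNG
#'   stream.
#' @return a [SceneSpec-class].
#' @export
sceneSpec <- function(fov = 20, pixelSize = 0.08, psfSigma = 100,
                      noise = "gaussian", noiseSigma = 0.02,
                      poissonScale = 50, expansion = 1, seed = 1L) {
  new("SceneSpec",
    fov = fov, pixelSize = pixelSize, psfSigma = psfSigma, noise = noise,
    noiseSigma = noiseSigma, poissonScale = poissonScale,
    expansion = expansion, seed = as.integer(seed)
  )
}

## render point emitters (acquisition-scale nm) into the pixel grid
renderEmitters <- function(ptsNm, spec, amplitude = 1) {
  pxNm <- spec@pixelSize * 1000
  n <- round(spec@fov / spec@pixelSize)
  img <- matrix(0, n, n)
  if (nrow(ptsNm)) {
    sig <- max(spec@psfSigma, pxNm / 4) / pxNm # in pixels
    halo <- ceiling(4 * sig)
    u <- ptsNm[, 1] / pxNm + 0.5 # column coordinate, pixel centres at integers
    v <- ptsNm[, 2] / pxNm + 0.5
    for (i in seq_len(nrow(ptsNm))) {
      c0 <- round(u[i])
      r0 <- round(v[i])
      cs <- max(1, c0 - halo):min(n, c0 + halo)
      rs <- max(1, r0 - halo):min(n, r0 + halo)
      if (!length(cs) || !length(rs)) next
      g <- outer(
        exp(-(rs - v[i])^2 / (2 * sig^2)),
        exp(-(cs - u[i])^2 / (2 * sig^2))
      )
      img[rs, cs] <- img[rs, cs] + amplitude * g
    }
  }
  img
}

noisyImage <- function(img, spec) {
  if (spec@noise == "gaussian" && spec@noiseSigma > 0) {
    rng <- diff(range(img))
    img <- img + matrix(
      stats::rnorm(length(img), 0, spec@noiseSigma * max(rng, 1e-12)),
      nrow(img)
    )
    img <- pmax(img, 0)
  } else if (spec@noise == "poisson") {
    img <- matrix(
      stats::rpois(length(img), pmax(img, 0) * spec@poissonScale) /
        spec@poissonScale,
      nrow(img)
    )
  }
  img
}

#' Render a network as a synthetic labeled-epitope image
#'
#' Places one fluorescent epitope per attached spectrin edge (at the
#' midpoint, mimicking a C-terminal label, or at both ends), scales
#' specimen coordinates by the expansion factor, convolves with the
#' Gaussian PSF and adds noise. The scene is centred in the field of view.
#'
#' @param net a [Network-class].
#' @param spec a [SceneSpec-class].
#' @param label "midpoint" (default) or "ends".
#' @return list with `image` ([CortexImage-class]) and `truth` (data.frame
#'   of emitter positions: x, y in acquisition-scale micrometres).
#' @export
renderNetwork <- function(net, spec = sceneSpec(expansion = 4),
                          label = c("midpoint", "ends")) {
  label <- match.arg(label)
  ed <- net@edges
  live <- ed$state == "attached" & ed$kind == "spectrin"
  if (any(live)) {
    ep <- edgeEndpointPositions(net)
    if (label == "midpoint") {
      pts <- cbind(
        (ep$p1[live, 1] + ep$p2[live, 1]) / 2,
        (ep$p1[live, 2] + ep$p2[live, 2]) / 2
      )
    } else {
      pts <- rbind(ep$p1[live, , drop = FALSE], ep$p2[live, , drop = FALSE])
      pts <- unique(pts)
    }
    pts <- pts * spec@expansion
    ## centre in the field of view
    fovNm <- spec@fov * 1000
    pts[, 1] <- pts[, 1] - mean(range(pts[, 1])) + fovNm / 2
    pts[, 2] <- pts[, 2] - mean(range(pts[, 2])) + fovNm / 2
  } else {
    pts <- matrix(numeric(0), 0, 2)
  }
  img <- noisyImage(renderEmitters(pts, spec), spec)
  list(
    image = cortexImage(img, pixelSize = spec@pixelSize),
    truth = data.frame(x = pts[, 1] / 1000, y = pts[, 2] / 1000)
  )
}

#' Generate a periodic band array
#'
#' Emulates an expansion-microscopy line-scan target: `nPeaks` parallel
#' bands at a true specimen-scale spacing, rendered at the scene's
#' expansion factor and PSF, with noise. The band axis runs along y so the
#' periodicity is read along x.
#'
#' @param spacingNm true specimen-scale spacing (nm).
#' @param nPeaks number of bands.
#' @param spec a [SceneSpec-class].
#' @return list with `image`, `truth` (data.frame: peak x positions in
#'   acquisition-scale nm, plus the acquisition-scale spacing
#'   `spacingAcqNm`).
#' @export
genPeriodicArray <- function(spacingNm = 200, nPeaks = 10,
                             spec = sceneSpec(expansion = 4, noise = "poisson")) {
  if (spacingNm <= 0) stop("spacing must be > 0")
  pxNm <- spec@pixelSize * 1000
  n <- round(spec@fov / spec@pixelSize)
  spacingAcq <- spacingNm * spec@expansion
  total <- (nPeaks - 1) * spacingAcq
  x0 <- (spec@fov * 1000 - total) / 2
  centers <- x0 + (seq_len(nPeaks) - 1) * spacingAcq
  sig <- max(spec@psfSigma, pxNm / 4)
  xcoord <- (seq_len(n) - 0.5) * pxNm
  prof <- rowSums(vapply(
    centers, function(cc) exp(-(xcoord - cc)^2 / (2 * sig^2)), numeric(n)
  ))
  img <- matrix(prof, nrow = n, ncol = n, byrow = TRUE)
  img <- noisyImage(img, spec)
  list(
    image = cortexImage(img, pixelSize = spec@pixelSize),
    truth = data.frame(xNm = centers, spacingAcqNm = spacingAcq)
  )
}

#' Generate a log-normally distributed intensity field
#'
#' Pixels are i.i.d. log-normal with log-mean `mu` and log-sd `sigma`,
#' emulating the per-square-micrometre intensity statistics of a diffuse
#' meshwork. A full cell mask is attached.
#'
#' @param mu,sigma log-normal parameters.
#' @param spec a [SceneSpec-class] (only fov/pixelSize used).
#' @param size optional explicit image side in pixels (overrides fov).
#' @return a [CortexImage-class] with mask.
#' @export
genLognormalField <- function(mu = 4, sigma = 0.5, spec = sceneSpec(),
                              size = NULL) {
  n <- if (is.null(size)) round(spec@fov / spec@pixelSize) else size
  x <- matrix(stats::rlnorm(n * n, mu, sigma), n, n)
  cortexImage(x, pixelSize = spec@pixelSize, mask = matrix(TRUE, n, n))
}

#' Generate a donor/FRET/acceptor triple with a prescribed tension map
#'
#' Builds a channel pair whose blurred donor/FRET ratio increases
#' monotonically with the prescribed tension (values in 0..1): the donor
#' signal rises with tension while the FRET signal falls (higher tension =
#' lower energy transfer = higher inverted ratio). The acceptor channel is
#' either independent of tension or anti-correlated with it (the clustered
#' scenario: dense spectrin at low tension).
#'
#' @param tensionMap matrix with values in 0..1.
#' @param spec a [SceneSpec-class]; its Gaussian noise fraction is applied
#'   per channel.
#' @param acceptorMode "independent" or "anticorrelated".
#' @param base mean channel intensity (default 100).
#' @return list of [CortexImage-class] `donor`, `fret`, `acceptor`, plus
#'   `mask` and the `tension` truth.
#' @export
genFretPair <- function(tensionMap, spec = sceneSpec(),
                        acceptorMode = c("independent", "anticorrelated"),
                        base = 100) {
  acceptorMode <- match.arg(acceptorMode)
  if (any(tensionMap < 0 | tensionMap > 1)) stop("tension map must lie in [0, 1]")
  n1 <- nrow(tensionMap)
  n2 <- ncol(tensionMap)
  nz <- function() {
    if (spec@noise == "gaussian" && spec@noiseSigma > 0) {
      matrix(stats::rnorm(n1 * n2, 0, spec@noiseSigma * base), n1, n2)
    } else {
      matrix(0, n1, n2)
    }
  }
  donor <- base * (0.5 + tensionMap) + nz()
  fret <- base * (1.5 - tensionMap) + nz()
  acc <- switch(acceptorMode,
    independent = matrix(base, n1, n2) + nz(),
    anticorrelated = base * (0.4 + 1.2 * (1 - tensionMap)) + nz()
  )
  mask <- matrix(TRUE, n1, n2)
  list(
    donor = cortexImage(pmax(donor, 0), pixelSize = spec@pixelSize),
    fret = cortexImage(pmax(fret, 1e-6), pixelSize = spec@pixelSize),
    acceptor = cortexImage(pmax(acc, 0),
      pixelSize = spec@pixelSize, bitDepth = 16
    ),
    mask = mask, tension = tensionMap
  )
}

#' Generate a FRAP recovery curve
#'
#' Forward model of the one-phase association
#' `I(t) = I0 + Imax * (1 - exp(-k t))` with optional Gaussian noise.
#'
#' @param I0 post-bleach intensity at t = 0.
#' @param Imax recovery amplitude.
#' @param k association rate (1/s).
#' @param noiseSigma Gaussian noise sd.
#' @param times sampling times (s).
#' @return data.frame with columns `time`, `intensity`; true parameters in
#'   attributes `I0`, `Imax`, `k`.
#' @export
genFrapCurve <- function(I0 = 0.2, Imax = 0.6, k = 0.05, noiseSigma = 0,
                         times = seq(0, 300, by = 3)) {
  I <- I0 + Imax * (1 - exp(-k * times))
  if (noiseSigma > 0) I <- I + stats::rnorm(length(times), 0, noiseSigma)
  out <- data.frame(time = times, intensity = I)
  attr(out, "I0") <- I0
  attr(out, "Imax") <- Imax
  attr(out, "k") <- k
  out
}

#' Generate a dissolving/growing cluster time lapse
#'
#' One bright disk on a dim noisy background; the disk area follows
#' `areaSchedule` (relative to the first frame). Designed so that a fixed
#' threshold derived from the initial frames tracks the disk area.
#'
#' @param areaSchedule vector of relative areas (first entry should be 1).
#' @param spec a [SceneSpec-class].
#' @param diskFraction fraction of the image covered by the initial disk
#'   (default 0.03, below the segmentation cutoff).
#' @param diskIntensity,bgIntensity intensities of disk and background.
#' @return list with `stack` (list of matrices) and `truth`
#'   (the schedule).
#' @export
genClusterTimelapse <- function(areaSchedule = seq(1, 0.5, length.out = 10),
                                spec = sceneSpec(noiseSigma = 0.01),
                                diskFraction = 0.03, diskIntensity = 1,
                                bgIntensity = 0.1) {
  n <- round(spec@fov / spec@pixelSize)
  A0 <- diskFraction * n * n
  r0 <- sqrt(A0 / pi)
  cx <- n / 2
  cy <- n / 2
  d2 <- outer(
    (seq_len(n) - cy)^2, (seq_len(n) - cx)^2, `+`
  )
  stack <- lapply(areaSchedule, function(a) {
    r <- r0 * sqrt(max(a, 0))
    img <- matrix(bgIntensity, n, n)
    img[d2 <= r^2] <- diskIntensity
    if (spec@noiseSigma > 0) {
      img <- img + matrix(stats::rnorm(n * n, 0, spec@noiseSigma), n, n)
    }
    pmax(img, 0)
  })
  list(stack = stack, truth = areaSchedule)
}
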