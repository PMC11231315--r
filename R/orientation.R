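#' Structure-tensor orientation and coherency analysis
#'
#' Computes Gaussian-derivative gradients (the image is convolved with a
#' Gaussian of `gradientSigma` pixels before central differencing), forms
#' the structure tensor by Gaussian-window averaging of the gradient outer
#' products, and derives the local orientation of image structures
#' (perpendicular to the dominant gradient direction) and the coherency
#' `(lmax - lmin)/(lmax + lmin)`. Angles are reported in degrees in
#' (-90, 90], measured from the +x (column) axis towards +y (row) axis;
#' with the conventional display (rows rendered downwards) this is the
#' clockwise angle from horizontal.
#'
#' @param img a [CortexImage-class] (background-subtracted upstream if
#'   needed).
#' @param gradientSigma Gaussian window of the structure tensor in pixels
#'   (default 5).
#' @param derivSigma scale of the derivative-of-Gaussian gradient filter in
#'   pixels (default 0.5; small so that fine structures keep their contrast
#'   and neighbouring gradient samples stay nearly independent).
#' @return an [OrientationMap-class]. Pixels with no gradient energy have
#'   NA orientation and coherency 0.
#' @export
orientationCoherency <- function(img, gradientSigma = 5, derivSigma = 0.5) {
  x <- img@data
  xs <- EBImage::gblur(x, sigma = derivSigma)
  nr <- nrow(xs)
  nc <- ncol(xs)
  ## central differences; gy along rows (y), gx along columns (x)
  gy <- (xs[c(2:nr, nr), ] - xs[c(1, 1:(nr - 1)), ]) / 2
  gx <- (xs[, c(2:nc, nc)] - xs[, c(1, 1:(nc - 1))]) / 2
  Jxx <- EBImage::gblur(gx * gx, sigma = gradientSigma)
  Jyy <- EBImage::gblur(gy * gy, sigma = gradientSigma)
  Jxy <- EBImage::gblur(gx * gy, sigma = gradientSigma)
  tensorOrientation <- function(jxx, jyy, jxy) {
    ## dominant gradient direction, then +90 deg for the structure
    phi <- 0.5 * atan2(2 * jxy, jxx - jyy)
    th <- phi * 180 / pi + 90
    ifelse(th > 90, th - 180, th)
  }
  energy <- Jxx + Jyy
  ori <- tensorOrientation(Jxx, Jyy, Jxy)
  coh <- ifelse(energy > .Machine$double.eps,
    sqrt((Jxx - Jyy)^2 + 4 * Jxy^2) / energy, 0
  )
  ori[energy <= .Machine$double.eps] <- NA_real_
  dom <- tensorOrientation(sum(Jxx), sum(Jyy), sum(Jxy))
  new("OrientationMap",
    orientation = ori, coherency = pmin(coh, 1),
    dominantDirection = dom
  )
}

#' Orientation histogram aligned to a reference channel
#'
#' Histograms the per-pixel orientations of `map`, shifted so that the
#' dominant direction of the reference channel (for the experiments the
#' actin channel) sits at 0 degrees.
#'
#' @param map an [OrientationMap-class].
#' @param reference either an [OrientationMap-class] whose dominant
#'   direction defines 0 degrees, or a numeric angle in degrees; NULL uses
#'   no shift.
#' @param binWidth histogram bin width in degrees (default 2).
#' @param weightByCoherency weight each pixel by its coherency (default
#'   TRUE).
#' @return data.frame with columns `angle` (bin midpoints, degrees relative
#'   to the reference) and `freq` (relative frequencies).
#' @export
orientationHistogram <- function(map, reference = NULL, binWidth = 2,
                                 weightByCoherency = TRUE) {
  ref <- if (is.null(reference)) {
    0
  } else if (is(reference, "OrientationMap")) {
    reference@dominantDirection
  } else {
    as.numeric(reference)
  }
  ang <- map@orientation - ref
  ang <- ((ang + 90) %% 180) - 90
  ok <- !is.na(ang)
  w <- if (weightByCoherency) map@coherency[ok] else rep(1, sum(ok))
  br <- seq(-90, 90, by = binWidth)
  bin <- cut(ang[ok], breaks = br, include.lowest = TRUE)
  tot <- tapply(w, bin, sum, default = 0)
  data.frame(
    angle = (br[-1] + br[-length(br)]) / 2,
    freq = as.numeric(tot) / sum(w)
  )
}
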