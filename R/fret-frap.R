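## Tension mapping by sensitized-emission FRET ratio, and FRAP recovery
## fitting.

#' Inverted FRET ratio map
#'
#' Both channels are Gaussian-blurred (sigma `blurSigmaUm`, default 1
#' micrometre, which sets the spatial resolution of the ratio), the donor
#' is divided by the FRET channel inside the cell mask, and the floating
#' ratio is min-max normalized to 0..1; pixels outside the mask are NaN.
#' A higher inverted ratio reflects a higher tensional state. When an
#' acceptor channel is supplied a per-pixel table (invFRET, acceptor) is
#' returned, excluding saturated acceptor pixels (at the top of the
#' acceptor's bit range).
#'
#' @param donor,fret registered equal-shape [CortexImage-class] channels.
#' @param mask logical matrix (cell mask); defaults to the donor's mask, or
#'   everything.
#' @param acceptor optional acceptor-channel [CortexImage-class].
#' @param blurSigmaUm Gaussian blur sigma in micrometres (default 1).
#' @return list with `invFret` ([CortexImage-class], NaN outside the mask),
#'   `cv` (coefficient of variation of the normalized ratio inside the
#'   mask), `pixelTable` (data.frame invFret/acceptor, or NULL), `nFlagged`
#'   (zero-denominator pixels inside the mask, excluded), and `degenerate`
#'   (TRUE when the ratio was constant and normalization collapsed to 0).
#' @export
invertedFret <- function(donor, fret, mask = NULL, acceptor = NULL,
                         blurSigmaUm = 1) {
  if (!identical(dim(donor@data), dim(fret@data))) {
    stop("donor and FRET images differ in shape")
  }
  if (is.null(mask)) mask <- cellMask(donor)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(donor@data), ncol(donor@data))
  sigmaPx <- blurSigmaUm / donor@pixelSize
  d <- safeGblur(donor@data, sigmaPx)
  f <- safeGblur(fret@data, sigmaPx)
  ratio <- matrix(NaN, nrow(d), ncol(d))
  ok <- mask & f > 0
  nFlagged <- sum(mask & f <= 0)
  ratio[ok] <- d[ok] / f[ok]
  v <- ratio[ok]
  degenerate <- FALSE
  if (!length(v)) stop("no valid pixels inside the mask")
  if (diff(range(v)) == 0) {
    warning("constant donor/FRET ratio: normalization degenerate, reporting 0")
    ratio[ok] <- 0
    degenerate <- TRUE
  } else {
    ratio[ok] <- (v - min(v)) / diff(range(v))
  }
  vn <- ratio[ok]
  cv <- if (mean(vn) > 0) stats::sd(vn) / mean(vn) else NA_real_
  tab <- NULL
  if (!is.null(acceptor)) {
    satLevel <- if (is.na(acceptor@bitDepth)) Inf else 2^acceptor@bitDepth - 1
    keep <- ok & acceptor@data < satLevel
    tab <- data.frame(
      invFret = ratio[keep], acceptor = acceptor@data[keep]
    )
  }
  list(
    invFret = cortexImage(ratio, pixelSize = donor@pixelSize),
    cv = cv, pixelTable = tab, nFlagged = nFlagged, degenerate = degenerate
  )
}

#' Fit a FRAP recovery curve (one-phase association)
#'
#' Least-squares fit of `I(t) = I0 + Imax * (1 - exp(-k t))` to a
#' post-bleach recovery curve (t = 0 at the bleach). The half-time is
#' `log(2)/k`; with intensities normalized to the pre-bleach level, the
#' plateau `I0 + Imax` is reported as the mobile fraction.
#'
#' @param times time points in seconds (t = 0 at bleach).
#' @param intensities normalized intensities (same length).
#' @return a [FrapFit-class].
#' @examples
#' t <- seq(0, 120, by = 3)
#' I <- 0.2 + 0.6 * (1 - exp(-0.05 * t))
#' frapFit(t, I)
#' @export
frapFit <- function(times, intensities) {
  if (length(times) != length(intensities)) {
    stop("times and intensities differ in length")
  }
  keep <- is.finite(times) & is.finite(intensities)
  times <- times[keep]
  intensities <- intensities[keep]
  if (length(times) < 5) stop("need at least 5 post-bleach points")
  I0s <- intensities[which.min(times)]
  plateau <- mean(intensities[times >= stats::quantile(times, 0.8)])
  Imaxs <- max(plateau - I0s, 1e-3)
  ## initial rate: time at half recovery
  half <- I0s + Imaxs / 2
  thalf <- times[which(intensities >= half)[1]]
  ks <- if (is.na(thalf) || thalf <= 0) 1 / max(times) else log(2) / thalf
  df <- data.frame(t = times, I = intensities)
  fit <- tryCatch(
    minpack.lm::nlsLM(I ~ I0 + Imax * (1 - exp(-k * t)),
      data = df, start = list(I0 = I0s, Imax = Imaxs, k = ks),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    stop(sprintf(
      "FRAP fit did not converge: %s (start I0=%.3g Imax=%.3g k=%.3g)",
      conditionMessage(fit), I0s, Imaxs, ks
    ))
  }
  cf <- coef(fit)
  if (cf[["k"]] <= 0) {
    stop(sprintf(
      "FRAP fit did not converge to a positive rate (k = %.3g); residual sd %.3g",
      cf[["k"]], stats::sd(stats::residuals(fit))
    ))
  }
  new("FrapFit",
    times = times, intensities = intensities,
    I0 = unname(cf["I0"]), Imax = unname(cf["Imax"]), k = unname(cf["k"]),
    halfTime = log(2) / unname(cf["k"]),
    mobileFraction = unname(cf["I0"] + cf["Imax"]),
    converged = TRUE
  )
}
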