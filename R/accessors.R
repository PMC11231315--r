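#' Accessors for Network objects
#'
#' @param object a [Network-class], [Trajectory-class] or [CortexImage-class].
#' @param ... unused.
#' @return `nodes`, `edges` and `triangles` return the corresponding
#'   data.frames; `modelParamsOf` the [ModelParams-class]; `simTime` the
#'   current simulation time in seconds.
#' @name Network-accessors
NULL

#' @rdname Network-accessors
#' @export
setMethod("nodes", "Network", function(object, ...) object@nodes)

#' @rdname Network-accessors
#' @export
setMethod("edges", "Network", function(object, ...) object@edges)

#' @rdname Network-accessors
#' @export
setMethod("triangles", "Network", function(object, ...) object@triangles)

#' @rdname Network-accessors
#' @export
setMethod("modelParamsOf", "Network", function(object) object@params)

#' @rdname Network-accessors
#' @export
setMethod("simTime", "Network", function(object) object@time)

#' Accessors for Trajectory objects
#'
#' @param object a [Trajectory-class].
#' @return `events` returns the event log data.frame, `finalNetwork` the
#'   final [Network-class], `snapshots` the list of snapshot networks.
#' @name Trajectory-accessors
NULL

#' @rdname Trajectory-accessors
#' @export
setMethod("events", "Trajectory", function(object) object@events)

#' @rdname Trajectory-accessors
#' @export
setMethod("finalNetwork", "Trajectory", function(object) object@final)

#' @rdname Trajectory-accessors
#' @export
setMethod("snapshots", "Trajectory", function(object) object@snapshots)

#' Accessors for CortexImage objects
#'
#' @param object a [CortexImage-class].
#' @param value logical matrix of the same shape as the image.
#' @name CortexImage-accessors
NULL

#' @rdname CortexImage-accessors
#' @export
setMethod("pixelData", "CortexImage", function(object) object@data)

#' @rdname CortexImage-accessors
#' @export
setMethod("pixelSize", "CortexImage", function(object) object@pixelSize)

#' @rdname CortexImage-accessors
#' @export
setMethod("cellMask", "CortexImage", function(object) {
  if (nrow(object@mask)) object@mask else NULL
})

#' @rdname CortexImage-accessors
#' @export
setMethod("cellMask<-", "CortexImage", function(object, value) {
  object@mask <- value
  validObject(object)
  object
})

#' Construct a CortexImage
#'
#' @param data numeric matrix of intensities.
#' @param pixelSize micrometres per pixel.
#' @param bitDepth nominal bit depth (8, 16) or NA for float data.
#' @param mask optional logical matrix marking the cell.
#' @return a [CortexImage-class].
#' @examples
#' img <- cortexImage(matrix(runif(64), 8), pixelSize = 0.1)
#' pixelSize(img)
#' @export
cortexImage <- function(data, pixelSize = 0.1, bitDepth = NA_real_,
                        mask = NULL) {
  storage.mode(data) <- "double"
  new("CortexImage",
    data = data, pixelSize = pixelSize, bitDepth = bitDepth,
    mask = if (is.null(mask)) matrix(logical(0), 0, 0) else mask
  )
}

setMethod("show", "Network", function(object) {
  nd <- object@nodes
  ed <- object@edges
  att <- ed$state == "attached"
  cat(sprintf(
    "Network at t = %g s: %d nodes, %d edges (%d attached), %d triangles\n",
    object@time, nrow(nd), nrow(ed), sum(att), nrow(object@triangles)
  ))
  if (nrow(nd)) {
    cat("  nodes: ", paste(sprintf(
      "%s=%d", names(table(nd$kind)),
      as.integer(table(nd$kind))
    ), collapse = " "), "\n")
  }
  if (nrow(ed)) {
    tb <- table(ed$kind[att])
    cat("  attached edges: ", paste(sprintf(
      "%s=%d", names(tb),
      as.integer(tb)
    ), collapse = " "), "\n")
  }
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf(
    "Trajectory: %d snapshots over %g s, %d events\n",
    length(object@snapshots),
    if (length(object@snapshotTimes)) max(object@snapshotTimes) else 0,
    nrow(object@events)
  ))
  if (nrow(object@events)) {
    tb <- table(object@events$event)
    cat("  ", paste(sprintf("%s=%d", names(tb), as.integer(tb)),
      collapse = " "
    ), "\n")
  }
})

setMethod("show", "CortexImage", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "CortexImage %dx%d px, %.3g um/px (%.3g x %.3g um)%s%s\n",
    d[1], d[2], object@pixelSize, d[1] * object@pixelSize,
    d[2] * object@pixelSize,
    if (is.na(object@bitDepth)) "" else sprintf(", %d-bit", object@bitDepth),
    if (nrow(object@mask)) ", with mask" else ""
  ))
})

setMethod("show", "FrapFit", function(object) {
  cat(sprintf(
    "FrapFit: I0=%.4g Imax=%.4g k=%.4g /s (half-time %.4g s, mobile fraction %.4g)%s\n",
    object@I0, object@Imax, object@k, object@halfTime,
    object@mobileFraction,
    if (object@converged) "" else " [not converged]"
  ))
})

setMethod("show", "OrientationMap", function(object) {
  cat(sprintf(
    "OrientationMap %dx%d px, dominant direction %.2f deg, mean coherency %.3f\n",
    nrow(object@orientation), ncol(object@orientation),
    object@dominantDirection, mean(object@coherency, na.rm = TRUE)
  ))
})
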