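## Generics for accessors and the main verbs of the package.

#' @rdname Network-accessors
#' @export
setGeneric("nodes", function(object, ...) standardGeneric("nodes"))

#' @rdname Network-accessors
#' @export
setGeneric("edges", function(object, ...) standardGeneric("edges"))

#' @rdname Network-accessors
#' @export
setGeneric("triangles", function(object, ...) standardGeneric("triangles"))

#' @rdname Network-accessors
#' @export
setGeneric("modelParamsOf", function(object) standardGeneric("modelParamsOf"))

#' @rdname Network-accessors
#' @export
setGeneric("simTime", function(object) standardGeneric("simTime"))

#' @rdname totalEnergy
#' @export
setGeneric("totalEnergy", function(net) standardGeneric("totalEnergy"))

#' @rdname netForce
#' @export
setGeneric("netForce", function(net) standardGeneric("netForce"))

#' @rdname Trajectory-accessors
#' @export
setGeneric("events", function(object) standardGeneric("events"))

#' @rdname Trajectory-accessors
#' @export
setGeneric("finalNetwork", function(object) standardGeneric("finalNetwork"))

#' @rdname Trajectory-accessors
#' @export
setGeneric("snapshots", function(object) standardGeneric("snapshots"))

#' @rdname CortexImage-accessors
#' @export
setGeneric("pixelData", function(object) standardGeneric("pixelData"))

#' @rdname CortexImage-accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname CortexImage-accessors
#' @export
setGeneric("cellMask", function(object) standardGeneric("cellMask"))

#' @rdname CortexImage-accessors
#' @export
setGeneric("cellMask<-", function(object, value) standardGeneric("cellMask<-"))
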