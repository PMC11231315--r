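## Serialization, configuration and run drivers.

NETWORK_SCHEMA <- "spectrinmesh-network/1"

#' Serialize a network to JSON
#'
#' Writes the documented JSON schema (params, time, nodes, edges; the
#' triangle table is reconstructed from the full spectrin edge list on
#' load). The serialization is canonical: serialize - parse - serialize
#' yields identical bytes.
#'
#' @param net a [Network-class].
#' @param path file path; when NULL the JSON string is returned.
#' @return `path` (invisibly) or the JSON string.
#' @export
writeNetworkJSON <- function(net, path = NULL) {
  obj <- list(
    schema = NETWORK_SCHEMA,
    params = paramsToList(net@params),
    time = net@time,
    nodes = net@nodes,
    edges = net@edges
  )
  js <- jsonlite::toJSON(obj,
    dataframe = "columns", digits = NA, auto_unbox = TRUE, na = "null",
    pretty = TRUE
  )
  if (is.null(path)) {
    return(as.character(js))
  }
  writeLines(js, path)
  invisible(path)
}

#' Parse a network from JSON
#'
#' @param path file path, or a JSON string.
#' @return a [Network-class].
#' @export
readNetworkJSON <- function(path) {
  obj <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE),
    error = function(e) {
      stop("network JSON parse error: ", conditionMessage(e))
    }
  )
  if (!identical(obj$schema, NETWORK_SCHEMA)) {
    stop("unrecognised network schema: ", format(obj$schema))
  }
  params <- paramsFromList(obj$params)
  nd <- as.data.frame(obj$nodes, stringsAsFactors = FALSE)
  ed <- as.data.frame(obj$edges, stringsAsFactors = FALSE)
  for (cl in c("id", "n1", "n2", "t1", "t2")) {
    if (cl %in% names(ed)) ed[[cl]] <- as.integer(ed[[cl]])
  }
  nd$id <- as.integer(nd$id)
  ed$tRemove <- as.numeric(ed$tRemove)
  ed$tAttach <- as.numeric(ed$tAttach)
  tr <- enumerateTriangles(nd, ed[ed$kind == "spectrin", , drop = FALSE])
  new("Network",
    nodes = nd, edges = ed, triangles = tr, params = params,
    time = as.numeric(obj$time)
  )
}

#' Write / read a network as a flat CSV set
#'
#' `nodes.csv` and `edges.csv` hold the graph; `params.csv` holds the
#' parameter set and simulation time as key/value rows. The triangle table
#' is reconstructed on load. The round trip is lossless (structural
#' equality).
#'
#' @param net a [Network-class].
#' @param dir directory (created if needed).
#' @return the directory (invisibly) / a [Network-class].
#' @export
writeNetworkCSV <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(net@nodes, file.path(dir, "nodes.csv"), row.names = FALSE)
  utils::write.csv(net@edges, file.path(dir, "edges.csv"), row.names = FALSE)
  pl <- paramsToList(net@params)
  pl$time <- net@time
  utils::write.csv(
    data.frame(key = names(pl), value = vapply(pl, function(v) {
      format(v, digits = 17)
    }, character(1))),
    file.path(dir, "params.csv"),
    row.names = FALSE
  )
  invisible(dir)
}

#' @rdname writeNetworkCSV
#' @export
readNetworkCSV <- function(dir) {
  nd <- utils::read.csv(file.path(dir, "nodes.csv"), stringsAsFactors = FALSE)
  ed <- utils::read.csv(file.path(dir, "edges.csv"), stringsAsFactors = FALSE)
  pv <- utils::read.csv(file.path(dir, "params.csv"), stringsAsFactors = FALSE)
  kv <- stats::setNames(as.list(as.numeric(pv$value)), pv$key)
  tm <- kv$time
  kv$time <- NULL
  params <- paramsFromList(kv)
  nd$id <- as.integer(nd$id)
  for (cl in c("id", "n1", "n2", "t1", "t2")) ed[[cl]] <- as.integer(ed[[cl]])
  ed$tAttach <- as.numeric(ed$tAttach)
  ed$tRemove <- as.numeric(ed$tRemove)
  tr <- enumerateTriangles(nd, ed[ed$kind == "spectrin", , drop = FALSE])
  new("Network",
    nodes = nd, edges = ed, triangles = tr, params = params, time = tm
  )
}

#' Round-trip a serialized network
#'
#' Loads a network from either a JSON file or a CSV run directory.
#'
#' @param path `.json` file or directory containing nodes/edges/params CSVs.
#' @return a [Network-class].
#' @export
roundTripNetwork <- function(path) {
  if (dir.exists(path)) readNetworkCSV(path) else readNetworkJSON(path)
}

## ---- run configuration ----

CONFIG_KEYS <- list(
  top = c("scenario", "seed", "params", "geometry", "run"),
  geometry = c(
    "nRows", "nCols", "nSegments", "faOffset", "standoff", "sfOffset",
    "nRodsInit", "perturbSigma", "prescribedFA"
  ),
  run = c(
    "Ttot", "detachment", "detachStretched", "myosinTurnover",
    "snapshotEvery", "equilibrate", "tol"
  )
)

#' Read and validate a run configuration
#'
#' The configuration is declarative YAML with blocks `scenario`, `seed`,
#' `params` (the [modelParams()] fields; `dt` must be given explicitly so
#' that a run is reproducible from its config alone), `geometry`
#' (lattice/fiber layout) and `run` (duration and switches). Unknown keys
#' are rejected with a field-level message; defaults for everything left
#' unset are filled in and echoed, so the returned object is the complete
#' effective configuration.
#'
#' @param path YAML file path, or a list already in config shape.
#' @return a validated config list with all defaults resolved.
#' @export
readRunConfig <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), CONFIG_KEYS$top)
  if (length(unknown)) {
    stop("config error: unknown top-level field(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(cfg$scenario)) stop("config error: required field 'scenario' missing")
  scens <- c(
    "pure_lattice", "lattice_plus_fa_cables",
    "lattice_plus_stress_fibers", "full_with_myosin"
  )
  if (!cfg$scenario %in% scens) {
    stop("config error: scenario must be one of ", paste(scens, collapse = ", "))
  }
  if (is.null(cfg$params) || is.null(cfg$params$dt)) {
    stop("config error: required field 'dt' missing from params")
  }
  for (blk in c("geometry", "run")) {
    unknown <- setdiff(names(cfg[[blk]]), CONFIG_KEYS[[blk]])
    if (length(unknown)) {
      stop(sprintf(
        "config error: unknown %s field(s): %s", blk,
        paste(unknown, collapse = ", ")
      ))
    }
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg$seed <- as.integer(cfg$seed)
  params <- paramsFromList(cfg$params) # validates
  cfg$params <- paramsToList(params)
  geoDefaults <- list(
    nRows = 10, nCols = 20, nSegments = 8, faOffset = 50, standoff = 500,
    sfOffset = NULL, nRodsInit = 5, perturbSigma = 0, prescribedFA = NULL
  )
  cfg$geometry <- utils::modifyList(geoDefaults, as.list(cfg$geometry))
  runDefaults <- list(
    Ttot = params@Ttot, detachment = TRUE, detachStretched = FALSE,
    myosinTurnover = TRUE, snapshotEvery = 60, equilibrate = FALSE,
    tol = 1e-3
  )
  cfg$run <- utils::modifyList(runDefaults, as.list(cfg$run))
  cfg
}

#' Simulate a configured scenario
#'
#' Seeds the RNG from the config, builds the scenario network and runs the
#' simulation; the complete effective configuration is echoed into the
#' trajectory.
#'
#' @param config path to a YAML config or a config list
#'   (see [readRunConfig()]).
#' @return a [Trajectory-class].
#' @export
simulateScenario <- function(config) {
  cfg <- readRunConfig(config)
  set.seed(cfg$seed)
  params <- paramsFromList(cfg$params)
  g <- cfg$geometry
  net <- buildScenario(cfg$scenario,
    params = params, nRows = g$nRows, nCols = g$nCols,
    nSegments = g$nSegments, faOffset = g$faOffset, standoff = g$standoff,
    sfOffset = g$sfOffset, prescribedFA = g$prescribedFA,
    nRodsInit = g$nRodsInit, perturbSigma = g$perturbSigma
  )
  r <- cfg$run
  tr <- runSimulation(net,
    Ttot = r$Ttot, detachment = r$detachment,
    detachStretched = r$detachStretched, myosinTurnover = r$myosinTurnover,
    snapshotEvery = r$snapshotEvery, equilibrate = r$equilibrate, tol = r$tol
  )
  tr@config <- cfg
  tr
}

#' Run a configured simulation and write a run directory
#'
#' Produces a reproducible run directory: the effective configuration and
#' package version (`run_log.yaml`), the event log (`events.csv`), initial
#' and final network snapshots (JSON), and the standard observables as
#' CSVs. The artifacts are a pure function of config + seed.
#'
#' @param config YAML path or config list.
#' @param outdir output directory (created).
#' @return the [Trajectory-class], invisibly.
#' @export
simulateRun <- function(config, outdir) {
  tr <- simulateScenario(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- tr@config
  log <- list(
    package = "spectrinmesh",
    version = as.character(utils::packageVersion("spectrinmesh")),
    seed = cfg$seed,
    config = cfg
  )
  yaml::write_yaml(log, file.path(outdir, "run_log.yaml"))
  utils::write.csv(tr@events, file.path(outdir, "events.csv"),
    row.names = FALSE
  )
  writeNetworkJSON(tr@snapshots[[1]], file.path(outdir, "network_initial.json"))
  writeNetworkJSON(tr@final, file.path(outdir, "network_final.json"))
  b <- bundlesPerNode(tr@final)
  utils::write.csv(b$perNode, file.path(outdir, "bundles_per_node.csv"),
    row.names = FALSE
  )
  el <- edgeLengthHistogram(tr@final)
  utils::write.csv(
    data.frame(length = el$lengths),
    file.path(outdir, "edge_lengths.csv"),
    row.names = FALSE
  )
  lt <- myosinLifetimes(tr)
  utils::write.csv(lt, file.path(outdir, "myosin_lifetimes.csv"),
    row.names = FALSE
  )
  utils::write.csv(myosinRodCount(tr), file.path(outdir, "rod_count.csv"),
    row.names = FALSE
  )
  invisible(tr)
}

## ---- TIFF image I/O ----

#' Read / write CortexImage TIFF files
#'
#' Images are written 16-bit by default (intensities scaled by the bit
#' range); binary masks follow the 8-bit 0/255 convention. `readCortexImage`
#' returns intensities on the original integer scale.
#'
#' @param path TIFF file.
#' @param pixelSize micrometres per pixel to attach on read.
#' @param img a [CortexImage-class].
#' @param bitDepth 8 or 16.
#' @param maxValue intensity mapped to the top of the bit range; defaults
#'   to the image maximum.
#' @return a [CortexImage-class] (read) or the path, invisibly (write).
#' @export
readCortexImage <- function(path, pixelSize = 0.1) {
  x <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(x)) == 3) x <- x[, , 1]
  bits <- if (max(x) > 255) 16 else 8
  cortexImage(x, pixelSize = pixelSize, bitDepth = bits)
}

#' @rdname readCortexImage
#' @export
writeCortexImage <- function(img, path, bitDepth = 16, maxValue = NULL) {
  x <- img@data
  if (is.null(maxValue)) maxValue <- max(x, 1e-12)
  xn <- pmin(pmax(x / maxValue, 0), 1)
  tiff::writeTIFF(xn, path, bits.per.sample = bitDepth)
  invisible(path)
}

#' Read / write an image stack as a multi-page TIFF
#'
#' @param stack list of matrices (frames).
#' @rdname readCortexImage
#' @export
writeImageStack <- function(stack, path, bitDepth = 16, maxValue = NULL) {
  if (is.null(maxValue)) maxValue <- max(unlist(lapply(stack, max)), 1e-12)
  frames <- lapply(stack, function(f) pmin(pmax(f / maxValue, 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = bitDepth)
  invisible(path)
}

#' @rdname readCortexImage
#' @export
readImageStack <- function(path) {
  x <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  lapply(x, function(f) if (length(dim(f)) == 3) f[, , 1] else f)
}

#' Plot a network
#'
#' Draws attached edges colored by kind (spectrin green, stress fibers
#' black, cables grey, myosin magenta) and short-actin nodes.
#'
#' @param x a [Network-class].
#' @param y ignored.
#' @param ... passed to `plot.default`.
#' @export
setMethod("plot", signature(x = "Network", y = "missing"), function(x, y, ...) {
  nd <- x@nodes
  ed <- x@edges[x@edges$state == "attached", ]
  ep <- edgeEndpointPositions(x)
  att <- x@edges$state == "attached"
  cols <- c(
    spectrin = "forestgreen", stress_fiber = "black", cable = "grey50",
    myosin_linker = "magenta3", myosin_rod = "magenta"
  )
  graphics::plot(nd$x, nd$y,
    asp = 1, pch = 16, cex = 0.5,
    col = ifelse(nd$kind == "focal_adhesion", "purple4", "grey30"),
    xlab = "x (nm)", ylab = "y (nm)", ...
  )
  graphics::segments(
    ep$p1[att, 1], ep$p1[att, 2], ep$p2[att, 1], ep$p2[att, 2],
    col = cols[x@edges$kind[att]]
  )
  invisible(NULL)
})
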