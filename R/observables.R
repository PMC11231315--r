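## Simulation observables: pure functions of a Network or Trajectory.

#' Spectrin bundles per short-actin filament
#'
#' Counts, for every short-actin node, the number of attached spectrin edges
#' it connects (6 for an interior node of the intact triangular lattice).
#'
#' @param net a [Network-class].
#' @return list with `perNode` (data.frame: node id, x, y, count) and
#'   `histogram` (named integer vector over counts 0..8). The histogram mass
#'   equals the number of short-actin nodes.
#' @export
bundlesPerNode <- function(net) {
  nd <- net@nodes
  ed <- net@edges
  sa <- nd$kind == "short_actin"
  live <- ed$state == "attached" & ed$kind == "spectrin"
  cnt <- tabulate(c(ed$n1[live], ed$n2[live]), nbins = nrow(nd))
  perNode <- data.frame(
    id = nd$id[sa], x = nd$x[sa], y = nd$y[sa], count = cnt[sa]
  )
  h <- table(factor(perNode$count, levels = 0:8))
  list(perNode = perNode, histogram = stats::setNames(as.integer(h), names(h)))
}

#' Histogram of attached spectrin edge lengths
#'
#' @param net a [Network-class].
#' @param binWidth bin width in nm (default 5, resolving the 180 vs 190 nm
#'   scale).
#' @return list with `lengths`, `mids`, `counts`, `mean`, `sd`.
#' @export
edgeLengthHistogram <- function(net, binWidth = 5) {
  ed <- net@edges
  live <- ed$state == "attached" & ed$kind == "spectrin"
  d <- edgeLengthsOf(net)[live]
  if (!length(d)) {
    return(list(
      lengths = numeric(), mids = numeric(), counts = integer(),
      mean = NA_real_, sd = NA_real_
    ))
  }
  lo <- floor(min(d) / binWidth) * binWidth
  hi <- ceiling(max(d) / binWidth) * binWidth
  if (hi <= lo) hi <- lo + binWidth
  br <- seq(lo, hi, by = binWidth)
  h <- hist(d, breaks = br, plot = FALSE)
  list(
    lengths = d, mids = h$mids, counts = h$counts,
    mean = mean(d), sd = stats::sd(d)
  )
}

#' Lifetimes of myosin linkers and rods
#'
#' One row per myosin edge ever present in the run. Myosins still attached
#' at the end of the trajectory are right-censored at the final time
#' (`censored = TRUE`); in the full scenario the stress-fiber linkers
#' typically persist for the whole run while stochastic rods turn over.
#'
#' @param traj a [Trajectory-class].
#' @return data.frame with columns `edge`, `kind` ("linker"/"rod"),
#'   `tAttach`, `tEnd`, `lifetime`, `censored`.
#' @export
myosinLifetimes <- function(traj) {
  net <- traj@final
  ed <- net@edges
  myo <- ed$kind %in% c("myosin_linker", "myosin_rod")
  ed <- ed[myo, ]
  Tend <- net@time
  ev <- traj@events
  rem <- ev[ev$event == "myosin_remove", ]
  if (nrow(rem) && any(!rem$edge %in% ed$id)) {
    stop("log-integrity error: myosin_remove event for unknown myosin edge")
  }
  bad <- ed$state == "removed" & is.na(ed$tRemove)
  if (any(bad)) stop("log-integrity error: removed myosin without removal time")
  cens <- ed$state == "attached"
  tEnd <- ifelse(cens, Tend, ed$tRemove)
  data.frame(
    edge = ed$id,
    kind = ifelse(ed$kind == "myosin_linker", "linker", "rod"),
    tAttach = ed$tAttach, tEnd = tEnd,
    lifetime = tEnd - ed$tAttach, censored = cens,
    stringsAsFactors = FALSE
  )
}

#' Signed spectrin spring force per edge
#'
#' The restorative force `ksS*(d0S - d)` of every spectrin edge: positive
#' for a compressed spring (pushing its nodes apart, the detachment-relevant
#' "expanding" force), negative for a stretched one.
#'
#' @param net a [Network-class].
#' @param attachedOnly drop removed edges (default TRUE).
#' @return data.frame with columns `edge`, `length`, `force`.
#' @export
stressMap <- function(net, attachedOnly = TRUE) {
  ed <- net@edges
  keep <- ed$kind == "spectrin"
  if (attachedOnly) keep <- keep & ed$state == "attached"
  d <- edgeLengthsOf(net)[keep]
  data.frame(
    edge = ed$id[keep], length = d,
    force = ed$ks[keep] * (ed$d0[keep] - d)
  )
}

#' Count attached myosin rods over the snapshots of a trajectory
#'
#' @param traj a [Trajectory-class].
#' @return data.frame with columns `time` and `nRods`.
#' @export
myosinRodCount <- function(traj) {
  data.frame(
    time = traj@snapshotTimes,
    nRods = vapply(traj@snapshots, function(n) {
      sum(n@edges$kind == "myosin_rod" & n@edges$state == "attached")
    }, integer(1))
  )
}
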