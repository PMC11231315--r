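## Overdamped spring/cable dynamics.
##
## Energies: springs store ks*(d - d0)^2/2, cables kc*d^2/2, summed over
## attached edges. Forces are the analytic gradient; a myosin force acting on
## a triangle centroid is split equally among the three triangle nodes (the
## centroid Jacobian is I/3 per node). Nodes move by F/xi * dt (explicit
## Euler); prescribed focal adhesions follow their vertical schedule until tS
## and are fixed afterwards.

## ---- internal engine: plain-vector mirror of a Network ----

asEngine <- function(net) {
  nd <- net@nodes
  ed <- net@edges
  tr <- net@triangles
  p <- net@params
  env <- new.env(parent = emptyenv())
  env$x <- nd$x
  env$y <- nd$y
  env$kin <- match(nd$kinematics, KINEMATICS) - 1L # 0 free 1 prescribed 2 fixed
  env$vy <- nd$vy
  env$nodeKind <- nd$kind
  env$ekind <- ed$kind
  env$en1 <- ed$n1
  env$en2 <- ed$n2
  env$et1 <- ed$t1
  env$et2 <- ed$t2
  env$ks <- ed$ks
  env$kc <- ed$kc
  env$d0 <- ed$d0
  env$att <- ed$state == "attached"
  env$tAtt <- ed$tAttach
  env$tRem <- ed$tRemove
  env$ta <- tr$a
  env$tb <- tr$b
  env$tc <- tr$c
  env$te1 <- tr$e1
  env$te2 <- tr$e2
  env$te3 <- tr$e3
  env$p <- paramsToList(p)
  env$time <- net@time
  env$evTime <- numeric()
  env$evKind <- character()
  env$evEdge <- integer()
  env$evX <- numeric()
  env$evY <- numeric()
  env
}

engineToNetwork <- function(env, params) {
  nd <- data.frame(
    id = seq_along(env$x), kind = env$nodeKind, x = env$x, y = env$y,
    kinematics = KINEMATICS[env$kin + 1L], vy = env$vy,
    stringsAsFactors = FALSE
  )
  ed <- data.frame(
    id = seq_along(env$ekind), kind = env$ekind, n1 = env$en1, n2 = env$en2,
    t1 = env$et1, t2 = env$et2, ks = env$ks, kc = env$kc, d0 = env$d0,
    state = ifelse(env$att, "attached", "removed"),
    tAttach = env$tAtt, tRemove = env$tRem, stringsAsFactors = FALSE
  )
  tr <- data.frame(
    id = seq_along(env$ta), a = env$ta, b = env$tb, c = env$tc,
    e1 = env$te1, e2 = env$te2, e3 = env$te3
  )
  new("Network", nodes = nd, edges = ed, triangles = tr, params = params,
    time = env$time)
}

engineEvents <- function(env) {
  data.frame(
    time = env$evTime, event = env$evKind, edge = env$evEdge,
    x = env$evX, y = env$evY, stringsAsFactors = FALSE
  )
}

logEvent <- function(env, kind, edge, x, y) {
  env$evTime <- c(env$evTime, env$time)
  env$evKind <- c(env$evKind, kind)
  env$evEdge <- c(env$evEdge, edge)
  env$evX <- c(env$evX, x)
  env$evY <- c(env$evY, y)
}

## Per-edge geometry and endpoint forces over the attached edges.
## Returns NULL-free list of vectors indexed along `which(att)`.
edgeForces <- function(env) {
  w <- which(env$att)
  cenx <- (env$x[env$ta] + env$x[env$tb] + env$x[env$tc]) / 3
  ceny <- (env$y[env$ta] + env$y[env$tb] + env$y[env$tc]) / 3
  n1 <- env$en1[w]
  n2 <- env$en2[w]
  t1 <- env$et1[w]
  t2 <- env$et2[w]
  s1 <- !is.na(n1)
  s2 <- !is.na(n2)
  p1x <- p1y <- p2x <- p2y <- numeric(length(w))
  p1x[s1] <- env$x[n1[s1]]
  p1y[s1] <- env$y[n1[s1]]
  p1x[!s1] <- cenx[t1[!s1]]
  p1y[!s1] <- ceny[t1[!s1]]
  p2x[s2] <- env$x[n2[s2]]
  p2y[s2] <- env$y[n2[s2]]
  p2x[!s2] <- cenx[t2[!s2]]
  p2y[!s2] <- ceny[t2[!s2]]
  dx <- p1x - p2x
  dy <- p1y - p2y
  d <- sqrt(dx * dx + dy * dy)
  ks <- env$ks[w]
  kc <- env$kc[w]
  if (any(d == 0 & ks > 0)) {
    stop("degenerate-direction error: spring edge with coincident endpoints")
  }
  coefS <- ifelse(ks > 0, -ks * (d - env$d0[w]) / pmax(d, .Machine$double.xmin), 0)
  coef <- coefS - kc
  list(
    w = w, d = d,
    f1x = coef * dx, f1y = coef * dy, # force on endpoint 1 (endpoint 2 gets -f1)
    s1 = s1, s2 = s2, n1 = n1, n2 = n2, t1 = t1, t2 = t2
  )
}

## Aggregate endpoint forces into per-node forces, over a logical `keep`
## mask along the attached-edge list (detached-this-step edges drop out).
nodeForces <- function(env, ef, keep = NULL) {
  if (is.null(keep)) keep <- rep(TRUE, length(ef$w))
  idx <- c(
    ef$n1[ef$s1 & keep],
    env$ta[ef$t1[!ef$s1 & keep]], env$tb[ef$t1[!ef$s1 & keep]],
    env$tc[ef$t1[!ef$s1 & keep]],
    ef$n2[ef$s2 & keep],
    env$ta[ef$t2[!ef$s2 & keep]], env$tb[ef$t2[!ef$s2 & keep]],
    env$tc[ef$t2[!ef$s2 & keep]]
  )
  k1n <- ef$s1 & keep
  k1t <- !ef$s1 & keep
  k2n <- ef$s2 & keep
  k2t <- !ef$s2 & keep
  vx <- c(
    ef$f1x[k1n], rep(ef$f1x[k1t] / 3, 3),
    -ef$f1x[k2n], rep(-ef$f1x[k2t] / 3, 3)
  )
  vy <- c(
    ef$f1y[k1n], rep(ef$f1y[k1t] / 3, 3),
    -ef$f1y[k2n], rep(-ef$f1y[k2t] / 3, 3)
  )
  Fx <- numeric(length(env$x))
  Fy <- numeric(length(env$x))
  if (length(idx)) {
    agg <- rowsum(cbind(vx, vy), idx)
    ids <- as.integer(rownames(agg))
    Fx[ids] <- agg[, 1]
    Fy[ids] <- agg[, 2]
  }
  cbind(fx = Fx, fy = Fy)
}

engineIntact <- function(env) {
  env$att[env$te1] & env$att[env$te2] & env$att[env$te3]
}

engineFree <- function(env) {
  occ <- rep(FALSE, length(env$ta))
  myo <- env$att & env$ekind %in% c("myosin_linker", "myosin_rod")
  occ[stats::na.omit(c(env$et1[myo], env$et2[myo]))] <- TRUE
  engineIntact(env) & !occ
}

engineCentroids <- function(env) {
  cbind(
    (env$x[env$ta] + env$x[env$tb] + env$x[env$tc]) / 3,
    (env$y[env$ta] + env$y[env$tb] + env$y[env$tc]) / 3
  )
}

## ---- exported operations on Network ----

#' Total mechanical energy of the network
#'
#' Sum of spring energies `ks*(d - d0)^2/2` and cable energies `kc*d^2/2`
#' over all attached edges; removed edges contribute nothing.
#'
#' @param net a [Network-class].
#' @return a single number (force units times nm).
#' @examples
#' net <- buildTriangularLattice(3, 3, modelParams())
#' totalEnergy(net) # 0 at rest
#' @rdname totalEnergy
#' @export
setMethod("totalEnergy", "Network", function(net) {
  ed <- net@edges
  att <- ed$state == "attached"
  if (!any(att)) return(0)
  d <- edgeLengthsOf(net)[att]
  sum(ed$ks[att] * (d - ed$d0[att])^2 / 2) + sum(ed$kc[att] * d^2 / 2)
})

#' Net force on every node
#'
#' Analytic gradient of the total energy with respect to node positions,
#' with the sign convention `F = -dU/dr`. Forces transmitted through a
#' triangle attachment are split equally among the three triangle nodes.
#' Prescribed and fixed nodes still report their force (it is simply not
#' used for motion).
#'
#' @param net a [Network-class].
#' @return a numeric matrix with one row per node and columns `fx`, `fy`.
#' @rdname netForce
#' @export
setMethod("netForce", "Network", function(net) {
  env <- asEngine(net)
  ef <- edgeForces(env)
  nodeForces(env, ef)
})

#' Advance the network by one explicit-Euler step
#'
#' Free nodes move by `F/xi * dt`; prescribed focal adhesions follow their
#' vertical schedule (speed `vy` while `time < tS`, zero afterwards); fixed
#' nodes stay put. Simulation time advances by `dt`.
#'
#' @param net a [Network-class].
#' @param forces matrix as returned by [netForce()]; recomputed when NULL.
#' @return the advanced [Network-class].
#' @export
eulerStep <- function(net, forces = NULL) {
  if (is.null(forces)) forces <- netForce(net)
  if (any(!is.finite(forces))) stop("integration error: non-finite forces")
  p <- net@params
  nd <- net@nodes
  free <- nd$kinematics == "free"
  nd$x[free] <- nd$x[free] + forces[free, 1] / p@xi * p@dt
  nd$y[free] <- nd$y[free] + forces[free, 2] / p@xi * p@dt
  pres <- nd$kinematics == "prescribed"
  if (any(pres) && net@time < p@tS) {
    nd$y[pres] <- nd$y[pres] + nd$vy[pres] * p@dt
  }
  net@nodes <- nd
  net@time <- net@time + p@dt
  net
}

#' Detach over-threshold compressed spectrin edges
#'
#' A compressed spectrin spring (length below rest) pushes its end nodes
#' apart; when that expanding force `ksS*(d0S - d)` exceeds the threshold
#' `Fth` the actin-spectrin interface fails and the edge is removed from the
#' network. With `stretched = TRUE` over-extended edges
#' (`ksS*(d - d0S) > Fth`) are removed as well (off by default: detachment
#' of compressed bundles is the modeled failure mode).
#'
#' @param net a [Network-class].
#' @param stretched also detach over-stretched edges.
#' @return list with `network` (updated) and `events` (data.frame of
#'   spectrin_detach rows, possibly empty).
#' @export
applyDetachment <- function(net, stretched = FALSE) {
  ed <- net@edges
  p <- net@params
  d <- edgeLengthsOf(net)
  cand <- ed$state == "attached" & ed$kind == "spectrin"
  fExpand <- ed$ks * (ed$d0 - d)
  out <- cand & fExpand > p@Fth
  if (stretched) out <- out | (cand & ed$ks * (d - ed$d0) > p@Fth)
  ev <- emptyEvents()
  if (any(out)) {
    ep <- edgeEndpointPositions(net)
    mx <- (ep$p1[, 1] + ep$p2[, 1]) / 2
    my <- (ep$p1[, 2] + ep$p2[, 2]) / 2
    ed$state[out] <- "removed"
    ed$tRemove[out] <- net@time
    net@edges <- ed
    ev <- data.frame(
      time = net@time, event = "spectrin_detach", edge = ed$id[out],
      x = mx[out], y = my[out], stringsAsFactors = FALSE
    )
  }
  list(network = net, events = ev)
}

#' Retarget or remove myosin after triangle breakage
#'
#' Each myosin end whose host triangle lost one of its spectrin sides
#' re-attaches to a uniformly random free triangle whose centroid lies
#' between `dMin` and `dMax` from the myosin's other end; when no candidate
#' exists the myosin edge is removed. Additionally, myosin linkers whose
#' length has contracted below `dMin` detach from the network.
#'
#' @param net a [Network-class].
#' @return list with `network` and `events` (myosin_rebind / myosin_remove
#'   rows).
#' @export
myosinRebind <- function(net) {
  env <- asEngine(net)
  engineMyosinRebind(env)
  list(
    network = engineToNetwork(env, net@params),
    events = engineEvents(env)
  )
}

#' One stochastic myosin turnover attempt
#'
#' With probability `dt*phiA` one myosin rod addition is attempted at a
#' random admissible location; with probability `dt*phiR` one uniformly
#' chosen myosin rod is removed (no-op when none exist). Draws consume the
#' caller's RNG stream.
#'
#' @param net a [Network-class].
#' @return list with `network` and `events`.
#' @export
stochasticMyosinUpdate <- function(net) {
  p <- net@params
  if (p@dt * max(p@phiA, p@phiR) > 1) {
    stop("configuration error: dt*phi > 1 (probability overflow)")
  }
  env <- asEngine(net)
  engineStochasticMyosin(env)
  list(
    network = engineToNetwork(env, net@params),
    events = engineEvents(env)
  )
}

## ---- engine-level myosin steps (shared by wrappers and the run loop) ----

engineMyosinRebind <- function(env) {
  myo <- which(env$att & env$ekind %in% c("myosin_linker", "myosin_rod"))
  if (!length(myo)) return(invisible(env))
  intact <- engineIntact(env)
  cen <- engineCentroids(env)
  dMin <- env$p$dMin
  dMax <- env$p$dMax
  for (e in myo) {
    if (!env$att[e]) next
    ends <- list(
      list(node = env$en1[e], tri = env$et1[e], slot = 1L),
      list(node = env$en2[e], tri = env$et2[e], slot = 2L)
    )
    for (end in ends) {
      if (!env$att[e]) break
      if (is.na(end$tri) || intact[end$tri]) next
      ## other-end anchor position
      other <- ends[[3L - end$slot]]
      if (!is.na(other$node)) {
        ox <- env$x[other$node]
        oy <- env$y[other$node]
      } else {
        ox <- cen[other$tri, 1]
        oy <- cen[other$tri, 2]
      }
      free <- which(engineFree(env))
      free <- setdiff(free, other$tri)
      if (length(free)) {
        dd <- sqrt((cen[free, 1] - ox)^2 + (cen[free, 2] - oy)^2)
        cand <- free[dd > dMin & dd < dMax]
      } else {
        cand <- integer()
      }
      if (length(cand)) {
        tid <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
        if (end$slot == 1L) env$et1[e] <- tid else env$et2[e] <- tid
        logEvent(env, "myosin_rebind", e, cen[tid, 1], cen[tid, 2])
      } else {
        env$att[e] <- FALSE
        env$tRem[e] <- env$time
        logEvent(env, "myosin_remove", e, ox, oy)
      }
    }
  }
  ## linkers contracted below dMin detach
  link <- which(env$att & env$ekind == "myosin_linker")
  if (length(link)) {
    cen <- engineCentroids(env)
    for (e in link) {
      px <- if (!is.na(env$en1[e])) env$x[env$en1[e]] else cen[env$et1[e], 1]
      py <- if (!is.na(env$en1[e])) env$y[env$en1[e]] else cen[env$et1[e], 2]
      qx <- if (!is.na(env$en2[e])) env$x[env$en2[e]] else cen[env$et2[e], 1]
      qy <- if (!is.na(env$en2[e])) env$y[env$en2[e]] else cen[env$et2[e], 2]
      if (sqrt((px - qx)^2 + (py - qy)^2) < env$p$dMin) {
        env$att[e] <- FALSE
        env$tRem[e] <- env$time
        logEvent(env, "myosin_remove", e, (px + qx) / 2, (py + qy) / 2)
      }
    }
  }
  invisible(env)
}

engineAddRod <- function(env) {
  free <- which(engineFree(env))
  if (length(free) < 2) return(FALSE)
  cen <- engineCentroids(env)[free, , drop = FALSE]
  dm <- as.matrix(stats::dist(cen))
  adm <- which(upper.tri(dm) & dm > env$p$dMin & dm < env$p$dMax,
    arr.ind = TRUE
  )
  if (!nrow(adm)) return(FALSE)
  pick <- adm[sample.int(nrow(adm), 1L), ]
  t1 <- free[pick[1]]
  t2 <- free[pick[2]]
  env$ekind <- c(env$ekind, "myosin_rod")
  env$en1 <- c(env$en1, NA_integer_)
  env$en2 <- c(env$en2, NA_integer_)
  env$et1 <- c(env$et1, t1)
  env$et2 <- c(env$et2, t2)
  env$ks <- c(env$ks, 0)
  env$kc <- c(env$kc, env$p$kcM)
  env$d0 <- c(env$d0, 0)
  env$att <- c(env$att, TRUE)
  env$tAtt <- c(env$tAtt, env$time)
  env$tRem <- c(env$tRem, NA_real_)
  cenAll <- engineCentroids(env)
  logEvent(
    env, "myosin_add", length(env$ekind),
    (cenAll[t1, 1] + cenAll[t2, 1]) / 2, (cenAll[t1, 2] + cenAll[t2, 2]) / 2
  )
  TRUE
}

engineStochasticMyosin <- function(env) {
  if (stats::runif(1) < env$p$dt * env$p$phiA) engineAddRod(env)
  if (stats::runif(1) < env$p$dt * env$p$phiR) {
    rods <- which(env$att & env$ekind == "myosin_rod")
    if (length(rods)) {
      e <- if (length(rods) == 1L) rods else rods[sample.int(length(rods), 1L)]
      env$att[e] <- FALSE
      env$tRem[e] <- env$time
      cen <- engineCentroids(env)
      logEvent(
        env, "myosin_remove", e,
        (cen[env$et1[e], 1] + cen[env$et2[e], 1]) / 2,
        (cen[env$et1[e], 2] + cen[env$et2[e], 2]) / 2
      )
    }
  }
  invisible(env)
}

## ---- the per-timestep loop ----

#' Run the overdamped network simulation
#'
#' Executes the per-timestep algorithm: compute edge forces; detach spectrin
#' edges whose expanding spring force exceeds `Fth`; move the nodes
#' (detached edges no longer contribute); apply the focal-adhesion vertical
#' schedule; retarget or remove myosin attached to broken triangles;
#' stochastically add and remove myosin rods. In `equilibrate` mode the run
#' stops early once the maximum per-step node displacement falls below
#' `tol`.
#'
#' @param net the initial [Network-class] (see [buildScenario()]).
#' @param Ttot total duration (s); defaults to the parameter set's `Ttot`.
#' @param detachment enable spectrin detachment.
#' @param detachStretched also detach over-stretched spectrin (default off).
#' @param myosinTurnover enable the stochastic rod add/remove steps.
#' @param snapshotEvery snapshot sampling interval (s); NA keeps only the
#'   initial and final states.
#' @param equilibrate stop when the network stops moving.
#' @param tol equilibration tolerance: maximum per-step displacement (nm).
#' @param energyGuard abort with an instability error if the total energy
#'   exceeds its initial value by this factor (default 10).
#' @return a [Trajectory-class].
#' @examples
#' net <- buildTriangularLattice(4, 6, modelParams(Ttot = 1))
#' tr <- runSimulation(net, Ttot = 1)
#' tr
#' @export
runSimulation <- function(net, Ttot = NULL, detachment = TRUE,
                          detachStretched = FALSE, myosinTurnover = TRUE,
                          snapshotEvery = 60, equilibrate = FALSE,
                          tol = 1e-3, energyGuard = 10) {
  p <- net@params
  if (is.null(Ttot)) Ttot <- p@Ttot
  env <- asEngine(net)
  nSteps <- max(1L, as.integer(round(Ttot / p@dt)))
  hasMyosin <- any(env$ekind %in% c("myosin_linker", "myosin_rod"))
  doTurnover <- myosinTurnover && (p@phiA > 0 || p@phiR > 0)
  snaps <- list(engineToNetwork(env, p))
  snapTimes <- env$time
  nextSnap <- if (is.na(snapshotEvery)) Inf else env$time + snapshotEvery
  E0 <- totalEnergy(snaps[[1]])
  guard <- if (E0 > 1e-9) E0 * energyGuard else Inf
  checkEvery <- max(1L, nSteps %/% 200L)
  for (step in seq_len(nSteps)) {
    ef <- edgeForces(env)
    keep <- rep(TRUE, length(ef$w))
    if (detachment) {
      spec <- env$ekind[ef$w] == "spectrin"
      fExpand <- env$ks[ef$w] * (env$d0[ef$w] - ef$d)
      out <- spec & fExpand > env$p$Fth
      if (detachStretched) {
        out <- out | (spec & env$ks[ef$w] * (ef$d - env$d0[ef$w]) > env$p$Fth)
      }
      if (any(out)) {
        eids <- ef$w[out]
        env$att[eids] <- FALSE
        env$tRem[eids] <- env$time
        for (q in which(out)) {
          a <- ef$n1[q]
          b <- ef$n2[q]
          logEvent(
            env, "spectrin_detach", ef$w[q],
            (env$x[a] + env$x[b]) / 2, (env$y[a] + env$y[b]) / 2
          )
        }
        keep <- !out
      }
    }
    Fm <- nodeForces(env, ef, keep)
    if (any(!is.finite(Fm))) {
      stop(sprintf(
        "instability error: non-finite forces at t = %g s (dt = %g)",
        env$time, env$p$dt
      ))
    }
    free <- env$kin == 0L
    dxs <- Fm[free, 1] / env$p$xi * env$p$dt
    dys <- Fm[free, 2] / env$p$xi * env$p$dt
    env$x[free] <- env$x[free] + dxs
    env$y[free] <- env$y[free] + dys
    maxDisp <- if (length(dxs)) max(abs(c(dxs, dys))) else 0
    pres <- env$kin == 1L
    if (any(pres) && env$time < env$p$tS) {
      env$y[pres] <- env$y[pres] + env$vy[pres] * env$p$dt
      maxDisp <- max(maxDisp, abs(env$vy[pres]) * env$p$dt)
    }
    env$time <- env$time + env$p$dt
    if (hasMyosin && detachment) engineMyosinRebind(env)
    if (doTurnover) {
      engineStochasticMyosin(env)
      hasMyosin <- hasMyosin || any(env$ekind == "myosin_rod")
    }
    if (env$time >= nextSnap - 1e-9) {
      snaps[[length(snaps) + 1L]] <- engineToNetwork(env, p)
      snapTimes <- c(snapTimes, env$time)
      nextSnap <- nextSnap + snapshotEvery
    }
    if (step %% checkEvery == 0L) {
      Enow <- totalEnergyEngine(env)
      if (Enow > guard) {
        stop(sprintf(
          "instability error: energy grew %.1fx above initial; reduce dt = %g",
          Enow / E0, env$p$dt
        ))
      }
    }
    if (equilibrate && maxDisp < tol) break
  }
  fin <- engineToNetwork(env, p)
  if (is.na(snapshotEvery) || snapTimes[length(snapTimes)] < env$time) {
    snaps[[length(snaps) + 1L]] <- fin
    snapTimes <- c(snapTimes, env$time)
  }
  new("Trajectory",
    snapshots = snaps, snapshotTimes = snapTimes,
    events = engineEvents(env), final = fin, config = list()
  )
}

totalEnergyEngine <- function(env) {
  w <- which(env$att)
  if (!length(w)) return(0)
  ef <- edgeForces(env)
  sum(env$ks[w] * (ef$d - env$d0[w])^2 / 2) + sum(env$kc[w] * ef$d^2 / 2)
}

#' Relax a network to mechanical equilibrium
#'
#' Convenience wrapper around [runSimulation()] in equilibration mode with
#' detachment and myosin turnover disabled: the network relaxes under its
#' springs and cables until the maximum per-step displacement drops below
#' `tol`.
#'
#' @param net a [Network-class].
#' @param maxT time budget (s).
#' @param tol maximum per-step displacement (nm) declaring equilibrium.
#' @return the relaxed [Network-class].
#' @export
equilibrateNetwork <- function(net, maxT = 600, tol = 1e-3) {
  tr <- runSimulation(net,
    Ttot = maxT, detachment = FALSE, myosinTurnover = FALSE,
    snapshotEvery = NA, equilibrate = TRUE, tol = tol
  )
  tr@final
}
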