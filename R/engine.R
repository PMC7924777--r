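#' @include AllClasses.R AllGenerics.R state.R
NULL

#' Exponential waiting time to the next reaction
#'
#' `T = -log(u) / lambda0` for a uniform draw `u` on (0, 1].
#'
#' @param lambda0 positive total propensity.
#' @param u uniform draw in (0, 1]; defaults to a fresh draw.
#' @return waiting time (1/time units of the rate constants).
#' @examples
#' sampleTime(2, exp(-1))   # 0.5
#' @export
sampleTime <- function(lambda0, u = stats::runif(1)) {
  if (!is.finite(lambda0) || lambda0 <= 0)
    stop("lambda0 must be positive (an absorbing state has no next event)")
  if (u <= 0 || u > 1) stop("u must lie in (0, 1]")
  -log(u) / lambda0
}

#' Select the next reaction channel
#'
#' Returns the smallest index `j` whose cumulative propensity satisfies
#' `sum(lambda[1:(j-1)]) < u * lambda0 <= sum(lambda[1:j])` (strict on the
#' left, weak on the right).  Zero-rate channels are never selected.
#'
#' @param lambda per-channel propensities.
#' @param u uniform draw in (0, 1].
#' @return channel index.
#' @examples
#' selectChannel(c(1, 1), u = 0.5)   # 1: the boundary goes left
#' @export
selectChannel <- function(lambda, u = stats::runif(1)) {
  lambda0 <- sum(lambda)
  if (lambda0 <= 0) stop("all channel rates are zero")
  if (u <= 0 || u > 1) stop("u must lie in (0, 1]")
  cum <- cumsum(lambda)
  j <- which(u * lambda0 <= cum)[1L]
  if (is.na(j)) j <- length(lambda)   # guard against rounding at the top end
  j
}

#' One exact SSA step
#'
#' Draws the waiting time and channel with [sampleTime()] and
#' [selectChannel()], then fires the channel with [fireChannel()].  Uses
#' the same RNG draw order as [runDirectSSA()], so single-stepping with the
#' same seed reproduces the compiled loop's event sequence exactly.
#'
#' @param state a [SimState-class] (modified in place).
#' @return one-row event record, or `NULL` if the state is absorbing
#'   (`totalRate(state) == 0`).
#' @export
stepSSA <- function(state) {
  lam <- .ips_core_lambda(state@ptr)
  lam0 <- sum(lam)
  if (lam0 <= 0) return(NULL)
  T <- sampleTime(lam0)
  r <- selectChannel(lam)
  fireChannel(state, r, dt = T)
}

.saveGrid <- function(t0, tFinal, saveInterval) {
  if (is.na(tFinal) || tFinal <= t0)
    stop("tFinal must be greater than the current time")
  if (is.null(saveInterval) || !is.finite(saveInterval) || !is.finite(tFinal))
    return(c(t0, tFinal))
  stopifnot(saveInterval > 0)
  grid <- seq(t0, tFinal, by = saveInterval)
  if (grid[length(grid)] < tFinal) grid <- c(grid, tFinal)
  grid
}

.mkTrajectory <- function(res, saveTimes, species) {
  keep <- seq_len(res$nSaved)
  saveTimes[!is.finite(saveTimes)] <- res$t   # to-absorption runs end at t
  counts <- res$populations[keep, , drop = FALSE]
  colnames(counts) <- c(.OPEN, species)
  ev <- res$events
  if (!is.null(ev)) ev <- as.data.frame(ev)
  new("Trajectory", times = saveTimes[keep], counts = counts,
      status = res$status, nEvents = res$nEvents,
      skipped = if (is.null(res$skipped)) 0 else res$skipped, events = ev)
}

#' Run the exact direct stochastic simulation algorithm
#'
#' Repeats (waiting time, channel selection, firing) until `tFinal`,
#' `maxEvents`, or an absorbing state (`lambda0 = 0`) is reached.
#' Population counts are recorded at every `saveInterval` grid point by
#' carrying the last state forward.  Spatial updates are local, so the
#' per-event cost is independent of the lattice size.
#'
#' @param state a [SimState-class] (modified in place; it ends at the
#'   stopping time).
#' @param tFinal stopping time.
#' @param saveInterval spacing of the population save grid; `NULL` records
#'   only the initial and final points.
#' @param maxEvents event-count stopping rule.
#' @param recordEvents if `TRUE`, the full event log is kept on the
#'   trajectory.
#' @return a [Trajectory-class].
#' @export
runDirectSSA <- function(state, tFinal, saveInterval = NULL,
                         maxEvents = Inf, recordEvents = FALSE) {
  saveTimes <- .saveGrid(simTime(state), tFinal, saveInterval)
  res <- .ips_run_ssa(state@ptr, as.numeric(tFinal), as.numeric(maxEvents),
                      saveTimes, recordEvents)
  .mkTrajectory(res, saveTimes, state@model@species)
}

#' Run tau-leaping with shuffled sequential firing
#'
#' Per leap of fixed length `tau`, a Poisson number of events is drawn for
#' each channel from the leap-start propensities.  Because spatial updates
#' do not commute, the combined event list is applied sequentially in
#' uniformly shuffled order; events whose sample class is empty at
#' application time are infeasible and are skipped (and counted, see the
#' `skipped` slot of the result).  Large skip counts indicate `tau` is too
#' coarse.
#'
#' @inheritParams runDirectSSA
#' @param tau leap length (fixed; no adaptive selection).
#' @param shuffle if `FALSE`, events are applied in channel order within a
#'   leap; exposed to demonstrate the non-commutativity of spatial updates
#'   and not recommended for production runs.
#' @return a [Trajectory-class].
#' @export
runTauLeap <- function(state, tau, tFinal, saveInterval = NULL,
                       maxEvents = Inf, shuffle = TRUE) {
  stopifnot(is.numeric(tau), tau > 0)
  saveTimes <- .saveGrid(simTime(state), tFinal, saveInterval)
  res <- .ips_run_tau(state@ptr, as.numeric(tau), as.numeric(tFinal),
                      as.numeric(maxEvents), saveTimes, shuffle)
  .mkTrajectory(res, saveTimes, state@model@species)
}

#' Simulate replicate trajectories of a model or packaged example
#'
#' High-level driver: builds (or reuses) the state, then runs
#' `nReplicates` independent trajectories.  Replicate `i` is seeded with
#' `seed + i`, and the initial configuration is redrawn per replicate when
#' `init` is a generating function (as for the packaged example models).
#'
#' @param x either a fixture list as returned by [makePredatorPrey()] and
#'   friends (components `graph`, `model`, `makeInit`), or a
#'   [SiteGraph-class] (then `model` and `init` must be given).
#' @param tFinal,saveInterval,maxEvents,recordEvents as in [runDirectSSA()].
#' @param method `"direct"` (exact SSA) or `"tau"` (tau-leaping).
#' @param tau leap length, required for `method = "tau"`.
#' @param nReplicates number of replicates.
#' @param seed integer; replicate `i` runs under `set.seed(seed + i)`.
#'   `NULL` continues the current RNG stream (replicates then are not
#'   individually re-seedable).
#' @param model,init for raw-graph input: the [IPSModel-class] and an
#'   occupancy vector or a zero-argument function returning one.
#' @return list with `populations` (data.frame: `replicate`, `t`,
#'   `species`, `count`) and `trajectories` (list of
#'   [Trajectory-class]).
#' @export
simulateIPS <- function(x, tFinal, saveInterval = NULL,
                        method = c("direct", "tau"), tau = NULL,
                        nReplicates = 1, seed = NULL, maxEvents = Inf,
                        recordEvents = FALSE, model = NULL, init = NULL) {
  method <- match.arg(method)
  if (method == "tau" && is.null(tau)) stop("method 'tau' needs a tau")
  if (is.list(x) && !is(x, "SiteGraph")) {
    graph <- x$graph; model <- x$model
    init <- x$makeInit
  } else {
    graph <- x
    if (is.null(model) || is.null(init))
      stop("supply model and init when passing a raw SiteGraph")
  }
  cs <- reactionChannels(model, latticeD(graph))
  state <- NULL
  trajs <- vector("list", nReplicates)
  pops <- vector("list", nReplicates)
  for (i in seq_len(nReplicates)) {
    if (!is.null(seed)) set.seed(seed + i)
    occ <- if (is.function(init)) init() else init
    if (is.null(state))
      state <- initializeState(graph, model, occ, channels = cs)
    else resetState(state, occ)
    tr <- if (method == "direct")
      runDirectSSA(state, tFinal, saveInterval, maxEvents, recordEvents)
    else
      runTauLeap(state, tau, tFinal, saveInterval, maxEvents)
    trajs[[i]] <- tr
    p <- populations(tr)
    p <- cbind(replicate = i, p)
    pops[[i]] <- p
  }
  list(populations = do.call(rbind, pops), trajectories = trajs,
       finalState = state)
}
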