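#' @include AllClasses.R AllGenerics.R engine.R
NULL

.fixture <- function(name, model, graph, makeInit, params) {
  structure(list(name = name, model = model, graph = graph,
                 makeInit = makeInit, params = params),
            class = "IPSFixture")
}

#' @export
print.IPSFixture <- function(x, ...) {
  cat(sprintf("IPS example model '%s' on a %s lattice (%d sites)\n", x$name,
              x$graph@topology, nSites(x$graph)))
  cat("  parameters:", paste(sprintf("%s=%g", names(x$params),
                                     unlist(x$params)), collapse = ", "), "\n")
  invisible(x)
}

#' Predator-prey model on a hexagonal lattice
#'
#' Foxes (`F`) and rabbits (`R`) with six reactions: fox predation
#' `F + R -> F + F`, rabbit reproduction `R + 0 -> R + R`, migration of
#' both species, and death of both species at a shared rate.  With the
#' hexagonal default (`D = 6`) the model expands to 26 reaction channels
#' in 20 sample classes; rabbits occupy 7 of those classes (one per number
#' of adjacent open sites, shared by reproduction and migration, plus the
#' death class).
#'
#' Default rates are chosen so that, from a well-mixed random start, the
#' two species coexist in traveling patches over long horizons rather than
#' collapsing to a predator spike and crash.
#'
#' @param params named rates: `predation` (alpha), `reproduction` (beta),
#'   `migration` (gamma, both species), `death` (mu, both species).
#' @param lattice a [SiteGraph-class]; defaults to a 100x100 closed
#'   hexagonal lattice.
#' @param init named densities for the random initial placement.
#' @return fixture list with components `name`, `model`, `graph`,
#'   `makeInit` (zero-argument function drawing an initial occupancy from
#'   the current RNG stream) and `params`.
#' @examples
#' pp <- makePredatorPrey(lattice = buildLattice("hex2d", c(20, 20)))
#' nChannels(reactionChannels(pp$model, 6))   # 26
#' @export
makePredatorPrey <- function(params = c(predation = 0.3, reproduction = 1.0,
                                        migration = 1.0, death = 0.2),
                             lattice = buildLattice("hex2d", c(100, 100)),
                             init = c(R = 0.3, F = 0.05)) {
  model <- ipsModel(c("F", "R"), list(
    parseReaction("F + R -> F + F", params[["predation"]], "fox predation"),
    parseReaction("R + 0 -> R + R", params[["reproduction"]], "rabbit reproduction"),
    parseReaction("F + 0 -> 0 + F", params[["migration"]], "fox migration"),
    parseReaction("R + 0 -> 0 + R", params[["migration"]], "rabbit migration"),
    parseReaction("F -> 0", params[["death"]], "fox death"),
    parseReaction("R -> 0", params[["death"]], "rabbit death")))
  .fixture("predator_prey", model, lattice,
           function() randomPlacement(lattice, init), as.list(params))
}

#' Rock-paper-scissors game
#'
#' Three species, each undergoing birth (`S + 0 -> S + S`), death
#' (`S -> 0`) and migration (`S + 0 -> 0 + S`), plus one cyclic predation
#' each: rock preys on scissors, scissors on paper, paper on rock
#' (`R + S -> R + R` and cyclic permutations).  The model has 3 on-site
#' and 9 pairwise reactions, hence `9 D + 3` reaction channels.
#'
#' With symmetric parameters and a symmetric random start the three
#' species are exchangeable; spatial clustering maintains all three, while
#' fast migration mixes the populations and drives extinctions.
#'
#' @param params named rates `birth`, `death`, `migration`, `predation`,
#'   shared by the three species.
#' @param lattice a [SiteGraph-class]; defaults to a 100x100 periodic
#'   square lattice.
#' @param init per-species density of the random initial placement.
#' @return fixture list; see [makePredatorPrey()].
#' @export
makeRockPaperScissors <- function(params = c(birth = 0.6, death = 0.05,
                                             migration = 0.4, predation = 1.0),
                                  lattice = buildLattice("square2d", c(100, 100),
                                                         "periodic"),
                                  init = 0.3) {
  sp <- c("R", "P", "S")
  prey <- c(R = "S", S = "P", P = "R")
  rx <- list()
  for (s in sp) {
    rx <- c(rx, list(
      parseReaction(sprintf("%s + 0 -> %s + %s", s, s, s), params[["birth"]],
                    paste(s, "birth")),
      parseReaction(sprintf("%s + %s -> %s + %s", s, prey[[s]], s, s),
                    params[["predation"]], paste(s, "predation")),
      parseReaction(sprintf("%s + 0 -> 0 + %s", s, s), params[["migration"]],
                    paste(s, "migration"))))
  }
  for (s in sp)
    rx <- c(rx, list(parseReaction(sprintf("%s -> 0", s), params[["death"]],
                                   paste(s, "death"))))
  model <- ipsModel(sp, rx)
  dens <- stats::setNames(if (length(init) == 1) rep(init, 3) else init, sp)
  .fixture("rock_paper_scissors", model, lattice,
           function() randomPlacement(lattice, dens), as.list(params))
}

#' Tumor-immune interaction under immunotherapy
#'
#' Cancer cells (`C`) follow a birth-death-migration process.  Immune
#' cells (`I`) immigrate at a constant per-site rate from an inert,
#' immobile barrier species (`B`) placed on the boundary sites, migrate,
#' and destroy cancer cells on contact; a kill leaves either an open site
#' or a fibrotic cell (`Fb`), via two competing predation reactions.
#' Fibrotic cells block cancer spread but are weakly porous to immune
#' cells: an immune cell may step into a fibrotic cell, forming the
#' transient species `FI` (a fibrotic cell with an immune cell passing
#' through), and later exit through an adjacent open site, restoring `Fb`.
#'
#' The volume-excluding shell of fibrotic cells that forms around the
#' tumor and shields it from eradication is the qualitative signature of
#' this model.
#'
#' @param params named rates: `birth`, `death`, `migration` (cancer);
#'   `influx` (B + 0 -> B + I), `immMigration`, `kill` (I + C -> I + 0),
#'   `fibrosis` (I + C -> I + Fb), `enter` (I + Fb -> 0 + FI), `exit`
#'   (FI + 0 -> Fb + I).
#' @param lattice a [SiteGraph-class]; defaults to a 50x50 closed square
#'   lattice.
#' @param tumorRadius Chebyshev radius of the initial central cancer
#'   cluster.
#' @return fixture list; see [makePredatorPrey()].  The initial
#'   configuration places `B` on every boundary site and `C` on the
#'   central cluster.
#' @export
makeImmunotherapy <- function(params = c(birth = 0.3, death = 0.02,
                                         migration = 0.3, influx = 0.02,
                                         immMigration = 2.0, kill = 1.0,
                                         fibrosis = 0.5, enter = 0.05,
                                         exit = 0.5),
                              lattice = buildLattice("square2d", c(50, 50)),
                              tumorRadius = 4) {
  model <- ipsModel(c("C", "I", "B", "Fb", "FI"), list(
    parseReaction("C + 0 -> C + C", params[["birth"]], "cancer birth"),
    parseReaction("C + 0 -> 0 + C", params[["migration"]], "cancer migration"),
    parseReaction("B + 0 -> B + I", params[["influx"]], "immune influx"),
    parseReaction("I + 0 -> 0 + I", params[["immMigration"]], "immune migration"),
    parseReaction("I + C -> I + 0", params[["kill"]], "immune kill"),
    parseReaction("I + C -> I + Fb", params[["fibrosis"]], "immune kill, fibrotic"),
    parseReaction("I + Fb -> 0 + FI", params[["enter"]], "immune enters fibrosis"),
    parseReaction("FI + 0 -> Fb + I", params[["exit"]], "immune exits fibrosis"),
    parseReaction("C -> 0", params[["death"]], "cancer death")))
  graph <- lattice
  xy <- siteCoords(graph)
  boundary <- which(apply(xy, 1L, function(cc)
    any(cc == 0L) || any(cc == graph@extent[seq_along(cc)] - 1L)))
  center <- floor((graph@extent - 1L) / 2L)
  tumor <- which(apply(xy, 1L, function(cc) max(abs(cc - center)) <= tumorRadius))
  tumor <- setdiff(tumor, boundary)
  makeInit <- function() {
    occ <- rep("0", nSites(graph))
    occ[boundary] <- "B"
    occ[tumor] <- "C"
    occ
  }
  .fixture("immunotherapy", model, graph, makeInit, as.list(params))
}

#' Lipid (PUFA) oxidation with deuteration
#'
#' A membrane of unoxidized polyunsaturated fatty acids, modeled as open
#' sites on a square lattice.  A single oxidized walker (`Ox`) starts at
#' the center; it hops to an adjacent unoxidized PUFA, leaving behind a
#' depleted (kinked) PUFA (`Dp`) -- the single reaction
#' `Ox + 0 -> Dp + Ox`.  A fraction `p` of sites holds deuterated PUFAs
#' (`De`), which resist oxidation (inert by default; an optional slow rate
#' `epsilon` lets the walker consume them).  The walk stops when the
#' walker is trapped by its own depleted trail and the deuterated sites;
#' the depleted-chain length is the number of `Dp` sites at absorption.
#'
#' @param p deuterated fraction in `[0, 1]`.
#' @param lattice a [SiteGraph-class]; defaults to a 101x101 closed square
#'   lattice with the walker at the central site.
#' @param epsilon optional oxidation rate of deuterated PUFAs (default 0:
#'   fully resistant).
#' @param hopRate rate of the oxidation hop (sets the time unit).
#' @return fixture list; see [makePredatorPrey()].
#' @examples
#' fx <- makePufa(p = 1, lattice = buildLattice("square2d", c(11, 11)))
#' st <- initializeState(fx$graph, fx$model, fx$makeInit())
#' totalRate(st)   # 0: the walker is trapped immediately
#' @export
makePufa <- function(p, lattice = buildLattice("square2d", c(101, 101)),
                     epsilon = 0, hopRate = 1) {
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  rx <- list(parseReaction("Ox + 0 -> Dp + Ox", hopRate, "oxidation hop"))
  if (epsilon > 0)
    rx <- c(rx, list(parseReaction("Ox + De -> Dp + Ox", epsilon,
                                   "deuterated oxidation")))
  model <- ipsModel(c("Dp", "De", "Ox"), rx)
  graph <- lattice
  n <- nSites(graph)
  center <- .centerSite(graph)
  makeInit <- function() {
    occ <- rep("0", n)
    occ[stats::runif(n) < p] <- "De"
    occ[center] <- "Ox"
    occ
  }
  .fixture("pufa_oxidation", model, graph, makeInit,
           list(p = p, epsilon = epsilon, hopRate = hopRate))
}

.centerSite <- function(graph) {
  if (!length(graph@extent)) return(1L)
  xy <- siteCoords(graph)
  center <- floor((graph@extent - 1L) / 2L)
  which(apply(xy, 1L, function(cc) all(cc == center)))[1L]
}

#' Sweep the deuteration fraction of the lipid-oxidation model
#'
#' For each deuteration fraction `p`, runs `replicates` independent walks
#' to absorption on a fresh random membrane and records the depleted-chain
#' length (number of depleted sites when the walker is trapped).
#'
#' @param ps deuteration fractions to sweep.
#' @param replicates walks per sweep point.
#' @param lattice the membrane lattice (101x101 closed square by default).
#' @param seed integer seed for the whole sweep (one RNG stream drives
#'   placements and walks in a fixed schedule); `NULL` continues the
#'   current stream.
#' @param epsilon passed to [makePufa()].
#' @return data.frame with one row per sweep point: `p`, `meanLength`,
#'   `seLength`, `replicates`.
#' @seealso [deuterationThreshold()] for locating the sharp drop.
#' @export
pufaSweep <- function(ps = seq(0, 0.4, by = 0.02), replicates = 2000,
                      lattice = buildLattice("square2d", c(101, 101)),
                      seed = NULL, epsilon = 0) {
  if (!is.null(seed)) set.seed(seed)
  state <- NULL
  out <- lapply(ps, function(p) {
    fx <- makePufa(p, lattice, epsilon = epsilon)
    cs <- reactionChannels(fx$model, latticeD(lattice))
    lengths <- numeric(replicates)
    for (r in seq_len(replicates)) {
      occ <- fx$makeInit()
      if (is.null(state))
        state <<- initializeState(fx$graph, fx$model, occ, channels = cs)
      else resetState(state, occ)
      tr <- runDirectSSA(state, tFinal = Inf, maxEvents = 10 * nSites(lattice))
      lengths[r] <- finalCount(tr, "Dp")
    }
    data.frame(p = p, meanLength = mean(lengths),
               seLength = stats::sd(lengths) / sqrt(replicates),
               replicates = replicates)
  })
  do.call(rbind, out)
}

#' Locate the deuteration fraction with the steepest relative drop
#'
#' Estimates where the mean depleted-chain length falls fastest in
#' relative terms as the deuteration fraction increases.  Because the
#' per-interval relative decrease of the raw means saturates into a noisy
#' plateau, the location is read off a fitted curve: weighted least
#' squares of log mean length against `p` under a decay-rate-saturation
#' model (quadratic in `p` below a knee, log-linear above it, continuous
#' and differentiable at the knee; weights are the inverse squared
#' coefficients of variation of the means).  The fitted curve's relative
#' decrease between consecutive sweep points is maximal, and first
#' attained, on the interval beginning at the knee; the reported location
#' is that interval's midpoint.
#'
#' @param sweep data.frame from [pufaSweep()] (columns `p`, `meanLength`,
#'   `seLength`).
#' @return list with `pStar` (estimated drop location), `knee` (fitted
#'   knee), `fitted` (fitted mean lengths at the sweep points) and
#'   `relDrop` (fitted per-interval relative decreases).
#' @export
deuterationThreshold <- function(sweep) {
  stopifnot(all(c("p", "meanLength") %in% names(sweep)), nrow(sweep) >= 6)
  sweep <- sweep[order(sweep$p), ]
  ps <- sweep$p
  y <- log(sweep$meanLength)
  w <- if ("seLength" %in% names(sweep) && all(sweep$seLength > 0))
    (sweep$meanLength / sweep$seLength)^2
  else rep(1, length(ps))

  kneeGrid <- ps[seq(3, length(ps) - 2)]
  best <- NULL
  for (psi in kneeGrid) {
    d <- ps - psi
    X <- cbind(1, d, ifelse(d < 0, d^2, 0))
    fit <- stats::lm.wfit(X, y, w)
    if (!is.na(fit$coefficients[3]) && fit$coefficients[3] > 0) {
      fit <- stats::lm.wfit(X[, 1:2, drop = FALSE], y, w)
      pred <- X[, 1:2, drop = FALSE] %*% fit$coefficients
    } else {
      pred <- X %*% ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    }
    sse <- sum(w * (y - pred)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(sse = sse, knee = psi, pred = as.vector(pred))
  }
  fitted <- exp(best$pred)
  relDrop <- (fitted[-length(fitted)] - fitted[-1]) / fitted[-length(fitted)]
  i <- which.max(round(relDrop, 10))   # first interval attaining the max
  list(pStar = (ps[i] + ps[i + 1]) / 2, knee = best$knee,
       fitted = fitted, relDrop = relDrop)
}
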