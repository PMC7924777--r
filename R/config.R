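#' @include AllClasses.R AllGenerics.R fixtures.R engine.R
NULL

.cfgStop <- function(path, msg) stop(sprintf("config %s: %s", path, msg),
                                     call. = FALSE)

.cfgCheck <- function(cond, path, msg) if (!isTRUE(cond)) .cfgStop(path, msg)

#' Read and validate a run configuration
#'
#' A run configuration is a single JSON document with four sections:
#' `lattice` (topology, extent, boundary, optional D), `model` (species,
#' reactions as diagram strings with rates), `init` (random densities, an
#' explicit site assignment, or a packaged example name with overrides)
#' and `simulation` (t_final, save_interval, max_events, method, tau,
#' seed, replicates).  Validation errors name the offending field.
#'
#' @param path JSON file path, or a list already parsed.
#' @return validated config list (class `"ipsConfig"`).
#' @seealso [runConfig()], [fixtureConfig()], [writeConfig()].
#' @export
readConfig <- function(path) {
  cfg <- if (is.character(path))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else path
  .cfgCheck(is.list(cfg), "$", "must be a JSON object")
  for (sec in c("lattice", "model", "simulation"))
    .cfgCheck(!is.null(cfg[[sec]]), paste0("$", sec), "section missing")
  lat <- cfg$lattice
  .cfgCheck(is.character(lat$topology) &&
              lat$topology %in% c("square2d", "hex2d", "cubic3d"),
            "$lattice$topology", "must be square2d, hex2d or cubic3d")
  .cfgCheck(is.numeric(lat$extent) && all(lat$extent >= 1),
            "$lattice$extent", "must be positive integers")
  .cfgCheck(is.null(lat$boundary) ||
              lat$boundary %in% c("closed", "periodic"),
            "$lattice$boundary", "must be closed or periodic")
  mod <- cfg$model
  .cfgCheck(is.character(mod$species) && length(mod$species) >= 1,
            "$model$species", "must list at least one species")
  rx <- mod$reactions
  .cfgCheck(!is.null(rx), "$model$reactions", "section missing")
  if (is.data.frame(rx)) rx <- split(rx, seq_len(nrow(rx)))
  for (i in seq_along(rx)) {
    r <- as.list(rx[[i]])
    .cfgCheck(is.character(r$diagram),
              sprintf("$model$reactions[%d]$diagram", i), "missing diagram")
    .cfgCheck(is.numeric(r$rate) && r$rate >= 0,
              sprintf("$model$reactions[%d]$rate", i),
              "missing or negative rate")
  }
  cfg$model$reactions <- rx
  ini <- cfg$init
  .cfgCheck(!is.null(ini), "$init", "section missing")
  .cfgCheck(!is.null(ini$densities) || !is.null(ini$sites),
            "$init", "needs either densities or an explicit site assignment")
  sim <- cfg$simulation
  .cfgCheck(is.numeric(sim$t_final) && sim$t_final > 0,
            "$simulation$t_final", "must be positive")
  .cfgCheck(is.null(sim$method) || sim$method %in% c("direct", "tau"),
            "$simulation$method", "must be direct or tau")
  if (identical(sim$method, "tau"))
    .cfgCheck(is.numeric(sim$tau) && sim$tau > 0,
              "$simulation$tau", "tau-leaping needs a positive tau")
  structure(cfg, class = "ipsConfig")
}

#' @describeIn readConfig materialize the configured graph, model and
#'   initial-condition generator.
#' @param cfg a config list.
#' @export
buildFromConfig <- function(cfg) {
  if (!inherits(cfg, "ipsConfig")) cfg <- readConfig(cfg)
  lat <- cfg$lattice
  graph <- buildLattice(lat$topology, lat$extent,
                        if (is.null(lat$boundary)) "closed" else lat$boundary,
                        D = lat$D)
  rx <- lapply(cfg$model$reactions, function(r) {
    r <- as.list(r)
    parseReaction(r$diagram, r$rate,
                  name = if (is.null(r$name) || is.na(r$name)) NULL else r$name,
                  species = cfg$model$species)
  })
  model <- ipsModel(cfg$model$species, rx)
  ini <- cfg$init
  makeInit <- if (!is.null(ini$densities)) {
    dens <- unlist(ini$densities)
    function() randomPlacement(graph, dens)
  } else {
    sites <- as.integer(ini$sites) + 1L   # config files are 0-based
    speciesAt <- as.character(ini$species)
    if (length(speciesAt) == 1L) speciesAt <- rep(speciesAt, length(sites))
    .cfgCheck(length(speciesAt) == length(sites), "$init$species",
              "must match sites in length")
    .cfgCheck(all(sites >= 1L & sites <= nSites(graph)), "$init$sites",
              "site index out of range")
    .cfgCheck(!anyDuplicated(sites), "$init$sites",
              "duplicate site (volume exclusion)")
    function() {
      occ <- rep(.OPEN, nSites(graph))
      occ[sites] <- speciesAt
      occ
    }
  }
  list(graph = graph, model = model, makeInit = makeInit,
       simulation = cfg$simulation)
}

#' @describeIn readConfig write a config list as JSON.
#' @param file output path.
#' @export
writeConfig <- function(cfg, file) {
  jsonlite::write_json(unclass(cfg), file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' Ready-to-run configuration for a packaged example model
#'
#' @param name one of `"predator_prey"`, `"rock_paper_scissors"`,
#'   `"immunotherapy"`, `"pufa_oxidation"`.
#' @return config list (see [readConfig()]); write it with [writeConfig()].
#' @export
fixtureConfig <- function(name = c("predator_prey", "rock_paper_scissors",
                                   "immunotherapy", "pufa_oxidation")) {
  name <- match.arg(name)
  fx <- switch(name,
    predator_prey = makePredatorPrey(),
    rock_paper_scissors = makeRockPaperScissors(),
    immunotherapy = makeImmunotherapy(),
    pufa_oxidation = makePufa(p = 0.2))
  g <- fx$graph
  cfg <- list(
    lattice = list(topology = g@topology, extent = g@extent,
                   boundary = g@boundary, D = latticeD(g)),
    model = list(
      species = speciesNames(fx$model),
      reactions = lapply(reactionList(fx$model), function(r)
        list(name = r@name, diagram = formatReaction(r), rate = r@rate))),
    init = local({
      occ <- fx$makeInit()
      which1 <- which(occ != .OPEN)
      if (name %in% c("immunotherapy"))
        list(sites = which1 - 1L, species = occ[which1])
      else
        list(densities = as.list(table(occ[which1]) / nSites(g)))
    }),
    simulation = list(t_final = 100, save_interval = 1, max_events = 1e7,
                      method = "direct", seed = 1, replicates = 1))
  if (name == "pufa_oxidation") {
    occ <- fx$makeInit()
    which1 <- which(occ != .OPEN)
    cfg$init <- list(sites = which1 - 1L, species = occ[which1])
  }
  structure(cfg, class = "ipsConfig")
}

#' Run a configured simulation and write its outputs
#'
#' Executes the configuration with [simulateIPS()] and writes
#' `populations.csv` (`replicate,t,species,count`), a final-state
#' `snapshots.csv` per replicate, `events.log` when event recording is on,
#' and `provenance.json` echoing the fully resolved configuration.
#'
#' @param config path to a JSON config, or a config list.
#' @param outDir output directory (created if needed); `NULL` skips all
#'   file output.
#' @param seed optional override of the configured seed.
#' @param recordEvents keep and write the event log.
#' @return the [simulateIPS()] result, invisibly.
#' @export
runConfig <- function(config, outDir = NULL, seed = NULL,
                      recordEvents = FALSE) {
  cfg <- readConfig(config)
  built <- buildFromConfig(cfg)
  sim <- built$simulation
  if (is.null(seed)) seed <- sim$seed
  res <- simulateIPS(built, tFinal = sim$t_final,
                     saveInterval = sim$save_interval,
                     method = if (is.null(sim$method)) "direct" else sim$method,
                     tau = sim$tau,
                     nReplicates = if (is.null(sim$replicates)) 1 else sim$replicates,
                     seed = seed,
                     maxEvents = if (is.null(sim$max_events)) Inf else sim$max_events,
                     recordEvents = recordEvents)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(res$populations, file.path(outDir, "populations.csv"),
                     row.names = FALSE, quote = FALSE)
    writeSnapshot(res$finalState, file.path(outDir, "snapshots.csv"))
    if (recordEvents) {
      ev <- do.call(rbind, lapply(seq_along(res$trajectories), function(i) {
        e <- res$trajectories[[i]]@events
        if (is.null(e)) NULL else cbind(replicate = i, e)
      }))
      if (!is.null(ev))
        utils::write.csv(ev, file.path(outDir, "events.log"),
                         row.names = FALSE, quote = FALSE)
    }
    resolved <- unclass(cfg)
    resolved$simulation$seed <- seed
    resolved$package <- list(name = "latticeIPS",
                             version = as.character(utils::packageVersion("latticeIPS")))
    jsonlite::write_json(resolved, file.path(outDir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(res)
}
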