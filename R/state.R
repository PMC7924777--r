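#' @include AllClasses.R AllGenerics.R enumeration.R
NULL

# tables in 0-based species codes and 0-based class ids for the C++ core
.coreTables <- function(channels, classes, species) {
  toCode <- function(x) {
    out <- integer(length(x))
    out[is.na(x)] <- -1L
    out[!is.na(x)] <- .speciesCode(x[!is.na(x)], species)
    out
  }
  list(
    classes = list(center = toCode(classes$center),
                   partner = toCode(classes$partner),
                   j = ifelse(is.na(classes$j), 0L, as.integer(classes$j))),
    channels = list(class = as.integer(channels$class - 1L),
                    type = ifelse(channels$type == "pairwise", 0L, 1L),
                    rate = as.numeric(channels$perRate),
                    center = toCode(channels$center),
                    partner = toCode(channels$partner),
                    pc = toCode(channels$pc),
                    pn = toCode(channels$pn),
                    j = ifelse(is.na(channels$j), 0L, as.integer(channels$j))))
}

# channel table augmented with product columns (needed by the core)
.channelsWithProducts <- function(cs) {
  ch <- cs@channels
  rx <- cs@model@reactions
  byName <- match(ch$reaction, vapply(rx, function(r) r@name, ""))
  ch$pc <- vapply(rx[byName], function(r) r@prodCenter, "")
  ch$pn <- vapply(rx[byName], function(r) r@prodNbr, "")
  ch
}

.asOccupancy <- function(occupancy, graph, model) {
  n <- nSites(graph)
  if (is.character(occupancy)) {
    occupancy[is.na(occupancy) | occupancy == ""] <- .OPEN
    occupancy <- .speciesCode(occupancy, model@species)
  }
  occupancy <- as.integer(occupancy)
  if (length(occupancy) != n)
    stop("occupancy must have one entry per site")
  if (any(is.na(occupancy)) || any(occupancy < 0L) ||
      any(occupancy > nSpecies(model)))
    stop("occupancy references undeclared species")
  occupancy
}

#' Initialize the simulation state
#'
#' Builds the full state from an occupancy assignment: per-site
#' neighborhood compositions, sample-class memberships, and channel
#' propensities.  Each site holds at most one particle (volume exclusion),
#' so `occupancy` is a single species code (or name) per site, with 0 for
#' open sites.
#'
#' @param graph a [SiteGraph-class].
#' @param model an [IPSModel-class].
#' @param occupancy integer codes (0 = open, k = `speciesNames(model)[k]`)
#'   or species names per site; see also [randomPlacement()].
#' @param channels optional [ChannelSet-class]; defaults to
#'   `reactionChannels(model, latticeD(graph))`.
#' @param t0 starting time.
#' @return a [SimState-class] (reference semantics).
#' @examples
#' g <- buildLattice("hex2d", c(5, 5))
#' m <- ipsModel("R", list(parseReaction("R + 0 -> R + R", 0.2),
#'                         parseReaction("R -> 0", 0.1)))
#' occ <- integer(nSites(g)); occ[13] <- 1L   # one rabbit mid-lattice
#' st <- initializeState(g, m, occ)
#' totalRate(st)   # 6*0.2 + 0.1
#' @export
initializeState <- function(graph, model, occupancy,
                            channels = reactionChannels(model, latticeD(graph)),
                            t0 = 0) {
  stopifnot(is(graph, "SiteGraph"), is(model, "IPSModel"),
            is(channels, "ChannelSet"))
  if (!identical(channels@model@species, model@species))
    stop("channel set was built for a different model")
  occupancy <- .asOccupancy(occupancy, graph, model)
  tabs <- .coreTables(.channelsWithProducts(channels), channels@classes,
                      model@species)
  ptr <- .ips_core_new(list(neighbors = graph@neighbors), nSpecies(model),
                       latticeD(graph), tabs$classes, tabs$channels,
                       occupancy, as.numeric(t0))
  new("SimState", ptr = ptr, graph = graph, model = model,
      channels = channels)
}

#' Reset a state to a new occupancy
#'
#' Reuses the allocated state core; equivalent to [initializeState()] with
#' the same graph/model/channels but cheaper inside replicate loops.
#'
#' @param state a [SimState-class].
#' @param occupancy as in [initializeState()].
#' @param t0 starting time.
#' @return the state, invisibly (modified in place).
#' @export
resetState <- function(state, occupancy, t0 = 0) {
  occupancy <- .asOccupancy(occupancy, state@graph, state@model)
  .ips_core_reset(state@ptr, occupancy, as.numeric(t0))
  invisible(state)
}

#' Apply a specific event to the state
#'
#' Executes one reaction event: occupancies change per the reaction's
#' positional products, and compositions, class memberships and
#' propensities are updated locally (only the changed sites and their
#' neighbors are touched).  Preconditions are checked: the center site must
#' be a member of the channel's sample class and, for pairwise channels,
#' the neighbor site must be adjacent with the required occupancy; a
#' violation signals bookkeeping corruption and raises an error.
#'
#' @param state a [SimState-class] (modified in place).
#' @param channel channel index (row of `channelTable(state@channels)`).
#' @param center center site index (1-based).
#' @param neighbor neighbor site index for pairwise channels, `NA` for
#'   on-site channels.
#' @param dt time increment added to the state clock.
#' @return one-row data.frame event record: `t`, `channel`, `center`,
#'   `neighbor`, old and new occupancies.
#' @export
applyEvent <- function(state, channel, center, neighbor = NA, dt = 0) {
  rec <- .ips_core_apply(state@ptr, as.integer(channel), as.integer(center),
                         if (is.na(neighbor)) 0L else as.integer(neighbor),
                         as.numeric(dt))
  as.data.frame(rec)
}

#' Fire a channel, sampling the participating particles
#'
#' The center particle is drawn uniformly from the channel's sample class;
#' for pairwise channels the partner is drawn uniformly among the center's
#' `j` qualifying neighbors.  The event is then applied as in
#' [applyEvent()].
#'
#' @inheritParams applyEvent
#' @return one-row data.frame event record.
#' @export
fireChannel <- function(state, channel, dt = 0) {
  rec <- .ips_core_fire(state@ptr, as.integer(channel), as.numeric(dt))
  as.data.frame(rec)
}

#' Rebuild the state from scratch (global update)
#'
#' Scans the lattice and reconstructs compositions, class memberships and
#' propensities from the occupancy alone.  This is the "global update"
#' counterpart of the incremental local updates, and serves as the
#' correctness oracle for [applyEvent()]: after any event sequence,
#' `rebuildGlobal(state)` must agree with the incrementally maintained
#' state.
#'
#' @param state a [SimState-class].
#' @return a fresh, independent [SimState-class] with the same occupancy
#'   and clock.
#' @export
rebuildGlobal <- function(state)
  initializeState(state@graph, state@model, occupancy(state),
                  channels = state@channels, t0 = simTime(state))

#' Comparable snapshot of the full state
#'
#' Extracts occupancy, compositions, memberships (sorted, so comparable as
#' sets), class sizes, propensities and the clock into plain R objects, for
#' oracle-equivalence checks.
#'
#' @param state a [SimState-class].
#' @return named list.
#' @export
stateSnapshot <- function(state) {
  s <- .ips_core_snapshot(state@ptr)
  s$members <- lapply(s$members, sort)
  s
}

#' Random initial placement
#'
#' Draws an occupancy vector with the given per-species densities: each
#' species receives `round(density * nSites)` particles on sites sampled
#' without replacement (volume exclusion holds by construction).  Uses the
#' current RNG stream; call `set.seed()` first for reproducibility.
#'
#' @param graph a [SiteGraph-class].
#' @param densities named numeric vector of site fractions per species
#'   (names are species; total must be <= 1).
#' @return character occupancy vector of species names, with `"0"` for
#'   open sites; pass it to [initializeState()].
#' @export
randomPlacement <- function(graph, densities) {
  n <- nSites(graph)
  if (sum(densities) > 1 + 1e-9) stop("total density exceeds 1")
  counts <- round(densities * n)
  occ <- rep(.OPEN, n)
  free <- seq_len(n)
  for (sp in names(densities)) {
    k <- counts[[sp]]
    if (k < 1) next
    pick <- sample(length(free), k)
    occ[free[pick]] <- sp
    free <- free[-pick]
  }
  occ
}

#' @describeIn initializeState current occupancy codes.
#' @param x a [SimState-class].
#' @export
setMethod("occupancy", "SimState",
          function(x) .ips_core_snapshot(x@ptr)$occupancy)

#' @rdname initializeState
#' @export
setMethod("compositions", "SimState", function(x) {
  cm <- .ips_core_snapshot(x@ptr)$composition
  rownames(cm) <- c(.OPEN, x@model@species)
  cm
})

#' @rdname initializeState
#' @export
setMethod("classMembers", "SimState",
          function(x) .ips_core_snapshot(x@ptr)$members)

#' @rdname initializeState
#' @export
setMethod("classSizes", "SimState",
          function(x) .ips_core_snapshot(x@ptr)$classSizes)

#' @rdname initializeState
#' @export
setMethod("propensities", "SimState", function(x) .ips_core_lambda(x@ptr))

#' @rdname initializeState
#' @export
setMethod("totalRate", "SimState", function(x) sum(.ips_core_lambda(x@ptr)))

#' @rdname initializeState
#' @export
setMethod("simTime", "SimState", function(x) .ips_core_snapshot(x@ptr)$t)

#' @rdname initializeState
#' @export
setMethod("populations", "SimState", function(x, ...) {
  p <- .ips_core_snapshot(x@ptr)$populations
  names(p) <- c(.OPEN, x@model@species)
  p
})

setMethod("show", "SimState", function(object) {
  s <- .ips_core_snapshot(object@ptr)
  pops <- s$populations
  names(pops) <- c("open", object@model@species)
  cat(sprintf("SimState at t = %g: %d sites, lambda0 = %g\n", s$t,
              nSites(object@graph), s$lambda0))
  cat("  populations:", paste(sprintf("%s=%d", names(pops), pops),
                              collapse = ", "), "\n")
})

#' Write a lattice snapshot as CSV
#'
#' Emits one row per site with the simulation time, the 0-based site index,
#' the site coordinates and the species name, so downstream tools need no
#' knowledge of site indexing.
#'
#' @param state a [SimState-class].
#' @param file path of the CSV to write (or a connection).
#' @param includeOpen if `TRUE`, open sites are written with species `"0"`;
#'   by default they are omitted.
#' @param append append to an existing file (suppresses the header).
#' @return the written data.frame, invisibly.
#' @export
writeSnapshot <- function(state, file, includeOpen = FALSE, append = FALSE) {
  occ <- occupancy(state)
  xy <- siteCoords(state@graph)
  df <- data.frame(t = simTime(state), site = seq_along(occ) - 1L, xy,
                   species = c(.OPEN, state@model@species)[occ + 1L])
  if (!includeOpen) df <- df[occ > 0L, , drop = FALSE]
  utils::write.table(df, file, sep = ",", row.names = FALSE,
                     col.names = !append, append = append, quote = FALSE)
  invisible(df)
}
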