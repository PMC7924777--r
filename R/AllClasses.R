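#' @title Class definitions
#' @description Internal S4 class definitions for latticeIPS.
#' @name latticeIPS-classes
#' @keywords internal
NULL

#' SiteGraph: the spatial domain of an interacting particle system
#'
#' A finite graph of lattice sites with explicit neighbor lists.  Regular
#' lattices (square, hexagonal, simple cubic) are built with
#' [buildLattice()]; arbitrary graphs with [fromAdjacency()].
#'
#' @slot nSites number of sites.
#' @slot neighbors list of integer vectors; `neighbors[[s]]` are the sites
#'   adjacent to site `s` (1-based).
#' @slot coords integer matrix of per-site coordinates (axial coordinates
#'   for hexagonal lattices), one row per site.
#' @slot D nominal maximum neighborhood size; drives how many reaction
#'   channels each pairwise reaction is split into.
#' @slot topology one of `"square2d"`, `"hex2d"`, `"cubic3d"`, `"custom"`.
#' @slot boundary `"closed"` or `"periodic"` (`"custom"` graphs use `"none"`).
#' @slot extent per-dimension lattice size (empty for custom graphs).
#'
#' @export
setClass("SiteGraph",
  representation(nSites = "integer", neighbors = "list", coords = "matrix",
                 D = "integer", topology = "character", boundary = "character",
                 extent = "integer"))

setValidity("SiteGraph", function(object) {
  n <- object@nSites
  nb <- object@neighbors
  if (length(nb) != n) return("length(neighbors) != nSites")
  for (s in seq_len(n)) {
    v <- nb[[s]]
    if (anyNA(v) || any(v < 1L) || any(v > n))
      return(sprintf("site %d: neighbor index out of range", s))
    if (any(v == s)) return(sprintf("site %d: self-loop", s))
    if (anyDuplicated(v)) return(sprintf("site %d: duplicate neighbor", s))
    if (length(v) > object@D)
      return(sprintf("site %d: degree exceeds D", s))
  }
  # adjacency symmetry
  for (s in seq_len(n))
    for (v in nb[[s]])
      if (!(s %in% nb[[v]]))
        return(sprintf("adjacency not symmetric between sites %d and %d", s, v))
  TRUE
})

#' Reaction: one on-site or pairwise reaction
#'
#' Reactions are written positionally: the first reactant occupies the
#' center site and the second (pairwise only) an adjacent site; the first
#' product replaces the center, the second the neighbor.  The token `"0"`
#' denotes an open site.  Build with [parseReaction()].
#'
#' @slot name reaction label.
#' @slot rtype `"on_site"` or `"pairwise"`.
#' @slot center,nbr reactant species names (`"0"` = open; `nbr` is `NA` for
#'   on-site reactions).
#' @slot prodCenter,prodNbr product species names, positionally.
#' @slot rate mass-action rate constant (1/time per particle for on-site,
#'   1/time per ordered center-neighbor pair for pairwise).
#'
#' @export
setClass("Reaction",
  representation(name = "character", rtype = "character",
                 center = "character", nbr = "character",
                 prodCenter = "character", prodNbr = "character",
                 rate = "numeric"))

setValidity("Reaction", function(object) {
  if (!object@rtype %in% c("on_site", "pairwise")) return("unknown rtype")
  if (length(object@rate) != 1 || is.na(object@rate) || object@rate < 0)
    return("rate must be a single nonnegative number")
  if (object@rtype == "on_site") {
    if (!is.na(object@nbr) || !is.na(object@prodNbr))
      return("on-site reaction must have empty neighbor slots")
  } else {
    if (is.na(object@nbr) || is.na(object@prodNbr))
      return("pairwise reaction must fill both neighbor slots")
  }
  TRUE
})

#' IPSModel: species and reactions of an interacting particle system
#'
#' @slot species character vector of species names (the open site `"0"` is
#'   not a species and is never listed).
#' @slot reactions list of [Reaction-class] objects.
#'
#' @export
setClass("IPSModel",
  representation(species = "character", reactions = "list"))

#' ChannelSet: reaction channels and sample classes for a model
#'
#' Expansion of a model for a lattice with nominal neighborhood size `D`:
#' each pairwise reaction is split into `D` reaction channels (one per
#' number `j` of adjacent reactants, with per-particle rate `j * k`), and
#' channels sharing the same ordered reactant pair and the same `j` share a
#' sample class.  Built with [reactionChannels()].
#'
#' @slot model the [IPSModel-class].
#' @slot D nominal neighborhood size used for the expansion.
#' @slot channels data.frame with one row per channel: `channel`,
#'   `reaction`, `type`, `center`, `partner`, `j`, `perRate`, `class`.
#' @slot classes data.frame with one row per sample class: `class`,
#'   `center`, `partner`, `j` (`partner`/`j` are `NA` for on-site classes).
#'
#' @export
setClass("ChannelSet",
  representation(model = "IPSModel", D = "integer",
                 channels = "data.frame", classes = "data.frame"))

#' SimState: full simulation state with reference semantics
#'
#' Holds occupancy, per-site neighborhood compositions, sample-class
#' memberships and propensities.  The state data live in an external
#' pointer maintained by compiled code, so `SimState` objects have
#' reference semantics: [applyEvent()], [fireChannel()], [runDirectSSA()]
#' and friends modify the object in place.  Use [rebuildGlobal()] to obtain
#' an independent copy rebuilt from occupancy alone.
#'
#' @slot ptr external pointer to the state core.
#' @slot graph the [SiteGraph-class].
#' @slot model the [IPSModel-class].
#' @slot channels the [ChannelSet-class].
#'
#' @export
setClass("SimState",
  representation(ptr = "externalptr", graph = "SiteGraph",
                 model = "IPSModel", channels = "ChannelSet"))

#' Trajectory: time-stamped population counts from one simulation run
#'
#' @slot times save-grid time points.
#' @slot counts integer matrix, one row per time point; columns are the
#'   open-site count (`"0"`) followed by the species.
#' @slot status one of `"t_final"`, `"absorbed"`, `"max_events"`.
#' @slot nEvents number of events fired.
#' @slot skipped number of infeasible tau-leap events skipped (0 for the
#'   exact method).
#' @slot events event log (`data.frame` with columns `t`, `channel`,
#'   `center`, `neighbor`) or `NULL`.
#'
#' @export
setClass("Trajectory",
  representation(times = "numeric", counts = "matrix", status = "character",
                 nEvents = "numeric", skipped = "numeric", events = "ANY"))

#' ExactCTMC: brute-force continuous-time Markov chain on a tiny graph
#'
#' Exhaustive enumeration of all occupancy configurations of a small site
#' graph together with the full generator matrix, used as an independent
#' oracle for the sampler.  Built with [enumerateCTMC()].
#'
#' @slot states integer matrix, one row per configuration (occupancy codes,
#'   0 = open).
#' @slot Q sparse generator matrix (off-diagonal entries are transition
#'   rates; rows sum to zero).
#' @slot graph the [SiteGraph-class].
#' @slot model the [IPSModel-class].
#'
#' @export
setClass("ExactCTMC",
  representation(states = "matrix", Q = "ANY",
                 graph = "SiteGraph", model = "IPSModel"))
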