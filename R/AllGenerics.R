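#' @include AllClasses.R
NULL

#' Number of sites in a site graph
#' @param x a [SiteGraph-class] or an object holding one.
#' @return integer scalar.
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' Per-site neighbor lists
#' @param x a [SiteGraph-class] or an object holding one.
#' @return list of integer vectors (1-based site indices).
#' @export
setGeneric("neighborList", function(x) standardGeneric("neighborList"))

#' Per-site degrees
#' @param x a [SiteGraph-class].
#' @return integer vector of neighbor counts.
#' @export
setGeneric("siteDegrees", function(x) standardGeneric("siteDegrees"))

#' Site coordinates
#' @param x a [SiteGraph-class].
#' @return integer matrix, one row per site.
#' @export
setGeneric("siteCoords", function(x) standardGeneric("siteCoords"))

#' Nominal maximum neighborhood size D
#' @param x a [SiteGraph-class] or [ChannelSet-class].
#' @return integer scalar.
#' @export
setGeneric("latticeD", function(x) standardGeneric("latticeD"))

#' Species names of a model
#' @param x an [IPSModel-class] or an object holding one.
#' @return character vector (excluding the open site).
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' Number of occupied species types L
#' @param x an [IPSModel-class] or an object holding one.
#' @return integer scalar.
#' @export
setGeneric("nSpecies", function(x) standardGeneric("nSpecies"))

#' Reactions of a model
#' @param x an [IPSModel-class] or an object holding one.
#' @return list of [Reaction-class] objects.
#' @export
setGeneric("reactionList", function(x) standardGeneric("reactionList"))

#' Number of reaction channels
#' @param x a [ChannelSet-class].
#' @return integer scalar, equal to D x (number of pairwise reactions) +
#'   (number of on-site reactions).
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' Number of sample classes
#' @param x a [ChannelSet-class].
#' @return integer scalar, equal to D x (number of unique ordered reactant
#'   pairs) + (number of unique on-site reactants).
#' @export
setGeneric("nClasses", function(x) standardGeneric("nClasses"))

#' Channel table
#' @param x a [ChannelSet-class].
#' @return data.frame, one row per reaction channel.
#' @export
setGeneric("channelTable", function(x) standardGeneric("channelTable"))

#' Sample-class table
#' @param x a [ChannelSet-class].
#' @return data.frame, one row per sample class.
#' @export
setGeneric("classTable", function(x) standardGeneric("classTable"))

#' Current occupancy
#' @param x a [SimState-class].
#' @return integer vector of species codes per site (0 = open); species
#'   code k corresponds to `speciesNames(x)[k]`.
#' @export
setGeneric("occupancy", function(x) standardGeneric("occupancy"))

#' Per-site neighborhood compositions
#' @param x a [SimState-class].
#' @return integer matrix with L+1 rows (open sites first) and one column
#'   per site; column s is the count vector of species among the neighbors
#'   of site s.
#' @export
setGeneric("compositions", function(x) standardGeneric("compositions"))

#' Sample-class memberships
#' @param x a [SimState-class].
#' @return list of integer vectors, one per sample class, giving the sites
#'   currently eligible as that class's center.
#' @export
setGeneric("classMembers", function(x) standardGeneric("classMembers"))

#' Sample-class sizes
#' @param x a [SimState-class].
#' @return integer vector of class sizes.
#' @export
setGeneric("classSizes", function(x) standardGeneric("classSizes"))

#' Per-channel propensities
#' @param x a [SimState-class].
#' @return numeric vector: per-particle rate times sample-class size, per
#'   channel (units 1/time).
#' @export
setGeneric("propensities", function(x) standardGeneric("propensities"))

#' Total propensity
#' @param x a [SimState-class].
#' @return numeric scalar, the sum of all channel propensities.
#' @export
setGeneric("totalRate", function(x) standardGeneric("totalRate"))

#' Current simulation time
#' @param x a [SimState-class].
#' @return numeric scalar.
#' @export
setGeneric("simTime", function(x) standardGeneric("simTime"))

#' Population counts
#' @param x a [SimState-class] or [Trajectory-class].
#' @param ... unused.
#' @return for a state, a named integer vector of particle counts per
#'   species (plus `"0"` for open sites); for a trajectory, a long
#'   data.frame with columns `t`, `species`, `count`.
#' @export
setGeneric("populations", function(x, ...) standardGeneric("populations"))
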