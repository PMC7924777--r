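#' @include AllClasses.R AllGenerics.R model.R
NULL

#' Expand a model into reaction channels and sample classes
#'
#' Every pairwise reaction is split into `D` reaction channels, one per
#' number `j = 1..D` of adjacent reactants of the partner type; the j-th
#' channel has per-particle rate `j * k`.  On-site reactions contribute one
#' channel each with per-particle rate `k`.  The total channel count is
#' therefore `D * P + O` for `P` pairwise and `O` on-site reactions.
#'
#' Channels whose reactions share the same ordered (center, partner)
#' reactant pair and the same `j` draw their firing particle from the same
#' sample class (e.g. migration and reproduction of the same species), so
#' the number of classes is `D * U + V` with `U` unique ordered reactant
#' pairs and `V` unique on-site reactants, and never exceeds the number of
#' channels.
#'
#' Ordering is deterministic: pairwise reactions in declaration order, `j`
#' ascending, then on-site reactions in declaration order; classes are
#' numbered by first appearance in that ordering.
#'
#' @param model an [IPSModel-class].
#' @param D positive integer, the nominal neighborhood size of the target
#'   lattice (see [buildLattice()]).
#' @return a [ChannelSet-class].
#' @examples
#' m <- ipsModel("A", list(parseReaction("A + 0 -> A + A", 0.4),
#'                         parseReaction("A + 0 -> 0 + A", 1.0),
#'                         parseReaction("A -> 0", 0.1)))
#' cs <- reactionChannels(m, D = 4)
#' nChannels(cs)   # 4*2 + 1 = 9
#' nClasses(cs)    # 4*1 + 1 = 5 (fission and migration share classes)
#' @export
reactionChannels <- function(model, D) {
  D <- as.integer(D)
  if (is.na(D) || D < 1L) stop("D must be a positive integer")
  diag <- validateModel(model)
  if (length(diag))
    stop("model does not validate:\n  ", paste(diag, collapse = "\n  "))

  rx <- model@reactions
  rtypes <- vapply(rx, function(r) r@rtype, "")
  ord <- c(which(rtypes == "pairwise"), which(rtypes == "on_site"))

  chan <- list()
  classKey <- character(0)
  classDef <- list()
  classOf <- function(key, def) {
    i <- match(key, classKey)
    if (is.na(i)) {
      classKey[[length(classKey) + 1L]] <<- key
      classDef[[length(classDef) + 1L]] <<- def
      i <- length(classKey)
    }
    i
  }

  for (i in ord) {
    r <- rx[[i]]
    if (r@rtype == "pairwise") {
      for (j in seq_len(D)) {
        cl <- classOf(sprintf("P|%s|%s|%d", r@center, r@nbr, j),
                      list(center = r@center, partner = r@nbr, j = j))
        chan[[length(chan) + 1L]] <- data.frame(
          reaction = r@name, type = "pairwise", center = r@center,
          partner = r@nbr, j = j, perRate = j * r@rate, class = cl,
          stringsAsFactors = FALSE)
      }
    } else {
      cl <- classOf(sprintf("O|%s", r@center),
                    list(center = r@center, partner = NA_character_, j = NA_integer_))
      chan[[length(chan) + 1L]] <- data.frame(
        reaction = r@name, type = "on_site", center = r@center,
        partner = NA_character_, j = NA_integer_, perRate = r@rate, class = cl,
        stringsAsFactors = FALSE)
    }
  }
  channels <- do.call(rbind, chan)
  channels <- cbind(channel = seq_len(nrow(channels)), channels)
  classes <- data.frame(
    class = seq_along(classDef),
    center = vapply(classDef, `[[`, "", "center"),
    partner = vapply(classDef, `[[`, "", "partner"),
    j = vapply(classDef, function(d) as.integer(d$j), 1L),
    stringsAsFactors = FALSE)

  new("ChannelSet", model = model, D = D, channels = channels,
      classes = classes)
}

#' Enumerate reaction channels
#'
#' Convenience view of [reactionChannels()] returning only the channel
#' table.
#'
#' @inheritParams reactionChannels
#' @return data.frame with one row per reaction channel.
#' @export
enumerateChannels <- function(model, D) channelTable(reactionChannels(model, D))

#' Enumerate sample classes
#'
#' Convenience view of [reactionChannels()] returning the class table and
#' the channel-to-class assignment.
#'
#' @inheritParams reactionChannels
#' @return list with `classes` (data.frame, one row per sample class) and
#'   `channelClass` (integer vector mapping channel index to class index).
#' @export
enumerateSampleClasses <- function(model, D) {
  cs <- reactionChannels(model, D)
  list(classes = classTable(cs), channelClass = cs@channels$class)
}

#' @describeIn reactionChannels number of reaction channels.
#' @param x a [ChannelSet-class].
#' @export
setMethod("nChannels", "ChannelSet", function(x) nrow(x@channels))

#' @rdname reactionChannels
#' @export
setMethod("nClasses", "ChannelSet", function(x) nrow(x@classes))

#' @rdname reactionChannels
#' @export
setMethod("channelTable", "ChannelSet", function(x) x@channels)

#' @rdname reactionChannels
#' @export
setMethod("classTable", "ChannelSet", function(x) x@classes)

#' @rdname reactionChannels
#' @export
setMethod("latticeD", "ChannelSet", function(x) x@D)

setMethod("show", "ChannelSet", function(object) {
  cat(sprintf("ChannelSet: %d channels, %d sample classes (D = %d)\n",
              nChannels(object), nClasses(object), object@D))
  print(utils::head(object@channels, 12))
  if (nChannels(object) > 12) cat(sprintf("  ... %d more channels\n",
                                          nChannels(object) - 12))
})

#' Write the channel/class table as CSV
#'
#' Machine-readable analogue of the channel table: columns `channel`,
#' `reaction`, `j`, `per_particle_rate`, `sample_class`.
#'
#' @param channelSet a [ChannelSet-class].
#' @param file path of the CSV to write.
#' @return the written data.frame, invisibly.
#' @export
writeChannelTable <- function(channelSet, file) {
  ch <- channelTable(channelSet)
  out <- data.frame(channel = ch$channel, reaction = ch$reaction, j = ch$j,
                    per_particle_rate = ch$perRate, sample_class = ch$class)
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Count neighborhood compositions
#'
#' Number of ways `L` species (plus open sites) can be distributed over a
#' neighborhood of `D` sites, by stars and bars: `choose(D + L, L)`.
#'
#' @param D nonnegative integer neighborhood size.
#' @param L nonnegative integer number of species.
#' @return integer count.
#' @examples
#' countConfigs(4, 2)   # 15
#' countConfigs(6, 1)   # 7
#' @export
countConfigs <- function(D, L) {
  stopifnot(D >= 0, L >= 0)
  as.integer(round(choose(D + L, L)))
}

#' Rank and unrank neighborhood compositions
#'
#' A neighborhood composition is a length-(L+1) vector of nonnegative
#' counts (open sites first, then each species) summing to the site's
#' degree.  `compositionRank` maps a composition to its 0-based index in
#' lexicographic order; `compositionUnrank` inverts it.  For fixed
#' `(degree, L)` the two are mutually inverse bijections onto
#' `0 .. choose(degree + L, L) - 1`.
#'
#' @param counts integer vector of length L+1, nonnegative, summing to the
#'   degree.
#' @return `compositionRank`: 0-based integer rank.
#' @examples
#' compositionRank(c(0, 0, 4))          # 0, the lexicographically smallest
#' compositionUnrank(0, degree = 4, L = 2)
#' @export
compositionRank <- function(counts) {
  counts <- as.integer(counts)
  if (any(is.na(counts)) || any(counts < 0)) stop("negative or missing counts")
  q <- length(counts)           # L + 1 slots
  rem <- sum(counts)
  rank <- 0
  for (i in seq_len(q - 1L)) {
    slots <- q - i              # positions after i
    v <- seq_len(counts[i]) - 1L
    if (length(v))
      rank <- rank + sum(choose(rem - v + slots - 1L, slots - 1L))
    rem <- rem - counts[i]
  }
  as.integer(round(rank))
}

#' @rdname compositionRank
#' @param rank 0-based rank.
#' @param degree neighborhood size (sum of the composition).
#' @param L number of species.
#' @return `compositionUnrank`: integer composition vector of length L+1.
#' @export
compositionUnrank <- function(rank, degree, L) {
  K <- choose(degree + L, L)
  if (rank < 0 || rank >= K) stop("rank out of range")
  counts <- integer(L + 1L)
  rem <- as.integer(degree)
  for (i in seq_len(L)) {
    slots <- L + 1L - i
    v <- 0L
    repeat {
      block <- choose(rem - v + slots - 1L, slots - 1L)
      if (rank < block) break
      rank <- rank - block
      v <- v + 1L
    }
    counts[i] <- v
    rem <- rem - v
  }
  counts[L + 1L] <- rem
  counts
}
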