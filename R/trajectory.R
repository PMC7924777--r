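#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn summarizeTrajectories long-format population counts of one
#'   trajectory (open sites omitted).
#' @param x a [Trajectory-class].
#' @param includeOpen include the open-site count as species `"0"`.
#' @param ... unused.
#' @export
setMethod("populations", "Trajectory", function(x, includeOpen = FALSE, ...) {
  cn <- colnames(x@counts)
  keep <- if (includeOpen) cn else setdiff(cn, "0")
  data.frame(
    t = rep(x@times, times = length(keep)),
    species = rep(keep, each = length(x@times)),
    count = as.vector(x@counts[, keep, drop = FALSE]))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d save points, %g events, status '%s'",
              length(object@times), object@nEvents, object@status))
  if (object@skipped > 0)
    cat(sprintf(" (%g infeasible tau-leap events skipped)", object@skipped))
  cat("\n  final counts:",
      paste(sprintf("%s=%d", colnames(object@counts),
                    object@counts[nrow(object@counts), ]), collapse = ", "),
      "\n")
})

#' Summary statistics across replicate trajectories
#'
#' Cross-replicate mean and variance of each species count at every shared
#' save-grid time point, plus per-replicate extinction times (first save
#' point at which a species count hits zero; `NA` if it never does).
#'
#' @param trajectories list of [Trajectory-class] objects on a common save
#'   grid (e.g. from [simulateIPS()]).
#' @return list with `summary` (data.frame: `t`, `species`, `mean`, `var`,
#'   `n`) and `extinction` (data.frame: `replicate`, `species`, `time`).
#' @export
summarizeTrajectories <- function(trajectories) {
  if (!length(trajectories)) stop("need at least one trajectory")
  if (is(trajectories, "Trajectory")) trajectories <- list(trajectories)
  times <- trajectories[[1]]@times
  species <- setdiff(colnames(trajectories[[1]]@counts), "0")
  nt <- min(vapply(trajectories, function(tr) length(tr@times), 1L))
  times <- times[seq_len(nt)]

  summ <- do.call(rbind, lapply(species, function(sp) {
    m <- vapply(trajectories, function(tr) as.numeric(tr@counts[seq_len(nt), sp]),
                numeric(nt))
    m <- matrix(m, nrow = nt)
    data.frame(t = times, species = sp,
               mean = rowMeans(m),
               var = apply(m, 1L, stats::var),
               n = length(trajectories))
  }))
  ext <- do.call(rbind, lapply(seq_along(trajectories), function(i) {
    tr <- trajectories[[i]]
    do.call(rbind, lapply(species, function(sp) {
      hit <- which(tr@counts[, sp] == 0L)
      data.frame(replicate = i, species = sp,
                 time = if (length(hit)) tr@times[hit[1L]] else NA_real_)
    }))
  }))
  list(summary = summ, extinction = ext)
}

#' Final count of a species in a trajectory
#'
#' Convenience accessor used e.g. for the depleted-chain length of the
#' lipid-oxidation example (the number of depleted sites once the walker is
#' trapped).
#'
#' @param trajectory a [Trajectory-class].
#' @param species species name.
#' @return integer count at the last save point.
#' @export
finalCount <- function(trajectory, species) {
  stopifnot(is(trajectory, "Trajectory"))
  unname(trajectory@counts[nrow(trajectory@counts), species])
}
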