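#' @include AllClasses.R AllGenerics.R model.R
NULL

# Brute-force validation utilities.  Deliberately written in the plainest
# possible style, sharing no code with the simulation core, so that
# agreement between the two is evidence of correctness rather than a
# tautology.

#' Total reaction rate by direct lattice scan
#'
#' Computes the total propensity the rudimentary way: scan every site, sum
#' the per-particle rates of every reaction it can undergo given its actual
#' neighborhood (j adjacent partners contribute `j * k` for a pairwise
#' reaction with rate constant `k`).  No channel or class bookkeeping is
#' used; this is the independent oracle for `totalRate()`.
#'
#' @param occupancy integer occupancy codes (0 = open) or species names.
#' @param model an [IPSModel-class].
#' @param graph a [SiteGraph-class].
#' @return total rate (1/time).
#' @export
naiveTotalRate <- function(occupancy, model, graph) {
  occupancy <- .asOccupancy(occupancy, graph, model)
  species <- model@species
  total <- 0
  for (s in seq_len(nSites(graph))) {
    here <- occupancy[s]
    hereName <- if (here == 0L) .OPEN else species[here]
    for (r in model@reactions) {
      if (r@center != hereName) next
      if (r@rtype == "on_site") {
        total <- total + r@rate
      } else {
        j <- 0
        for (v in graph@neighbors[[s]]) {
          vName <- if (occupancy[v] == 0L) .OPEN else species[occupancy[v]]
          if (vName == r@nbr) j <- j + 1
        }
        total <- total + j * r@rate
      }
    }
  }
  total
}

#' Exhaustive CTMC enumeration on a tiny graph
#'
#' Enumerates every occupancy configuration of a small site graph and
#' builds the full generator matrix: the rate from configuration `c` to
#' `c'` is the summed rate of all elementary events mapping `c` to `c'`
#' (per ordered center-neighbor pair for pairwise reactions).  Intended as
#' an exact oracle for the sampler on graphs where `(L+1)^nSites <= 1e4`.
#'
#' @param graph a [SiteGraph-class] with few sites.
#' @param model an [IPSModel-class].
#' @return an [ExactCTMC-class].
#' @export
enumerateCTMC <- function(graph, model) {
  n <- nSites(graph)
  L <- nSpecies(model)
  nStates <- (L + 1)^n
  if (nStates > 1e4) stop("state space too large to enumerate")
  species <- model@species
  states <- as.matrix(expand.grid(rep(list(0:L), n)))
  colnames(states) <- NULL
  storage.mode(states) <- "integer"
  idxOf <- function(occ) 1L + sum(occ * (L + 1)^(seq_along(occ) - 1L))

  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  addRate <- function(from, to, rate) {
    ii <<- c(ii, from); jj <<- c(jj, to); vv <<- c(vv, rate)
  }
  nameOf <- function(code) if (code == 0L) .OPEN else species[code]
  codeOf <- function(name) if (name == .OPEN) 0L else match(name, species)

  for (st in seq_len(nStates)) {
    occ <- states[st, ]
    for (s in seq_len(n)) {
      for (r in model@reactions) {
        if (nameOf(occ[s]) != r@center) next
        if (r@rtype == "on_site") {
          occ2 <- occ
          occ2[s] <- codeOf(r@prodCenter)
          if (!identical(occ2, occ)) addRate(st, idxOf(occ2), r@rate)
        } else {
          for (v in graph@neighbors[[s]]) {
            if (nameOf(occ[v]) != r@nbr) next
            occ2 <- occ
            occ2[s] <- codeOf(r@prodCenter)
            occ2[v] <- codeOf(r@prodNbr)
            if (!identical(occ2, occ)) addRate(st, idxOf(occ2), r@rate)
          }
        }
      }
    }
  }
  Q <- Matrix::sparseMatrix(i = ii, j = jj, x = vv,
                            dims = c(nStates, nStates))
  Matrix::diag(Q) <- Matrix::diag(Q) - Matrix::rowSums(Q)
  new("ExactCTMC", states = states, Q = Q, graph = graph, model = model)
}

#' @describeIn enumerateCTMC index of an occupancy configuration in the
#'   enumeration.
#' @param ctmc an [ExactCTMC-class].
#' @param occupancy occupancy codes or species names.
#' @export
ctmcStateIndex <- function(ctmc, occupancy) {
  occ <- .asOccupancy(occupancy, ctmc@graph, ctmc@model)
  L <- nSpecies(ctmc@model)
  as.integer(1 + sum(occ * (L + 1)^(seq_along(occ) - 1)))
}

#' @describeIn enumerateCTMC exact state distribution at time `t` from an
#'   initial configuration, via the matrix exponential of the generator.
#' @param t time.
#' @export
ctmcDistribution <- function(ctmc, occupancy, t) {
  p0 <- numeric(nrow(ctmc@states))
  p0[ctmcStateIndex(ctmc, occupancy)] <- 1
  as.vector(p0 %*% Matrix::expm(ctmc@Q * t))
}

setMethod("show", "ExactCTMC", function(object) {
  cat(sprintf("ExactCTMC: %d configurations of %d sites x %d species\n",
              nrow(object@states), nSites(object@graph),
              nSpecies(object@model)))
})
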