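# Plain brute-force oracles, written independently of the simulation core
# (straight loops over the lattice, no class bookkeeping shared with the
# package internals), so agreement is evidence rather than tautology.

# neighborhood composition + class membership + propensities by full scan
oracleScanState <- function(occ, model, graph, channelSet) {
  n <- nSites(graph)
  species <- speciesNames(model)
  L <- length(species)
  nameOf <- function(code) if (code == 0L) "0" else species[code]
  comp <- matrix(0L, nrow = L + 1, ncol = n)
  for (s in seq_len(n))
    for (v in neighborList(graph)[[s]])
      comp[occ[v] + 1L, s] <- comp[occ[v] + 1L, s] + 1L
  ct <- classTable(channelSet)
  members <- vector("list", nrow(ct))
  for (k in seq_len(nrow(ct))) {
    hits <- integer(0)
    for (s in seq_len(n)) {
      if (nameOf(occ[s]) != ct$center[k]) next
      if (is.na(ct$partner[k])) {
        hits <- c(hits, s)
      } else {
        pcode <- if (ct$partner[k] == "0") 0L else match(ct$partner[k], species)
        if (comp[pcode + 1L, s] == ct$j[k]) hits <- c(hits, s)
      }
    }
    members[[k]] <- hits
  }
  ch <- channelTable(channelSet)
  lam <- numeric(nrow(ch))
  for (r in seq_len(nrow(ch)))
    lam[r] <- ch$perRate[r] * length(members[[ch$class[r]]])
  list(composition = comp, members = members, lambda = lam,
       lambda0 = sum(lam))
}

# full-state agreement between the incremental core, a global rebuild, and
# the plain scan above
expectStateConsistent <- function(state, label = "") {
  snap <- stateSnapshot(state)
  reb <- stateSnapshot(rebuildGlobal(state))
  expect_identical(snap$occupancy, reb$occupancy, label = paste(label, "occupancy"))
  expect_identical(snap$composition, reb$composition, label = paste(label, "composition"))
  expect_identical(snap$members, reb$members, label = paste(label, "members"))
  expect_equal(snap$lambda, reb$lambda, tolerance = 1e-9,
               label = paste(label, "lambda"))
  scan <- oracleScanState(snap$occupancy, state@model, state@graph,
                          state@channels)
  expect_identical(snap$composition, unname(scan$composition))
  expect_identical(snap$members, lapply(scan$members, as.integer))
  expect_equal(snap$lambda, scan$lambda, tolerance = 1e-9)
  expect_equal(snap$lambda0, sum(snap$lambda), tolerance = 1e-9)
  expect_true(all(snap$lambda >= 0))
  invisible(snap)
}

# exhaustive enumeration of neighborhood compositions (for count/rank checks)
enumCompositions <- function(d, L) {
  grid <- do.call(expand.grid, rep(list(0:d), L + 1))
  grid <- grid[rowSums(grid) == d, , drop = FALSE]
  m <- as.matrix(grid)
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  # lexicographic order of the count vectors
  m[do.call(order, as.data.frame(m)), , drop = FALSE]
}

# rudimentary direct-method sampler: rescan the whole lattice every event
naiveGillespie <- function(occ, model, graph, tFinal) {
  species <- speciesNames(model)
  nameOf <- function(code) if (code == 0L) "0" else species[code]
  codeOf <- function(nm) if (nm == "0") 0L else match(nm, species)
  t <- 0
  repeat {
    centers <- integer(0); nbrs <- integer(0); rates <- numeric(0)
    ridx <- integer(0)
    for (s in seq_len(nSites(graph))) {
      for (k in seq_along(reactionList(model))) {
        r <- reactionList(model)[[k]]
        if (r@center != nameOf(occ[s])) next
        if (r@rtype == "on_site") {
          centers <- c(centers, s); nbrs <- c(nbrs, NA_integer_)
          rates <- c(rates, r@rate); ridx <- c(ridx, k)
        } else {
          for (v in neighborList(graph)[[s]]) {
            if (nameOf(occ[v]) != r@nbr) next
            centers <- c(centers, s); nbrs <- c(nbrs, v)
            rates <- c(rates, r@rate); ridx <- c(ridx, k)
          }
        }
      }
    }
    lam0 <- sum(rates)
    if (lam0 <= 0) break
    t <- t + stats::rexp(1, lam0)
    if (t > tFinal) break
    e <- sample.int(length(rates), 1L, prob = rates)
    r <- reactionList(model)[[ridx[e]]]
    occ[centers[e]] <- codeOf(r@prodCenter)
    if (!is.na(nbrs[e])) occ[nbrs[e]] <- codeOf(r@prodNbr)
  }
  occ
}

# chi-square comparison of observed counts against expected probabilities,
# merging low-expectation bins
chisqAgainst <- function(observed, probs, minExpected = 5) {
  n <- sum(observed)
  keep <- probs > 0 | observed > 0
  observed <- observed[keep]; probs <- probs[keep]
  ord <- order(probs)
  observed <- observed[ord]; probs <- probs[ord]
  # pool smallest-expectation bins until all expectations reach the floor
  while (length(probs) > 2 && n * probs[1] < minExpected) {
    probs[2] <- probs[2] + probs[1]
    observed[2] <- observed[2] + observed[1]
    probs <- probs[-1]; observed <- observed[-1]
  }
  stats::chisq.test(observed, p = probs / sum(probs))
}
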