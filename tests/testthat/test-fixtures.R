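test_that("every packaged model validates and starts volume-excluded", {
  set.seed(1)
  fixtures <- list(makePredatorPrey(lattice = buildLattice("hex2d", c(10, 10))),
                   makeRockPaperScissors(lattice = buildLattice("square2d", c(10, 10), "periodic")),
                   makeImmunotherapy(lattice = buildLattice("square2d", c(12, 12))),
                   makePufa(0.3, buildLattice("square2d", c(11, 11))))
  for (fx in fixtures) {
    expect_length(validateModel(fx$model), 0)
    occ <- fx$makeInit()
    expect_length(occ, nSites(fx$graph))     # one species per site at most
    st <- initializeState(fx$graph, fx$model, occ)
    expect_true(all(occupancy(st) >= 0 & occupancy(st) <= nSpecies(fx$model)))
  }
})

test_that("fixture initial states are seed-deterministic", {
  fx <- makeRockPaperScissors(lattice = buildLattice("square2d", c(10, 10), "periodic"))
  set.seed(123); a <- fx$makeInit()
  set.seed(123); b <- fx$makeInit()
  expect_identical(a, b)
})

test_that("predator-prey with predation off reduces foxes to pure death", {
  mu <- 0.4; tEnd <- 1.2
  fx <- makePredatorPrey(c(predation = 0, reproduction = 0.5, migration = 1,
                           death = mu),
                         lattice = buildLattice("hex2d", c(8, 8)),
                         init = c(R = 0.2, F = 0.25))
  set.seed(33)
  res <- simulateIPS(fx, tFinal = tEnd, nReplicates = 250, seed = 40)
  finals <- vapply(res$trajectories, function(tr) finalCount(tr, "F"), 1L)
  N0 <- round(0.25 * 64)
  expected <- N0 * exp(-mu * tEnd)
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - expected), 3 * se)
})

test_that("predator-prey defaults sustain coexistence (spiral-wave regime)", {
  fx <- makePredatorPrey(lattice = buildLattice("hex2d", c(40, 40)))
  res <- simulateIPS(fx, tFinal = 40, nReplicates = 5, seed = 60)
  fin <- t(vapply(res$trajectories, function(tr)
    tr@counts[nrow(tr@counts), c("F", "R")], c(F = 0L, R = 0L)))
  both <- rowSums(fin > 0) == 2
  expect_gte(sum(both), 3)   # majority of replicates keep both species
})

test_that("rock-paper-scissors has the stated reaction complement", {
  fx <- makeRockPaperScissors(lattice = buildLattice("square2d", c(10, 10), "periodic"))
  rx <- reactionList(fx$model)
  types <- vapply(rx, function(r) r@rtype, "")
  expect_equal(sum(types == "pairwise"), 9L)   # birth+migration+predation x3
  expect_equal(sum(types == "on_site"), 3L)
  for (D in c(4, 6))
    expect_equal(nChannels(reactionChannels(fx$model, D)), 9L * D + 3L)
})

test_that("symmetric rock-paper-scissors treats the three species exchangeably", {
  fx <- makeRockPaperScissors(lattice = buildLattice("square2d", c(20, 20), "periodic"))
  res <- simulateIPS(fx, tFinal = 15, nReplicates = 6, seed = 70)
  fin <- t(vapply(res$trajectories, function(tr)
    tr@counts[nrow(tr@counts), c("R", "P", "S")], c(R = 0L, P = 0L, S = 0L)))
  means <- colMeans(fin)
  expect_true(all(means > 0))
  expect_lt(max(means) / min(means), 2.5)   # no systematic winner
})

test_that("fast migration shortens time to first extinction", {
  lat <- buildLattice("square2d", c(12, 12), "periodic")
  extTimes <- function(mig, seeds) {
    vapply(seeds, function(s) {
      fx <- makeRockPaperScissors(
        params = c(birth = 0.6, death = 0.05, migration = mig, predation = 1),
        lattice = lat)
      res <- simulateIPS(fx, tFinal = 600, saveInterval = 5, nReplicates = 1,
                         seed = s)
      tr <- res$trajectories[[1]]
      gone <- apply(tr@counts[, c("R", "P", "S")] == 0, 1, any)
      if (any(gone)) tr@times[which(gone)[1]] else 600
    }, 1.0)
  }
  lo <- extTimes(0.2, 1:15)
  hi <- extTimes(20, 101:115)
  expect_lt(mean(hi), mean(lo))
})

test_that("immunotherapy reductions behave as the reaction wiring dictates", {
  fx0 <- makeImmunotherapy(params = c(birth = 0.3, death = 0.02, migration = 0.3,
                                      influx = 0.02, immMigration = 2, kill = 1,
                                      fibrosis = 0, enter = 0.05, exit = 0.5),
                           lattice = buildLattice("square2d", c(16, 16)))
  res0 <- simulateIPS(fx0, tFinal = 20, nReplicates = 2, seed = 80)
  for (tr in res0$trajectories) {               # no fibrosis source
    expect_equal(finalCount(tr, "Fb"), 0L)
    expect_equal(finalCount(tr, "FI"), 0L)
  }

  fx1 <- makeImmunotherapy(params = c(birth = 0.3, death = 0.02, migration = 0.3,
                                      influx = 0, immMigration = 2, kill = 1,
                                      fibrosis = 0.5, enter = 0.05, exit = 0.5),
                           lattice = buildLattice("square2d", c(16, 16)))
  res1 <- simulateIPS(fx1, tFinal = 20, nReplicates = 2, seed = 81)
  for (tr in res1$trajectories) {               # immune cells never arrive
    expect_equal(finalCount(tr, "I"), 0L)
    expect_equal(finalCount(tr, "Fb"), 0L)
    expect_gt(finalCount(tr, "C"), 0L)          # cancer grows unopposed
  }
})

test_that("immunotherapy defaults grow a fibrotic shell with surviving cancer", {
  fx <- makeImmunotherapy()
  res <- simulateIPS(fx, tFinal = 60, saveInterval = 20, nReplicates = 5, seed = 90)
  ok <- vapply(res$trajectories, function(tr) {
    fb <- tr@counts[, "Fb"]
    tail(fb, 1) > fb[2] && finalCount(tr, "C") > 0
  }, TRUE)
  expect_gte(sum(ok), 3)
})

test_that("a fully deuterated membrane traps the walker immediately", {
  fx <- makePufa(1, buildLattice("square2d", c(21, 21)))
  st <- initializeState(fx$graph, fx$model, fx$makeInit())
  expect_equal(totalRate(st), 0)
  tr <- runDirectSSA(st, tFinal = Inf, maxEvents = 100)
  expect_equal(tr@status, "absorbed")
  expect_equal(finalCount(tr, "Dp"), 0L)
})

test_that("the undeuterated walker self-traps with a finite chain every time", {
  set.seed(19)
  fx <- makePufa(0, buildLattice("square2d", c(101, 101)))
  st <- NULL
  lengths <- vapply(seq_len(200), function(i) {
    if (is.null(st)) st <<- initializeState(fx$graph, fx$model, fx$makeInit())
    else resetState(st, fx$makeInit())
    tr <- runDirectSSA(st, tFinal = Inf, maxEvents = 1e5)
    expect_equal(tr@status, "absorbed")
    finalCount(tr, "Dp")
  }, 1L)
  expect_true(all(is.finite(lengths)))
  expect_true(all(lengths >= 1))
  expect_gt(mean(lengths), 30)    # known scale of 2-D self-trapping walks
  expect_lt(mean(lengths), 150)
})

test_that("makePufa rejects impossible deuteration fractions", {
  expect_error(makePufa(-0.1), "\\[0, 1\\]")
  expect_error(makePufa(1.2), "\\[0, 1\\]")
})

test_that("trajectory summaries behave on edge cases", {
  # constant trajectory: zero variance
  g <- buildLattice("square2d", c(3, 3))
  m <- migrationModel(1)
  occ <- integer(9); occ[5] <- 1L
  st <- initializeState(g, m, occ)
  tr <- runDirectSSA(st, tFinal = 2, saveInterval = 0.5)
  s <- summarizeTrajectories(list(tr, tr))
  expect_true(all(s$summary$var == 0))
  expect_true(all(s$summary$mean == 1))
  expect_true(all(is.na(s$extinction$time)))

  # death process: summary mean tracks the closed form
  mu <- 0.6; N0 <- 25; tEnd <- 1
  md <- pureDeathModel(mu)
  occ <- integer(36); occ[seq_len(N0)] <- 1L
  res <- simulateIPS(buildLattice("square2d", c(6, 6)), model = md, init = occ,
                     tFinal = tEnd, saveInterval = tEnd, nReplicates = 300,
                     seed = 44)
  s <- summarizeTrajectories(res$trajectories)
  fin <- s$summary[s$summary$t == tEnd, ]
  se <- sqrt(fin$var / fin$n)
  expect_lt(abs(fin$mean - N0 * exp(-mu * tEnd)), 3 * se)

  # fully deuterated membranes: all chain lengths zero
  fx <- makePufa(1, buildLattice("square2d", c(9, 9)))
  res <- simulateIPS(fx, tFinal = 5, nReplicates = 3, seed = 46)
  chain <- vapply(res$trajectories, finalCount, 1L, species = "Dp")
  expect_true(all(chain == 0L))
})
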