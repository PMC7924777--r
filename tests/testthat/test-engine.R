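test_that("waiting times follow T = -log(u)/lambda0", {
  expect_equal(sampleTime(2, exp(-1)), 0.5)
  expect_equal(sampleTime(5, 1), 0)
  expect_error(sampleTime(0), "positive")
  expect_error(sampleTime(-1), "positive")
  set.seed(1)
  draws <- vapply(seq_len(1e5), function(i) sampleTime(1), 1.0)
  expect_equal(mean(draws), 1.0, tolerance = 0.01)
})

test_that("channel selection uses the strict-left weak-right cumulative rule", {
  expect_equal(selectChannel(c(1, 1), u = 0.5), 1L)   # boundary goes left
  expect_equal(selectChannel(c(1, 1), u = 0.500001), 2L)
  for (u in c(0.05, 0.4, 0.99))
    expect_equal(selectChannel(c(0, 3), u = u), 2L)   # zero rates never fire
  expect_error(selectChannel(c(0, 0), u = 0.5), "zero")

  set.seed(2)
  picks <- vapply(seq_len(1e5), function(i) selectChannel(c(1, 2, 3)), 1L)
  tab <- tabulate(picks, 3)
  expect_gt(chisq.test(tab, p = c(1, 2, 3) / 6)$p.value, 0.01)
})

test_that("firing samples centers uniformly within a class", {
  m <- pureDeathModel(1)
  g <- buildLattice("square2d", c(4, 4))
  occ <- integer(16); occ[c(2, 7, 9, 14)] <- 1L
  st <- initializeState(g, m, occ)
  set.seed(3)
  picks <- vapply(seq_len(4000), function(i) {
    resetState(st, occ)
    fireChannel(st, 1)$center
  }, 1L)
  tab <- table(factor(picks, levels = c(2, 7, 9, 14)))
  expect_gt(chisq.test(as.vector(tab))$p.value, 0.01)

  occ1 <- integer(16); occ1[6] <- 1L
  resetState(st, occ1)
  expect_equal(fireChannel(st, 1)$center, 6L)   # class of size 1
})

test_that("identical seeds give identical event logs", {
  fx <- makePredatorPrey(lattice = buildLattice("hex2d", c(8, 8)))
  run <- function() {
    set.seed(77)
    st <- initializeState(fx$graph, fx$model, fx$makeInit())
    runDirectSSA(st, tFinal = 2, recordEvents = TRUE)@events
  }
  expect_identical(run(), run())
})

test_that("single-stepping in R reproduces the compiled SSA loop", {
  fx <- makeRockPaperScissors(lattice = buildLattice("square2d", c(6, 6), "periodic"))
  set.seed(55)
  occ <- fx$makeInit()

  set.seed(10)
  st1 <- initializeState(fx$graph, fx$model, occ)
  log1 <- runDirectSSA(st1, tFinal = 0.5, recordEvents = TRUE)@events

  set.seed(10)
  st2 <- initializeState(fx$graph, fx$model, occ)
  recs <- list()
  while (simTime(st2) < 0.5) {
    rec <- stepSSA(st2)
    if (is.null(rec)) break
    if (rec$t > 0.5) break
    recs[[length(recs) + 1]] <- rec
  }
  log2 <- do.call(rbind, recs)
  expect_equal(nrow(log1), nrow(log2))
  expect_equal(log1$t, log2$t)
  expect_equal(log1$channel, log2$channel)
  expect_equal(log1$center, log2$center)
})

test_that("pure death decays as N0 exp(-mu t) (exact engine)", {
  mu <- 0.8; N0 <- 40; tEnd <- 1.5
  g <- buildLattice("square2d", c(8, 8))
  m <- pureDeathModel(mu)
  set.seed(5)
  occ <- integer(64); occ[sample(64, N0)] <- 1L
  finals <- numeric(400)
  st <- initializeState(g, m, occ)
  set.seed(6)
  for (i in seq_along(finals)) {
    resetState(st, occ)
    tr <- runDirectSSA(st, tFinal = tEnd)
    finals[i] <- finalCount(tr, "A")
  }
  expected <- N0 * exp(-mu * tEnd)
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - expected), 3 * se)
})

test_that("a lone migrating particle occupies each of two sites half the time", {
  g <- buildLattice("square2d", c(2, 1))
  m <- migrationModel(1)
  st <- initializeState(g, m, c(1L, 0L))
  set.seed(8)
  tr2 <- runDirectSSA(st, tFinal = 4000, recordEvents = TRUE)
  ev <- tr2@events
  # fraction of time the particle sits on site 1: jump times partition [0, T]
  onFirst <- c(TRUE, ev$center == 2)       # after each event it sits on newNeighbor
  holds <- diff(c(0, ev$t, 4000))
  frac <- sum(holds[onFirst]) / 4000
  expect_equal(frac, 0.5, tolerance = 0.05)
})

test_that("holding times on a two-site migration chain are Exp(gamma)", {
  gamma <- 1.7
  g <- buildLattice("square2d", c(2, 1))
  st <- initializeState(g, migrationModel(gamma), c(1L, 0L))
  set.seed(12)
  tr <- runDirectSSA(st, tFinal = Inf, maxEvents = 1e4, recordEvents = TRUE)
  holds <- diff(c(0, tr@events$t))
  ks <- ks.test(holds, "pexp", gamma)
  expect_gt(ks$p.value, 0.01)
})

test_that("the class-based sampler agrees with a naive lattice-scan Gillespie", {
  m <- birthDeathMigrationModel(b = 1, d = 0.4, m = 0.6)
  g <- buildLattice("square2d", c(4, 4))
  occ <- integer(16); occ[c(6, 7, 10)] <- 1L
  tEnd <- 1.0
  nRep <- 2000

  st <- initializeState(g, m, occ)
  set.seed(31)
  fast <- vapply(seq_len(nRep), function(i) {
    resetState(st, occ)
    finalCount(runDirectSSA(st, tFinal = tEnd), "A")
  }, 1L)
  set.seed(32)
  slow <- vapply(seq_len(nRep), function(i)
    sum(naiveGillespie(occ, m, g, tEnd) > 0), 1L)

  lv <- 0:max(fast, slow)
  tf <- tabulate(fast + 1, length(lv)); ts <- tabulate(slow + 1, length(lv))
  keep <- (tf + ts) > 0
  suppressWarnings(p <- chisq.test(rbind(tf[keep], ts[keep]))$p.value)
  expect_gt(p, 0.01)
})

test_that("tau-leaping with zero propensity fires nothing", {
  g <- buildLattice("square2d", c(3, 3))
  st <- initializeState(g, pureDeathModel(1), integer(9))
  tr <- runTauLeap(st, tau = 0.1, tFinal = 1)
  expect_equal(tr@nEvents, 0)
  expect_equal(tr@status, "absorbed")
})

test_that("small-tau leaping matches the exact death decay", {
  mu <- 1; N0 <- 30; tEnd <- 1
  g <- buildLattice("square2d", c(6, 6))
  m <- pureDeathModel(mu)
  occ <- integer(36); occ[seq_len(N0)] <- 1L
  st <- initializeState(g, m, occ)
  set.seed(14)
  finals <- vapply(seq_len(300), function(i) {
    resetState(st, occ)
    finalCount(runTauLeap(st, tau = 0.02, tFinal = tEnd), "A")
  }, 1L)
  expected <- N0 * exp(-mu * tEnd)
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - expected), 4 * se + 0.5)   # small tau bias floor
})

test_that("shuffling the leap queue changes infeasible-skip counts", {
  # fission (first in channel order) vs death on a 3-site line from a lone
  # particle: unshuffled leaps always try fission before death, so fission
  # is never preempted; shuffled leaps let death fire first and strand the
  # fission event, so they must skip more often -- spatial updates within a
  # leap do not commute
  m <- ipsModel("A", list(parseReaction("A + 0 -> A + A", 0.7, "fission"),
                          parseReaction("A -> 0", 0.7, "death")))
  g <- buildLattice("square2d", c(3, 1))
  runIt <- function(shuffle) {
    st <- initializeState(g, m, c(1L, 0L, 0L))
    total <- 0
    for (i in seq_len(2000)) {
      resetState(st, c(1L, 0L, 0L))
      tr <- runTauLeap(st, tau = 0.7, tFinal = 0.7, shuffle = shuffle)
      total <- total + tr@skipped
    }
    total
  }
  set.seed(15)
  skipShuffled <- runIt(TRUE)
  set.seed(15)
  skipOrdered <- runIt(FALSE)
  expect_gt(skipShuffled, skipOrdered * 1.5)
})
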