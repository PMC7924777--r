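test_that("an empty lattice has zero total rate", {
  g <- buildLattice("square2d", c(4, 4))
  st <- initializeState(g, birthDeathMigrationModel(), integer(16))
  expect_equal(totalRate(st), 0)
  expect_equal(sum(classSizes(st)), 0L)
})

test_that("a lone rabbit carries the hand-computed propensity", {
  beta <- 0.7; gamma <- 1.3; mu <- 0.11
  pp <- makePredatorPrey(c(predation = 0.5, reproduction = beta,
                           migration = gamma, death = mu),
                         lattice = buildLattice("hex2d", c(5, 5)))
  occ <- integer(25); occ[13] <- match("R", speciesNames(pp$model))
  st <- initializeState(pp$graph, pp$model, occ)
  expect_equal(totalRate(st), 6 * beta + 6 * gamma + mu)

  ct <- classTable(st@channels)
  expect_equal(classSizes(st)[ct$center == "R" & !is.na(ct$j) & ct$j == 6], 1L)
  expect_equal(classSizes(st)[ct$center == "R" & is.na(ct$j)], 1L)
  expect_true(all(classSizes(st)[ct$center == "F"] == 0L))
})

test_that("initialization rejects invalid occupancies", {
  g <- buildLattice("square2d", c(3, 3))
  m <- birthDeathMigrationModel()
  expect_error(initializeState(g, m, rep(2L, 9)), "undeclared")
  expect_error(initializeState(g, m, c("A", "B", rep("0", 7))), "undeclared")
  expect_error(initializeState(g, m, integer(5)), "one entry per site")
})

test_that("symmetric pairwise reactions count ordered pairs (2k per adjacent pair)", {
  k <- 0.25
  m <- ipsModel(c("A", "B"), list(parseReaction("A + A -> B + 0", k, "dimerize")))
  g <- buildLattice("square2d", c(3, 1))
  st <- initializeState(g, m, c(1L, 1L, 0L))
  expect_equal(totalRate(st), 2 * k)   # both A's are eligible centers
  expect_equal(naiveTotalRate(c(1L, 1L, 0L), m, g), 2 * k)
})

test_that("migration conserves particle counts and updates locally", {
  m <- migrationModel(2)
  g <- buildLattice("square2d", c(4, 4))
  occ <- integer(16); occ[6] <- 1L
  st <- initializeState(g, m, occ)
  ch <- channelTable(st@channels)
  r <- ch$channel[ch$j == 4][1]
  rec <- fireChannel(st, r, dt = 0.1)
  expect_equal(rec$oldCenter, 1L)
  expect_equal(rec$newCenter, 0L)
  expect_equal(rec$newNeighbor, 1L)
  expect_equal(unname(populations(st)["A"]), 1L)
  expect_equal(simTime(st), 0.1)
  expectStateConsistent(st, "after migration")
})

test_that("a predation event moves the fox out of the one-rabbit class", {
  pp <- predatorPreyModel()
  g <- buildLattice("hex2d", c(5, 5))
  occ <- integer(25)
  fox <- 13L
  occ[fox] <- match("F", speciesNames(pp))
  rabbit <- neighborList(g)[[fox]][1]
  occ[rabbit] <- match("R", speciesNames(pp))
  cs <- reactionChannels(pp, latticeD(g))
  st <- initializeState(g, pp, occ, channels = cs)

  ch <- channelTable(cs)
  predation1 <- ch$channel[ch$reaction == "fox predation" & ch$j == 1]
  cls <- ch$class[ch$channel == predation1]
  expect_true(fox %in% classMembers(st)[[cls]])

  rec <- fireChannel(st, predation1)
  expect_equal(rec$neighbor, rabbit)          # only one qualifying rabbit
  expect_equal(occupancy(st)[rabbit], match("F", speciesNames(pp)))
  expect_false(fox %in% classMembers(st)[[cls]])  # no rabbits left adjacent
  expectStateConsistent(st, "after predation")
})

test_that("apply rejects events whose preconditions fail", {
  m <- birthDeathMigrationModel()
  g <- buildLattice("square2d", c(3, 3))
  occ <- integer(9); occ[5] <- 1L
  st <- initializeState(g, m, occ)
  ch <- channelTable(st@channels)
  death <- ch$channel[ch$type == "on_site"]
  expect_error(applyEvent(st, death, center = 1), "not a member")
  mig1 <- ch$channel[ch$reaction == "migration" & ch$j == 1]
  expect_error(applyEvent(st, mig1, center = 5, neighbor = 4), "neighbor count")
  mig4 <- ch$channel[ch$reaction == "migration" & ch$j == 4]
  expect_error(applyEvent(st, mig4, center = 5, neighbor = 9), "not adjacent")
  expect_error(applyEvent(st, mig4, center = 5), "requires a neighbor")
})

test_that("rebuilding an initialized state is the identity", {
  set.seed(9)
  pp <- makePredatorPrey(lattice = buildLattice("hex2d", c(6, 6)))
  st <- initializeState(pp$graph, pp$model, pp$makeInit())
  expect_identical(stateSnapshot(st), stateSnapshot(rebuildGlobal(st)))
  # and on an empty lattice
  st0 <- initializeState(pp$graph, pp$model, integer(36))
  expect_equal(totalRate(rebuildGlobal(st0)), 0)
})

test_that("incremental updates equal a global rebuild through random event streams", {
  set.seed(101)
  fixtures <- list(
    makePredatorPrey(lattice = buildLattice("hex2d", c(8, 8))),
    makeRockPaperScissors(lattice = buildLattice("square2d", c(8, 8), "periodic")),
    makeImmunotherapy(lattice = buildLattice("square2d", c(8, 8)), tumorRadius = 2),
    makePufa(0.15, buildLattice("square2d", c(9, 9))))
  for (fx in fixtures) {
    st <- initializeState(fx$graph, fx$model, fx$makeInit())
    pops <- populations(st)
    for (ev in seq_len(150)) {
      rec <- stepSSA(st)
      if (is.null(rec)) {   # absorbed; restart with a fresh configuration
        resetState(st, fx$makeInit())
        next
      }
      if (ev %% 10 == 0) expectStateConsistent(st, fx$name)
    }
    # class-size accounting: the on-site class of each species holds every
    # particle of that species
    ct <- classTable(st@channels)
    sz <- classSizes(st)
    pops <- populations(st)
    for (k in which(is.na(ct$j)))
      if (ct$center[k] != "0")
        expect_equal(sz[k], unname(pops[ct$center[k]]))
  }
})
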