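test_that("a single pairwise reaction splits into D channels with rates j*k", {
  alpha <- 0.37
  m <- ipsModel(c("F", "R"),
                list(parseReaction("F + R -> F + F", alpha, "predation")))
  ch <- enumerateChannels(m, D = 6)
  expect_equal(nrow(ch), 6L)
  expect_equal(ch$j, 1:6)
  expect_equal(ch$perRate, alpha * (1:6))
  expect_equal(ch$center, rep("F", 6))
  expect_equal(ch$partner, rep("R", 6))
})

test_that("on-site reactions contribute one unsplit channel", {
  m <- ipsModel("A", list(parseReaction("A -> 0", 0.5)))
  for (D in c(4, 6, 8))
    expect_equal(nrow(enumerateChannels(m, D)), 1L)
})

test_that("the predator-prey expansion reproduces the published structure", {
  cs <- reactionChannels(predatorPreyModel(), D = 6)
  expect_equal(nChannels(cs), 26L)        # 6*4 pairwise + 2 on-site
  expect_equal(nClasses(cs), 20L)         # 6*3 unique pairs + 2 on-site

  ct <- classTable(cs)
  expect_equal(sum(ct$center == "R"), 7L) # rabbits: j = 1..6 with open sites + death

  # the (R, open, j=3) class is shared by migration and reproduction
  shared <- ct$class[ct$center == "R" & !is.na(ct$partner) &
                       ct$partner == "0" & ct$j == 3]
  ch <- channelTable(cs)
  hits <- ch[ch$class == shared, ]
  expect_equal(nrow(hits), 2L)
  expect_setequal(hits$reaction, c("rabbit reproduction", "rabbit migration"))
})

test_that("channel and class counting formulas hold for random models", {
  set.seed(42)
  for (rep in seq_len(100)) {
    rm <- randomModel()
    D <- sample(c(4L, 6L, 8L), 1)
    cs <- reactionChannels(rm$model, D)
    expect_equal(nChannels(cs), D * rm$P + rm$O)
    expect_equal(nClasses(cs), D * rm$U + rm$V)
    expect_lte(nClasses(cs), nChannels(cs))
    expect_equal(channelTable(cs)$perRate,
                 with(channelTable(cs),
                      ifelse(type == "pairwise", j, 1) *
                        vapply(reaction, function(nm) {
                          rx <- reactionList(rm$model)
                          rx[[match(nm, vapply(rx, function(r) r@name, ""))]]@rate
                        }, 1.0, USE.NAMES = FALSE)))
  }
})

test_that("composition counting matches exhaustive enumeration", {
  for (D in 0:8)
    for (L in 0:4)
      expect_equal(countConfigs(D, L), nrow(enumCompositions(D, L)),
                   info = sprintf("D=%d L=%d", D, L))
  expect_equal(countConfigs(4, 2), 15L)
  expect_equal(countConfigs(6, 1), 7L)
  expect_equal(countConfigs(0, 3), 1L)
})

test_that("composition rank and unrank are a lexicographic bijection", {
  for (d in c(0, 1, 4, 6, 8)) {
    for (L in 0:4) {
      all <- enumCompositions(d, L)
      ranks <- apply(all, 1, compositionRank)
      expect_equal(ranks, seq_len(nrow(all)) - 1L)   # lexicographic order
      for (k in seq_len(nrow(all)))
        expect_equal(compositionUnrank(k - 1L, d, L), unname(all[k, ]))
    }
  }
  # the worked 4-neighbor 2-species example: 1 open + 1 first + 2 second
  expect_equal(sum(c(1, 1, 2)), 4)
  expect_lt(compositionRank(c(1, 1, 2)), countConfigs(4, 2))
  expect_equal(compositionUnrank(compositionRank(c(1, 1, 2)), 4, 2), c(1L, 1L, 2L))
  expect_error(compositionUnrank(15, 4, 2), "out of range")
  expect_error(compositionRank(c(-1, 2)), "negative")
})

test_that("channel tables export as CSV", {
  cs <- reactionChannels(predatorPreyModel(), D = 6)
  f <- tempfile(fileext = ".csv")
  writeChannelTable(cs, f)
  tab <- read.csv(f)
  expect_equal(nrow(tab), 26L)
  expect_named(tab, c("channel", "reaction", "j", "per_particle_rate",
                      "sample_class"))
  expect_equal(sort(unique(tab$sample_class)), 1:20)
  unlink(f)
})
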