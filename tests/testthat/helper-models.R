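# shared tiny-model builders and a random-model generator for property tests

ppParams <- c(predation = 0.3, reproduction = 1.0, migration = 1.0, death = 0.2)

predatorPreyModel <- function(params = ppParams)
  makePredatorPrey(params, lattice = buildLattice("hex2d", c(5, 5)))$model

pureDeathModel <- function(mu = 0.5)
  ipsModel("A", list(parseReaction("A -> 0", mu, "death")))

migrationModel <- function(gamma = 1)
  ipsModel("A", list(parseReaction("A + 0 -> 0 + A", gamma, "migration")))

birthDeathMigrationModel <- function(b = 1, d = 0.3, m = 0.7)
  ipsModel("A", list(parseReaction("A + 0 -> A + A", b, "birth"),
                     parseReaction("A + 0 -> 0 + A", m, "migration"),
                     parseReaction("A -> 0", d, "death")))

# random valid model; counts of pairwise/on-site reactions and unique
# reactant signatures are recomputed here independently of the package
randomModel <- function() {
  L <- sample(1:4, 1)
  species <- LETTERS[seq_len(L)]
  tokens <- c("0", species)
  nR <- sample(1:6, 1)
  rx <- list()
  info <- list()
  for (i in seq_len(nR)) {
    if (stats::runif(1) < 0.6) {   # pairwise
      repeat {
        re <- sample(tokens, 2, replace = TRUE)
        pr <- sample(tokens, 2, replace = TRUE)
        if (!identical(re, pr) && !all(c(re, pr) == "0")) break
      }
      rx[[i]] <- parseReaction(sprintf("%s + %s -> %s + %s",
                                       re[1], re[2], pr[1], pr[2]),
                               stats::runif(1), name = sprintf("rx%d", i))
      info[[i]] <- list(type = "pairwise", sig = paste(re, collapse = "|"))
    } else {                        # on-site
      repeat {
        re <- sample(tokens, 1)
        pr <- sample(tokens, 1)
        if (re != pr) break
      }
      rx[[i]] <- parseReaction(sprintf("%s -> %s", re, pr), stats::runif(1),
                               name = sprintf("rx%d", i))
      info[[i]] <- list(type = "on_site", sig = re)
    }
  }
  model <- ipsModel(species, rx)
  types <- vapply(info, `[[`, "", "type")
  sigs <- vapply(info, `[[`, "", "sig")
  list(model = model,
       P = sum(types == "pairwise"), O = sum(types == "on_site"),
       U = length(unique(sigs[types == "pairwise"])),
       V = length(unique(sigs[types == "on_site"])))
}
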