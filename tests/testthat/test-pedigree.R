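test_that("preparePedigree sorts parents before offspring and validates", {
  ped <- preparePedigree(data.frame(
    id = c("o", "s", "d"), sire = c("s", 0, 0), dam = c("d", 0, 0),
    sex = c("M", "M", "F")))
  expect_setequal(pedIds(ped)[1:2], c("s", "d"))
  expect_identical(pedIds(ped)[3], "o")

  # already sorted three-generation chain stays in order
  chain <- data.frame(id = c("a", "b", "c"), sire = c(0, 0, 0),
                      dam = c(0, "a", "b"), sex = c("F", "F", "F"))
  expect_identical(pedIds(preparePedigree(chain)), c("a", "b", "c"))

  # an id used both as sire and dam is a sex conflict
  expect_error(preparePedigree(data.frame(
    id = c("x", "a", "b"), sire = c(0, "x", 0), dam = c(0, 0, "x"),
    sex = c("M", "F", "F"))), "both as sire and as dam")
  # recorded sex contradicts parental role
  expect_error(preparePedigree(data.frame(
    id = c("x", "y"), sire = c(0, "x"), dam = c(0, 0),
    sex = c("F", "M"))), "recorded as female")
  # duplicated ids
  expect_error(preparePedigree(data.frame(
    id = c("x", "x"), sire = c(0, 0), dam = c(0, 0), sex = c("M", "M"))),
    "duplicated")
  # cycle: an individual its own ancestor
  expect_error(preparePedigree(data.frame(
    id = c("a", "b"), sire = c(0, 0), dam = c("b", "a"),
    sex = c("F", "F"))), "cycle")
  # sex codes 1/2 accepted
  ped12 <- preparePedigree(data.frame(id = c("m", "f"), sire = c(0, 0),
                                      dam = c(0, 0), sex = c(1, 2)))
  expect_identical(pedSex(ped12), c("M", "F"))
})

test_that("A and S reproduce the canonical expected relationships", {
  ped <- trioFamily()
  A <- relValues(buildA(ped))
  S <- relValues(buildS(ped))

  # autosomes: parent/offspring 0.5 regardless of sex, full sibs 0.5
  expect_equal(A["s", "o"], 0.5)
  expect_equal(A["d", "o"], 0.5)
  expect_equal(A["f1", "f2"], 0.5)
  expect_equal(unname(diag(A)), rep(1, 6))

  # X: no sire/son relationship; dam/son 0.5; full sisters 0.75;
  # full brothers 0.25; male diagonal exactly 0.5
  expect_identical(S["s", "o"], 0)
  expect_equal(S["d", "o"], 0.5)
  expect_equal(S["s", "f1"], 0.5)    # sire/daughter
  expect_equal(S["f1", "f2"], 0.75)
  expect_equal(S["o", "b2"], 0.25)
  expect_equal(S["o", "f1"], 0.25)   # full sibs male/female
  expect_identical(unname(S[cbind(c("s","o","b2"), c("s","o","b2"))]),
                   rep(0.5, 3))
  expect_equal(S["d", "d"], 1)

  # half sibs: paternal sisters 0.5, paternal brothers 0, maternal 0.25
  hs <- halfSibFamily()
  Sh <- relValues(buildS(hs))
  Ah <- relValues(buildA(hs))
  expect_equal(Sh["ph1", "ph2"], 0.5)   # paternal half-sisters
  expect_identical(Sh["ph3", "ph1"], 0) # paternal half male/female
  expect_equal(Sh["mh1", "mh2"], 0.25)  # maternal half-brothers
  expect_equal(Sh["mh2", "mh3"], 0.25)  # maternal half male/female
  expect_equal(Ah["ph1", "ph2"], 0.25)
})

test_that("male S diagonal is exactly 0.5 on random pedigrees", {
  for (seed in 1:5) {
    ped <- randomPedigree(seed, generations = 4)
    S <- relValues(buildS(ped))
    expect_identical(unname(diag(S)[pedSex(ped) == "M"]),
                     rep(0.5, sum(pedSex(ped) == "M")))
    # female diagonal = 1 + S(sire, dam)
    fem <- which(pedSex(ped) == "F" & !is.na(pedSire(ped)) &
                   !is.na(pedDam(ped)))
    for (i in fem)
      expect_equal(S[i, i], 1 + S[pedSire(ped)[i], pedDam(ped)[i]])
  }
})

test_that("dam-to-daughter chains match A while male paths differ", {
  chain <- preparePedigree(data.frame(
    id = c("g1", "g2", "g3"), sire = c(0, 0, 0), dam = c(0, "g1", "g2"),
    sex = c("F", "F", "F")))
  S <- relValues(buildS(chain)); A <- relValues(buildA(chain))
  expect_equal(S["g1", "g2"], A["g1", "g2"])   # both 0.5
  expect_equal(S["g1", "g3"], A["g1", "g3"])   # both 0.25
  # but S != A in general on a mixed pedigree
  expect_false(isTRUE(all.equal(relValues(buildS(trioFamily())),
                                relValues(buildA(trioFamily())))))
})

test_that("sparse S inverse inverts S and stays sparse", {
  # single base individuals: known closed forms
  pm <- preparePedigree(data.frame(id = "m", sire = 0, dam = 0, sex = "M"))
  expect_equal(as.matrix(buildSInverse(pm))[1, 1], 2)
  pf <- preparePedigree(data.frame(id = "f", sire = 0, dam = 0, sex = "F"))
  expect_equal(as.matrix(buildSInverse(pf))[1, 1], 1)

  for (seed in c(2, 9)) {
    ped <- randomPedigree(seed, generations = 3, nMales = 3, nFemales = 4)
    n <- length(ped)
    S <- relValues(buildS(ped))
    Si <- buildSInverse(ped)
    expect_lt(max(abs(as.matrix(Si) %*% S - diag(n))), 1e-8)
    expect_lte(Matrix::nnzero(Si), 9 * n)
  }
})

test_that("metafounder S reduces to S at gamma 0 and inflates base links", {
  ped <- randomPedigree(5)
  expect_equal(relValues(buildSMetafounders(ped, metafounderConfig(0))),
               relValues(buildS(ped)), tolerance = 1e-12)

  two <- preparePedigree(data.frame(id = c("f1", "f2"), sire = c(0, 0),
                                    dam = c(0, 0), sex = c("F", "F")))
  Sg <- relValues(buildSMetafounders(two, metafounderConfig(0.4)))
  expect_gt(Sg["f1", "f2"], 0)
  # monotone in gamma
  Sg2 <- relValues(buildSMetafounders(two, metafounderConfig(0.8)))
  expect_gt(Sg2["f1", "f2"], Sg["f1", "f2"])
  # base female diagonal = 1 + gamma_mf/2 (sire and dam metafounders)
  expect_equal(Sg["f1", "f1"], 1 + 0.4 / 2)

  # unassigned base individual with multiple groups errors
  cfgG <- metafounderConfig(matrix(c(.4, .1, .1, .4), 2,
                                   dimnames = list(c("g1", "g2"),
                                                   c("g1", "g2"))))
  expect_error(buildSMetafounders(two, cfgG), "no metafounder assignment")
})

test_that("P^r hits its exact limits and the r bounds are enforced", {
  ped <- randomPedigree(3)
  expect_equal(relValues(buildPPar(ped, 0.5)), relValues(buildA(ped)),
               tolerance = 1e-12)
  expect_error(buildPPar(ped, -0.1), "recombination fraction")
  expect_error(buildPPar(ped, 0.6), "recombination fraction")

  # r = 0: a grandson shares the grandsire's Y-side PAR haplotype intact
  chain <- preparePedigree(data.frame(
    id = c("gs", "d1", "f", "d2", "gson"),
    sire = c(0, 0, "gs", 0, "f"), dam = c(0, 0, "d1", 0, "d2"),
    sex = c("M", "F", "M", "F", "M")))
  P0 <- relValues(buildPPar(chain, 0))
  expect_equal(P0["gs", "gson"], 0.5)
  # while the daughter line at r = 0 carries the X-side haplotype
  expect_equal(unname(diag(P0)), rep(1, 5))
})

test_that("rescaleS scales male blocks by k and k^2", {
  ped <- trioFamily()
  S <- buildS(ped)
  expect_equal(relValues(rescaleS(S, 1)), relValues(S))
  S2 <- relValues(rescaleS(S, 2))
  expect_equal(S2["o", "o"], 2)          # male diagonal 0.5 * k^2
  expect_equal(S2["d", "o"], 1)          # dam/son 0.5 * k
  expect_equal(S2["f1", "f2"], 0.75)     # female block unchanged
  expect_error(rescaleS(S, 0), "positive")
  expect_error(rescaleS(buildA(ped), 2), "kind")
})
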