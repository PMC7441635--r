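test_that("simulated pedigrees have the configured structure and are
           bit-reproducible under a fixed seed", {
  cfg <- simConfig(generations = 1, nMales = 2, nFemales = 2, seed = 1)
  ped <- simulatePedigree(cfg)
  expect_equal(length(ped), 4)
  expect_true(all(is.na(pedSire(ped))))

  cfg3 <- simConfig(generations = 3, nMales = 3, nFemales = 4, seed = 2)
  ped3 <- simulatePedigree(cfg3)
  # non-founders draw both parents from the previous generation
  gen <- as.integer(sub("^g(\\d+).*", "\\1", pedIds(ped3)))
  nonf <- which(gen > 1)
  expect_true(all(!is.na(pedSire(ped3)[nonf])))
  pgen <- as.integer(sub("^g(\\d+).*", "\\1",
                         pedIds(ped3)[pedSire(ped3)[nonf]]))
  expect_true(all(pgen == gen[nonf] - 1))

  expect_identical(pedIds(simulatePedigree(cfg3)), pedIds(ped3))
  d1 <- geneDropX(ped3, cfg3); d2 <- geneDropX(ped3, cfg3)
  expect_identical(genoValues(d1$genotypes), genoValues(d2$genotypes))
})

test_that("founder gene-content variances are pq for males, 2pq for females", {
  p <- 0.5
  cfg <- simConfig(generations = 1, nMales = 20000, nFemales = 20000,
                   nLoci = 1, p = p, seed = 5)
  ped <- simulatePedigree(cfg)
  m <- genoValues(geneDropX(ped, cfg)$genotypes)
  vM <- var(m[pedSex(ped) == "M", 1])
  vF <- var(m[pedSex(ped) == "F", 1])
  expect_equal(vM, p * (1 - p), tolerance = 0.03)
  expect_equal(vF, 2 * p * (1 - p), tolerance = 0.03)
})

test_that("zero female map length means non-recombinant maternal gametes
           and sires pass their X intact to daughters", {
  cfg <- simConfig(generations = 2, nMales = 5, nFemales = 5, nLoci = 50,
                   p = 0.5, mapLengthX = 0, seed = 6)
  ped <- simulatePedigree(cfg)
  drop <- geneDropX(ped, cfg)
  rec <- drop$gametes
  expect_true(all(rec@meioses$crossovers == 0))
  # each maternal gamete copies a single dam haplotype
  damRows <- rec@meioses$parentSex == "F"
  orig <- rec@origin[damRows, , drop = FALSE]
  expect_true(all(orig == orig[, 1]))
  # sire-to-daughter rows exist, sire-to-son rows must not
  sireRows <- rec@meioses[rec@meioses$parentSex == "M", ]
  expect_true(all(sireRows$offspringSex == "F"))
  expect_true(all(sireRows$crossovers == 0))
})

test_that("PAR transmission shows the sex-gradient anchored at the PAB", {
  d <- c(0, haldaneInv(0.25), 50)
  cfg <- simConfig(generations = 2, nMales = 60, nFemales = 60,
                   parMap = d, nLoci = 3, p = 0.5, seed = 7)
  # many meioses: replicate the two-generation pedigree massively
  cfgBig <- simConfig(generations = 2, nMales = 800, nFemales = 800,
                      parMap = d, nLoci = 3, p = 0.5, seed = 7)
  ped <- simulatePedigree(cfgBig)
  drop <- geneDropPar(ped, cfgBig)
  prof <- transmissionProfile(drop$gametes)
  sireSon <- prof[prof$parentSex == "M" & prof$offspringSex == "M", ]
  sireDau <- prof[prof$parentSex == "M" & prof$offspringSex == "F", ]
  dam <- prof[prof$parentSex == "F", ]
  n <- sireSon$nMeioses[1]
  se <- sqrt(0.25 / n)
  # at the PAB sons inherit the paternal (Y-side) haplotype with certainty
  expect_equal(sireSon$pPaternal[1], 1)
  expect_equal(sireDau$pPaternal[1], 0)
  # at c = 0.25 the probability is 1 - c
  expect_lt(abs(sireSon$pPaternal[2] - 0.75), 4 * se)
  # complementarity of the two-haplotype choice at every locus
  expect_true(all(abs(sireDau$pPaternal - (1 - sireSon$pPaternal)) <
                    6 * se))
  # dams transmit either haplotype with equal probability everywhere
  expect_true(all(abs(dam$pPaternal - 0.5) < 4 * sqrt(0.25 / dam$nMeioses)))
})

test_that("full dosage compensation doubles the male genotypic variance", {
  cfg <- simConfig(generations = 1, nMales = 4000, nFemales = 4000,
                   nLoci = 60, p = 0.5, k = 2, rG = 1, h2Target = 0.5,
                   seed = 8)
  ped <- simulatePedigree(cfg)
  drop <- geneDropX(ped, cfg)
  phen <- simulatePhenotypes(drop$genotypes, cfg)
  vM <- var(phen$g[phen$sex == "M"])
  vF <- var(phen$g[phen$sex == "F"])
  expect_equal(vM / vF, 2, tolerance = 0.15)

  # k = 1, rG = 1: both sexes share the same substitution effects, so a
  # male and a female with identical gene content get identical values
  cfg1 <- simConfig(generations = 1, nMales = 50, nFemales = 50,
                    nLoci = 30, p = 0.5, k = 1, rG = 1, h2Target = 0.5,
                    seed = 9)
  ped1 <- simulatePedigree(cfg1)
  d1 <- geneDropX(ped1, cfg1)
  ph <- simulatePhenotypes(d1$genotypes, cfg1)
  p <- 0.5
  Zm <- genoValues(d1$genotypes)[ph$sex == "M", ] - p
  Zf <- genoValues(d1$genotypes)[ph$sex == "F", ] - 2 * p
  aM <- qr.solve(Zm, ph$g[ph$sex == "M"])
  aF <- qr.solve(qr(Zf, LAPACK = TRUE), ph$g[ph$sex == "F"])
  expect_equal(unname(drop(Zm %*% aF)), ph$g[ph$sex == "M"],
               tolerance = 1e-6)

  # h2Target = 0 gives pure-noise phenotypes
  cfg0 <- simConfig(generations = 1, nMales = 30, nFemales = 30,
                    nLoci = 20, p = 0.5, h2Target = 0, seed = 10)
  ped0 <- simulatePedigree(cfg0)
  ph0 <- simulatePhenotypes(geneDropX(ped0, cfg0)$genotypes, cfg0)
  expect_true(all(ph0$g == 0))
})

test_that("identical X copies are enriched versus an equal-length autosome", {
  # few dams and a short female map: maternal half-brothers often share
  # an entire X (males receive their single X from the dam)
  cfg <- simConfig(generations = 3, nMales = 15, nFemales = 3,
                   nLoci = 300, p = 0.5, mapLengthX = 0.2, seed = 11)
  ped <- simulatePedigree(cfg)
  gx <- buildGX(geneDropX(ped, cfg)$genotypes)
  ga <- buildGAuto(geneDropAutosome(ped, cfg))
  male <- pedSex(ped) == "M"
  propX <- highRelationshipProportions(toCorrelation(gx),
                                       thresholds = 0.99,
                                       subset = "males")
  propA <- highRelationshipProportions(toCorrelation(ga),
                                       thresholds = 0.99,
                                       subset = "males")
  expect_gt(propX, propA)
  expect_gt(propX, 0)
})
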