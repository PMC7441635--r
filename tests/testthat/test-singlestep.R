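# Helper: a RelationshipMatrix from a plain matrix + sexes.
asRel <- function(V, sex, kind = "GX") {
  new("RelationshipMatrix", values = (V + t(V)) / 2, sex = sex, kind = kind,
      params = list())
}

test_that("gene-content prediction regresses through pedigree links", {
  # ungenotyped dam, genotyped son and an unrelated genotyped male
  ped <- preparePedigree(data.frame(
    id = c("dam", "son", "oth"), sire = c(0, 0, 0), dam = c(0, "dam", 0),
    sex = c("F", "M", "M")))
  S <- buildS(ped)
  Sp <- partitionS(S, c("son", "oth"))
  z2 <- c(son = 0.6, oth = -0.2)
  pq <- 0.25
  pr <- predictGeneContent(Sp, z2, pq)
  Sv <- relValues(S)
  # single predictor: coefficient S(dam,son)/S(son,son)
  expect_equal(unname(pr$z1hat),
               unname(Sv["dam", "son"] / Sv["son", "son"] * z2["son"]))
  expect_equal(unname(pr$condVar[1, 1]),
               (Sv["dam", "dam"] - Sv["dam", "son"]^2 / Sv["son", "son"]) *
                 2 * pq)

  # unrelated ungenotyped individual: zero prediction, full prior variance
  ped2 <- preparePedigree(data.frame(
    id = c("u", "g1", "g2"), sire = c(0, 0, 0), dam = c(0, 0, 0),
    sex = c("F", "F", "F")))
  Sp2 <- partitionS(buildS(ped2), c("g1", "g2"))
  pr2 <- predictGeneContent(Sp2, c(1, -1), 0.25)
  expect_equal(unname(pr2$z1hat), 0)
  expect_equal(unname(pr2$condVar[1, 1]), 1 * 2 * 0.25)
})

test_that("prediction error is calibrated against the conditional variance", {
  p <- 0.5
  cfg <- simConfig(generations = 3, nMales = 3, nFemales = 3,
                   nLoci = 10000, p = p, seed = 21)
  ped <- simulatePedigree(cfg)
  drop <- geneDropX(ped, cfg)
  ids <- pedIds(ped)
  genotyped <- ids[seq(2, length(ids), by = 2)]
  Sp <- partitionS(buildS(ped), genotyped)
  m <- genoValues(drop$genotypes)
  mu <- ifelse(pedSex(ped) == "M", p, 2 * p)
  Z <- m - mu
  pr <- predictGeneContent(Sp, Z[genotyped, ], p * (1 - p))
  err <- Z[Sp$ungenotyped, ] - pr$z1hat
  mse <- rowMeans(err^2)
  seMse <- apply(err^2, 1, sd) / sqrt(ncol(err))
  # mean squared prediction error equals the conditional variance
  expect_true(all(abs(mse - diag(pr$condVar)) < 4 * seMse))
})

test_that("H^X reduces exactly at both ends and matches dense algebra", {
  set.seed(5)
  ped <- randomPedigree(31, generations = 3, nMales = 3, nFemales = 4)
  ids <- pedIds(ped)
  S <- buildS(ped)
  genotyped <- ids[seq(1, length(ids), by = 2)][1:8]
  Sp <- partitionS(S, genotyped)
  sexG <- pedSex(ped)[match(Sp$genotyped, ids)]

  # G^X == S22 -> H^X == S (algebraic identity)
  H <- buildHX(Sp, asRel(Sp$S22, sexG))
  expect_equal(relValues(H), relValues(S), tolerance = 1e-12)

  # all genotyped -> H^X == G^X
  SpAll <- partitionS(S, ids)
  Gv <- relValues(S) + diag(0.01, length(ids))
  Hall <- buildHX(SpAll, asRel(Gv, pedSex(ped)))
  expect_equal(relValues(Hall), (Gv + t(Gv)) / 2, tolerance = 1e-12)

  # random G^X: equals the displayed block formula evaluated independently
  Grand <- crossprod(matrix(rnorm(64), 8, 8)) / 8 + diag(0.05, 8)
  dimnames(Grand) <- list(Sp$genotyped, Sp$genotyped)
  H2 <- relValues(buildHX(Sp, asRel(Grand, sexG)))
  S22i <- solve(Sp$S22)
  B <- Sp$S12 %*% S22i
  Gs <- (Grand + t(Grand)) / 2
  expU <- Sp$S11 - B %*% t(Sp$S12) + B %*% Gs %*% t(B)
  expect_equal(unname(H2[Sp$ungenotyped, Sp$ungenotyped]), unname(expU),
               tolerance = 1e-10)
  expect_equal(unname(H2[Sp$ungenotyped, Sp$genotyped]),
               unname(B %*% Gs), tolerance = 1e-10)
  expect_equal(unname(H2[Sp$genotyped, Sp$genotyped]), unname(Gs),
               tolerance = 1e-12)
  expect_lt(max(abs(H2 - t(H2))), 1e-12)
})

test_that("H^X inverse agrees with the dense inverse of H^X", {
  set.seed(6)
  ped <- randomPedigree(32, generations = 3, nMales = 3, nFemales = 4)
  ids <- pedIds(ped)
  S <- buildS(ped)
  genotyped <- ids[seq(1, length(ids), by = 2)][1:8]
  Sp <- partitionS(S, genotyped)
  sexG <- pedSex(ped)[match(Sp$genotyped, ids)]
  Sinv <- buildSInverse(ped)

  # G^X == S22: correction vanishes, inverse equals S^-1
  HiS <- buildHXInverse(Sinv, Sp$S22, asRel(Sp$S22, sexG))
  expect_lt(max(abs(as.matrix(HiS) - as.matrix(Sinv))), 1e-8)

  # invertible G^X: H^X (H^X)^-1 = I within 1e-6
  Grand <- crossprod(matrix(rnorm(80), 10, 8)) / 10 + diag(0.05, 8)
  dimnames(Grand) <- list(Sp$genotyped, Sp$genotyped)
  GXr <- asRel(Grand, sexG)
  H <- relValues(buildHX(Sp, GXr))
  Hi <- as.matrix(buildHXInverse(Sinv, Sp$S22, GXr))
  expect_lt(max(abs(H %*% Hi[ids, ids] - diag(length(ids)))), 1e-6)

  # numerically singular G^X is refused
  Gsing <- tcrossprod(matrix(rnorm(8), 8, 1))
  dimnames(Gsing) <- list(Sp$genotyped, Sp$genotyped)
  expect_error(buildHXInverse(Sinv, Sp$S22, asRel(Gsing, sexG)),
               "singular")
})

test_that("blending restores positive definiteness of a rank-deficient GX", {
  # duplicated male X copies: a few distinct chromosomes shared by many
  # males make G^X rank deficient
  cfg <- simConfig(generations = 3, nMales = 2, nFemales = 10,
                   nLoci = 400, p = 0.5, mapLengthX = 0.1, seed = 14)
  ped <- simulatePedigree(cfg)
  drop <- geneDropX(ped, cfg)
  GX <- buildGX(drop$genotypes, p = 0.5)
  evG <- eigen(relValues(GX), symmetric = TRUE, only.values = TRUE)$values
  expect_lt(min(evG), 1e-10)            # rank deficient as constructed
  S <- buildS(ped)
  Gb <- blendGRM(S, GX, alpha = 0.05)
  ev <- eigen(relValues(Gb), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_lt(max(abs(relValues(Gb) - t(relValues(Gb)))), 1e-12)
  # blended matrix supports the single-step inverse
  Sp <- partitionS(S, relIds(GX))
  Hi <- buildHXInverse(buildSInverse(ped), Sp$S22, Gb)
  H <- relValues(buildHX(Sp, Gb))
  expect_lt(max(abs(H %*% as.matrix(Hi) - diag(nrow(H)))), 1e-6)
})

test_that("blend endpoints and the moment-matching scaling are exact", {
  ped <- trioFamily()
  S <- buildS(ped)
  # alpha = 1 returns S exactly
  GX <- asRel(relValues(S) * 0.8 + 0.01, pedSex(ped))
  expect_equal(relValues(blendGRM(S, GX, alpha = 1)), relValues(S),
               tolerance = 1e-12)
  # alpha = 0 with an already mean-matched GX returns GX unchanged
  expect_equal(relValues(blendGRM(S, S, alpha = 0)), relValues(S),
               tolerance = 1e-12)
  # after scaling (any alpha), mean diagonal and overall mean match S
  # on the variance-equalized scale
  b <- blendGRM(S, GX, alpha = 0)
  w <- ifelse(pedSex(ped) == "M", sqrt(2), 1)
  We <- tcrossprod(w)
  expect_equal(mean(diag(relValues(b) * We)),
               mean(diag(relValues(S) * We)), tolerance = 1e-10)
  expect_equal(mean(relValues(b) * We), mean(relValues(S) * We),
               tolerance = 1e-10)
  expect_error(blendGRM(S, GX, alpha = 1.2), "alpha")
})
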