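# Shared fixtures: canonical toy pedigrees and Monte-Carlo helpers.

# Base sire s and dam d with offspring of both sexes: one son (o), a second
# son (b2), and two daughters (f1, f2) -> covers sire/son, dam/son,
# full sibs of every sex combination, and the diagonals.
trioFamily <- function() {
  preparePedigree(data.frame(
    id   = c("s", "d", "o", "b2", "f1", "f2"),
    sire = c(0, 0, "s", "s", "s", "s"),
    dam  = c(0, 0, "d", "d", "d", "d"),
    sex  = c("M", "F", "M", "M", "F", "F")))
}

# Half-sib family: common sire with two unrelated dams, and a common dam
# with two unrelated sires, offspring of both sexes.
halfSibFamily <- function() {
  preparePedigree(data.frame(
    id   = c("s", "d1", "d2", "ph1", "ph2", "ph3",
             "s1", "s2", "dm", "mh1", "mh2", "mh3"),
    sire = c(0, 0, 0, "s", "s", "s", 0, 0, 0, "s1", "s2", "s2"),
    dam  = c(0, 0, 0, "d1", "d2", "d2", 0, 0, 0, "dm", "dm", "dm"),
    sex  = c("M", "F", "F", "F", "F", "M",
             "M", "M", "F", "M", "M", "F")))
}

# Random pedigree through the simulator (prepared, discrete generations).
randomPedigree <- function(seed, generations = 3, nMales = 3, nFemales = 4) {
  simulatePedigree(simConfig(generations = generations, nMales = nMales,
                             nFemales = nFemales, seed = seed))
}

# Empirical covariance of gene content (centered at the generating
# frequencies) together with its per-entry Monte-Carlo standard error.
empiricalCov <- function(m, sex, p) {
  mu <- ifelse(sex == "M", p, 2 * p)
  Z <- m - mu
  L <- ncol(Z)
  emp <- tcrossprod(Z) / L
  se <- sqrt(pmax(tcrossprod(Z^2) / L - emp^2, 0) / L)
  list(cov = emp, se = se)
}

# Assert an empirical covariance matches its expectation entrywise at the
# 3-Monte-Carlo-SE scale. With hundreds of simultaneous entries a handful
# of |z| > 3 exceedances is the expected binomial rate, so the check
# allows the 0.5% multiplicity quota and bounds the worst deviation at
# 4.5 SEs (well beyond chance for these entry counts).
expectCovMatches <- function(emp, expected, label = "covariance") {
  z <- abs(emp$cov - expected) / pmax(emp$se, 1e-12)
  nEntries <- length(z)
  expect_lte(sum(z > 3), ceiling(0.005 * nEntries),
             label = paste(label, ": entries beyond 3 MC SEs"))
  expect_lt(max(z), 4.5, label = paste(label, ": worst deviation (SEs)"))
}
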