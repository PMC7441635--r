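#' Build a simulation configuration
#'
#' @param generations number of discrete offspring generations after the
#'   founders (1 = founders only).
#' @param nMales,nFemales males/females per generation.
#' @param nLoci number of loci to drop.
#' @param p base allele frequency (scalar or per locus).
#' @param mapLengthX female X-specific map length in Morgan; `NA` (default)
#'   drops loci independently (inter-locus recombination 1/2), 0 gives full
#'   linkage.
#' @param parMap male cM distances from each PAR locus to the
#'   pseudo-autosomal boundary (default: a single locus at the PAB).
#' @param k dosage-compensation factor for phenotype simulation.
#' @param rG cross-sex genetic correlation for phenotype simulation.
#' @param h2Target female-trait heritability for phenotype simulation.
#' @param seed mandatory integer seed.
#' @return a [SimConfig-class].
#' @export
simConfig <- function(generations = 3, nMales = 5, nFemales = 10,
                      nLoci = 1000, p = 0.5, mapLengthX = NA_real_,
                      parMap = 0, k = 1, rG = 1, h2Target = 0.5, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  new("SimConfig", generations = generations, nMales = nMales,
      nFemales = nFemales, nLoci = nLoci, p = p, mapLengthX = mapLengthX,
      parMap = parMap, k = k, rG = rG, h2Target = h2Target, seed = seed)
}

#' Simulate a discrete-generation pedigree
#'
#' Founders in generation 1; every individual of a later generation draws
#' its sire and dam uniformly at random from the males and females of the
#' previous generation. Sexes are assigned by the configured counts.
#'
#' @param cfg a [simConfig()].
#' @return a prepared [Pedigree-class].
#' @export
simulatePedigree <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  set.seed(cfg@seed)
  nm <- cfg@nMales; nf <- cfg@nFemales
  id <- sire <- dam <- sex <- character(0)
  for (g in seq_len(cfg@generations)) {
    ids <- c(paste0("g", g, "m", seq_len(nm)), paste0("g", g, "f", seq_len(nf)))
    sx <- c(rep("M", nm), rep("F", nf))
    if (g == 1) {
      s <- d <- rep(NA_character_, nm + nf)
    } else {
      prevM <- paste0("g", g - 1, "m", seq_len(nm))
      prevF <- paste0("g", g - 1, "f", seq_len(nf))
      s <- sample(prevM, nm + nf, replace = TRUE)
      d <- sample(prevF, nm + nf, replace = TRUE)
    }
    id <- c(id, ids); sire <- c(sire, s); dam <- c(dam, d); sex <- c(sex, sx)
  }
  preparePedigree(data.frame(id = id, sire = sire, dam = dam, sex = sex))
}

# One meiosis: recombine haplotypes hapA/hapB (vectors over loci) with
# switch probabilities cvec between adjacent loci. pStartA is the
# probability of starting on hapA; startA forces the start.
# Returns gamete, whether each allele came from hapA, and crossover count.
.meiosis <- function(hapA, hapB, cvec, pStartA = 0.5, startA = NULL) {
  L <- length(hapA)
  if (is.null(startA)) startA <- runif(1) < pStartA
  switches <- if (L > 1) runif(L - 1) < cvec else logical(0)
  onA <- xor(rep(startA, L), c(FALSE, cumsum(switches) %% 2 == 1))
  list(gamete = ifelse(onA, hapA, hapB), fromA = onA,
       crossovers = sum(switches))
}

# Switch probabilities for loci evenly spaced on `lengthM` Morgan
# (NA = independent loci, c = 1/2 everywhere).
.switchProbs <- function(nLoci, lengthM) {
  if (nLoci < 2) return(numeric(0))
  if (is.na(lengthM)) return(rep(0.5, nLoci - 1))
  d <- lengthM * 100 / (nLoci - 1)          # cM between adjacent loci
  rep(haldane(d), nLoci - 1)
}

.baseFreqs <- function(cfg, L) {
  p <- cfg@p
  if (length(p) == 1) rep(p, L) else rep_len(p, L)
}

#' Gene-drop X-specific loci through a pedigree
#'
#' Founder alleles are drawn at the base frequencies; males carry a single
#' haplotype (from their dam) and females two. Daughters receive the
#' sire's X intact (no recombination, no Mendelian sampling); sons receive
#' no X from their sire. Maternal gametes are formed with Haldane
#' crossovers on the configured female map (`mapLengthX`; `NA` makes loci
#' independent). Gene content is 0/1 for males and 0/1/2 for females. The
#' empirical covariance of gene content across many dropped loci converges
#' to `S * 2pq`, which makes this the Monte-Carlo oracle for [buildS()].
#'
#' @param ped a prepared [Pedigree-class].
#' @param cfg a [simConfig()].
#' @return list with `genotypes` (a [GenotypeMatrix-class]) and `gametes`
#'   (a [GameteRecord-class] of dam meioses and sire-to-daughter
#'   transmissions).
#' @export
geneDropX <- function(ped, cfg) {
  stopifnot(is(ped, "Pedigree"), is(cfg, "SimConfig"))
  set.seed(cfg@seed + 1L)
  n <- length(ped); L <- cfg@nLoci
  p <- .baseFreqs(cfg, L)
  cvec <- .switchProbs(L, cfg@mapLengthX)
  hapP <- matrix(NA_integer_, n, L)   # paternal X (females only)
  hapM <- matrix(NA_integer_, n, L)   # maternal / single X
  recRows <- list(); orig <- list()
  for (i in seq_len(n)) {
    d <- ped@dam[i]; s <- ped@sire[i]
    if (is.na(d)) hapM[i, ] <- rbinom(L, 1, p)
    else {
      mei <- .meiosis(hapP[d, ], hapM[d, ], cvec)
      hapM[i, ] <- mei$gamete
      recRows[[length(recRows) + 1L]] <- data.frame(
        parent = ped@id[d], offspring = ped@id[i], parentSex = "F",
        offspringSex = ped@sex[i], crossovers = mei$crossovers)
      orig[[length(orig) + 1L]] <- as.integer(mei$fromA)
    }
    if (ped@sex[i] == "F") {
      if (is.na(s)) hapP[i, ] <- rbinom(L, 1, p)
      else {
        hapP[i, ] <- hapM[s, ]        # sire's single X, intact
        recRows[[length(recRows) + 1L]] <- data.frame(
          parent = ped@id[s], offspring = ped@id[i], parentSex = "M",
          offspringSex = "F", crossovers = 0L)
        orig[[length(orig) + 1L]] <- rep(0L, L)   # always his maternal X
      }
    }
  }
  m <- ifelse(ped@sex == "F", 1, 0) * ifelse(is.na(hapP), 0, hapP) + hapM
  m[ped@sex == "M", ] <- hapM[ped@sex == "M", ]
  dimnames(m) <- list(ped@id, paste0("x", seq_len(L)))
  cM <- if (is.na(cfg@mapLengthX)) rep(NA_real_, L) else
    seq(0, cfg@mapLengthX * 100, length.out = L)
  map <- data.frame(locus = colnames(m), region = "X",
                    bp = seq_len(L), cM = cM)
  rec <- new("GameteRecord",
             meioses = if (length(recRows)) do.call(rbind, recRows) else
               data.frame(parent = character(), offspring = character(),
                          parentSex = character(), offspringSex = character(),
                          crossovers = integer()),
             origin = if (length(orig)) do.call(rbind, orig) else
               matrix(integer(), 0, L),
             cM = cM)
  list(genotypes = genotypeMatrix(m, ped@sex, map), gametes = rec)
}

#' Gene-drop pseudo-autosomal loci through a pedigree
#'
#' All individuals are diploid on the PAR. Male meiosis starts at the
#' pseudo-autosomal boundary on the haplotype matching the offspring's
#' sex -- the paternal (Y-side) haplotype for sons, the maternal (X-side)
#' haplotype for daughters -- and switches haplotype at Haldane crossovers
#' along the male map (`parMap`, cM to the PAB). Dam meiosis has no
#' sex-gradient: either haplotype starts with probability 1/2. At the PAB
#' itself sons therefore always inherit the sire's paternal allele and
#' daughters his maternal allele; at distance `r` the probability decays
#' to `1 - haldane(r)`.
#'
#' @param ped a prepared [Pedigree-class].
#' @param cfg a [simConfig()]; `parMap` gives the locus positions.
#' @param independent drop every locus through its own independent meiosis
#'   (each locus then follows its marginal transmission law at its own
#'   distance, with no cross-locus linkage). This is the Monte-Carlo
#'   oracle mode: independent replicate loci give valid standard errors
#'   for empirical covariances. Default `FALSE` (one linked crossover
#'   process per meiosis).
#' @return list with `genotypes` and `gametes` as in [geneDropX()].
#' @export
geneDropPar <- function(ped, cfg, independent = FALSE) {
  stopifnot(is(ped, "Pedigree"), is(cfg, "SimConfig"))
  set.seed(cfg@seed + 2L)
  pos <- sort(cfg@parMap)
  L <- length(pos)
  p <- .baseFreqs(cfg, L)
  cvec <- haldane(diff(pos))
  c0 <- haldane(pos[1])                 # PAB -> first locus
  cAll <- haldane(pos)                  # PAB -> each locus (independent mode)
  n <- length(ped)
  hapP <- matrix(NA_integer_, n, L); hapM <- matrix(NA_integer_, n, L)
  recRows <- list(); orig <- list()
  addRec <- function(parent, offspring, psex, osex, mei) {
    recRows[[length(recRows) + 1L]] <<- data.frame(
      parent = parent, offspring = offspring, parentSex = psex,
      offspringSex = osex, crossovers = mei$crossovers)
    orig[[length(orig) + 1L]] <<- as.integer(mei$fromA)
  }
  # per-locus independent meiosis: allele taken from the paternal
  # haplotype with probability pPat[j], independently across loci
  indepDraw <- function(hA, hB, pPat) {
    onA <- runif(L) < pPat
    list(gamete = ifelse(onA, hA, hB), fromA = onA, crossovers = NA_integer_)
  }
  for (i in seq_len(n)) {
    s <- ped@sire[i]; d <- ped@dam[i]
    if (is.na(s)) hapP[i, ] <- rbinom(L, 1, p)
    else {
      mei <- if (independent) {
        # P(paternal) = 1 - c for sons, c for daughters, per locus
        indepDraw(hapP[s, ], hapM[s, ],
                  if (ped@sex[i] == "M") 1 - cAll else cAll)
      } else {
        # haplotype at the PAB matches offspring sex; may switch before locus 1
        startOnPat <- xor(ped@sex[i] == "M", runif(1) < c0)
        .meiosis(hapP[s, ], hapM[s, ], cvec, startA = startOnPat)
      }
      hapP[i, ] <- mei$gamete
      addRec(ped@id[s], ped@id[i], "M", ped@sex[i], mei)
    }
    if (is.na(d)) hapM[i, ] <- rbinom(L, 1, p)
    else {
      mei <- if (independent) indepDraw(hapP[d, ], hapM[d, ], 0.5)
      else .meiosis(hapP[d, ], hapM[d, ], cvec)
      hapM[i, ] <- mei$gamete
      addRec(ped@id[d], ped@id[i], "F", ped@sex[i], mei)
    }
  }
  m <- hapP + hapM
  dimnames(m) <- list(ped@id, paste0("par", seq_len(L)))
  map <- data.frame(locus = colnames(m), region = "PAR",
                    bp = seq_len(L), cM = pos)
  rec <- new("GameteRecord", meioses = do.call(rbind, recRows),
             origin = do.call(rbind, orig), cM = pos)
  list(genotypes = genotypeMatrix(m, ped@sex, map), gametes = rec)
}

#' Gene-drop autosomal loci through a pedigree
#'
#' Standard diploid dropping with Haldane recombination in both sexes on a
#' map of `mapLength` Morgan (`NA` = independent loci). The empirical
#' covariance of gene content converges to `A * 2pq`.
#'
#' @param ped a prepared [Pedigree-class].
#' @param cfg a [simConfig()].
#' @param mapLength map length in Morgan (default `cfg@mapLengthX`, so an
#'   autosome of the same length as the simulated X can be compared).
#' @return a [GenotypeMatrix-class].
#' @export
geneDropAutosome <- function(ped, cfg, mapLength = cfg@mapLengthX) {
  stopifnot(is(ped, "Pedigree"), is(cfg, "SimConfig"))
  set.seed(cfg@seed + 3L)
  n <- length(ped); L <- cfg@nLoci
  p <- .baseFreqs(cfg, L)
  cvec <- .switchProbs(L, mapLength)
  hapP <- matrix(NA_integer_, n, L); hapM <- matrix(NA_integer_, n, L)
  for (i in seq_len(n)) {
    s <- ped@sire[i]; d <- ped@dam[i]
    hapP[i, ] <- if (is.na(s)) rbinom(L, 1, p) else
      .meiosis(hapP[s, ], hapM[s, ], cvec)$gamete
    hapM[i, ] <- if (is.na(d)) rbinom(L, 1, p) else
      .meiosis(hapP[d, ], hapM[d, ], cvec)$gamete
  }
  m <- hapP + hapM
  dimnames(m) <- list(ped@id, paste0("a", seq_len(L)))
  map <- data.frame(locus = colnames(m), region = "A", bp = seq_len(L),
                    cM = if (is.na(mapLength)) NA_real_ else
                      seq(0, mapLength * 100, length.out = L))
  genotypeMatrix(m, ped@sex, map)
}

#' Simulate phenotypes under configurable dosage compensation
#'
#' Marker substitution effects are drawn iid per locus; male effects are
#' correlated `rG` with female effects and scaled by `k`, so the male
#' genotypic variance is `k^2/2` times the female one at Hardy-Weinberg
#' equilibrium (`k = 2` doubles it). Residual noise is calibrated so the
#' trait heritability in females equals `h2Target` (the same residual
#' variance is applied to males).
#'
#' @param G a [GenotypeMatrix-class] with X-specific loci.
#' @param cfg a [simConfig()] (uses `k`, `rG`, `h2Target`, `p`, `seed`).
#' @return data.frame with id, sex, y, g (genotypic value).
#' @export
simulatePhenotypes <- function(G, cfg) {
  stopifnot(is(G, "GenotypeMatrix"), is(cfg, "SimConfig"))
  set.seed(cfg@seed + 4L)
  keep <- genoMap(G)$region == "X"
  m <- genoValues(G)[, keep, drop = FALSE]
  L <- ncol(m)
  p <- .baseFreqs(cfg, L)
  Z <- .centerX(m, genoSex(G), p, k = 1)
  aF <- rnorm(L)
  aM <- cfg@k * (cfg@rG * aF + sqrt(max(0, 1 - cfg@rG^2)) * rnorm(L))
  male <- genoSex(G) == "M"
  g <- numeric(nrow(m))
  g[male] <- drop(Z[male, , drop = FALSE] %*% aM)
  g[!male] <- drop(Z[!male, , drop = FALSE] %*% aF)
  varGF <- 2 * sum(p * (1 - p))         # female genotypic variance
  sdE <- if (cfg@h2Target <= 0) sqrt(varGF) else
    sqrt(varGF * (1 - cfg@h2Target) / cfg@h2Target)
  if (cfg@h2Target <= 0) g[] <- 0
  y <- g + rnorm(nrow(m), 0, sdE)
  data.frame(id = rownames(m), sex = genoSex(G), y = y, g = g,
             row.names = NULL)
}

#' Empirical transmission profile along a map
#'
#' Tabulates, per locus, the probability that the transmitted allele came
#' from the parent's paternal haplotype, split by parent and offspring
#' sex. On the PAR this reproduces the sex-gradient: the sire-to-son curve
#' is 1 at the pseudo-autosomal boundary and decays with distance while
#' the sire-to-daughter curve mirrors it; dam curves stay flat at 1/2.
#'
#' @param rec a [GameteRecord-class].
#' @return data.frame: locus index, cM, parentSex, offspringSex, pPaternal,
#'   nMeioses.
#' @export
transmissionProfile <- function(rec) {
  stopifnot(is(rec, "GameteRecord"))
  out <- list()
  for (ps in c("M", "F")) for (os in c("M", "F")) {
    sel <- rec@meioses$parentSex == ps & rec@meioses$offspringSex == os
    if (!any(sel)) next
    pp <- colMeans(rec@origin[sel, , drop = FALSE])
    out[[paste(ps, os)]] <- data.frame(
      locus = seq_along(pp),
      cM = if (length(rec@cM)) rec@cM else NA_real_,
      parentSex = ps, offspringSex = os, pPaternal = pp,
      nMeioses = sum(sel), row.names = NULL)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
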