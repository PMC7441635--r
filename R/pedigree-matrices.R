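#' Autosomal numerator relationship matrix (tabular method)
#'
#' Standard tabular recursion: `a_ii = 1 + 0.5 a_sd` and
#' `a_ij = 0.5 (a_js + a_jd)` for `j` placed earlier than `i`; an unknown
#' parent contributes 0.
#'
#' @param ped a prepared [Pedigree-class].
#' @return a [RelationshipMatrix-class] with kind `"A"`.
#' @examples
#' ped <- preparePedigree(data.frame(id = c("s","d","o"),
#'   sire = c(0,0,"s"), dam = c(0,0,"d"), sex = c("M","F","M")))
#' relValues(buildA(ped))["s", "o"]  # 0.5
#' @export
buildA <- function(ped) {
  n <- length(ped)
  A <- matrix(0, n, n, dimnames = list(ped@id, ped@id))
  s <- ped@sire; d <- ped@dam
  for (i in seq_len(n)) {
    if (i > 1) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(s[i])) row <- row + 0.5 * A[s[i], j]
      if (!is.na(d[i])) row <- row + 0.5 * A[d[i], j]
      A[i, j] <- row; A[j, i] <- row
    }
    A[i, i] <- 1 + if (!is.na(s[i]) && !is.na(d[i])) 0.5 * A[s[i], d[i]] else 0
  }
  .newRel(A, ped@sex, "A")
}

#' X-chromosome pedigree relationship matrix S
#'
#' Fernando-Grossman recursion for the X-specific region under the gene
#' content coding 0/1 in (hemizygous) males and 0/1/2 in females, so that
#' `Var(m) = S * 2pq`:
#' a male takes his single X from his dam, `S(i, x) = 0.5 S(dam, x)` with
#' diagonal exactly 0.5 (no sire contribution, no Mendelian sampling on a
#' single inherited copy beyond the dam's gamete draw);
#' a female receives the sire's X intact plus a dam gamete,
#' `S(i, x) = S(sire, x) + 0.5 S(dam, x)` with diagonal `1 + S(sire, dam)`.
#' Unknown parents contribute 0 (base males 0.5, base females 1 on the
#' diagonal).
#'
#' @param ped a prepared [Pedigree-class].
#' @return a [RelationshipMatrix-class] with kind `"S"`.
#' @examples
#' ped <- preparePedigree(data.frame(id = c("s","d","o"),
#'   sire = c(0,0,"s"), dam = c(0,0,"d"), sex = c("M","F","M")))
#' relValues(buildS(ped))["s", "o"]  # 0: no sire/son relationship on X
#' relValues(buildS(ped))["d", "o"]  # 0.5
#' @export
buildS <- function(ped) {
  .newRel(.buildSCore(ped), ped@sex, "S")
}

# Core S recursion over an optional pre-initialized founder block
# (rows/cols `init` are taken as given; used by the metafounder variant).
.buildSCore <- function(ped, initIdx = integer(0), initBlock = NULL) {
  n <- length(ped)
  S <- matrix(0, n, n, dimnames = list(ped@id, ped@id))
  if (length(initIdx)) S[initIdx, initIdx] <- initBlock
  s <- ped@sire; d <- ped@dam
  for (i in setdiff(seq_len(n), initIdx)) {
    if (i > 1) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (ped@sex[i] == "F" && !is.na(s[i])) row <- row + S[s[i], j]
      if (!is.na(d[i])) row <- row + 0.5 * S[d[i], j]
      S[i, j] <- row; S[j, i] <- row
    }
    S[i, i] <- if (ped@sex[i] == "M") 0.5 else
      1 + if (!is.na(s[i]) && !is.na(d[i])) S[s[i], d[i]] else 0
  }
  S
}

#' Sparse inverse of the X-chromosome relationship matrix
#'
#' Accumulates, for each individual, the contribution
#' `(1/v_i) (e_i - sum b_p e_p)(e_i - sum b_p e_p)'` where the regression
#' coefficients on known parents are `b = 0.5` on the dam for males and
#' `b = (1, 0.5)` on (sire, dam) for females, and the Mendelian-sampling
#' variance is `v_i = S_ii - b' S_pp b` (equal to `0.5 - 0.25 S_dd` for
#' both sexes when all parents are known). Unknown parents are dropped
#' from `b`, with `v_i` adjusted accordingly.
#'
#' @param ped a prepared [Pedigree-class].
#' @return a symmetric sparse matrix (`Matrix::dsCMatrix`) with individual
#'   ids as dimnames; at most 9 stored triplets per individual.
#' @examples
#' ped <- preparePedigree(data.frame(id = "m", sire = 0, dam = 0, sex = "M"))
#' as.matrix(buildSInverse(ped))  # 1/0.5 = 2
#' @export
buildSInverse <- function(ped) {
  n <- length(ped)
  S <- .buildSCore(ped)
  ii <- jj <- integer(0); xx <- numeric(0)
  for (i in seq_len(n)) {
    par <- c(if (ped@sex[i] == "F") ped@sire[i] else NA_integer_, ped@dam[i])
    b <- c(1, 0.5)[!is.na(par)]
    par <- par[!is.na(par)]
    v <- S[i, i] - if (length(par))
      drop(crossprod(b, S[par, par, drop = FALSE] %*% b)) else 0
    if (v <= 0) stop("non-positive Mendelian-sampling variance for '",
                     ped@id[i], "' (corrupted S diagonal)")
    coef <- c(1, -b); idx <- c(i, par)
    for (a in seq_along(idx)) for (bb in seq_along(idx)) {
      ii <- c(ii, idx[a]); jj <- c(jj, idx[bb])
      xx <- c(xx, coef[a] * coef[bb] / v)
    }
  }
  out <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                              dimnames = list(ped@id, ped@id))
  Matrix::forceSymmetric(out)
}

#' Metafounder configuration
#'
#' One male-line and one female-line metafounder per genetic group; `gamma`
#' holds the self- and cross-relationships among groups (a `g x g` symmetric
#' matrix, values in `[0, 2]`). `groupOf` optionally maps base individuals
#' (those with at least one unknown parent) to group names; with a single
#' group it may be omitted.
#'
#' @param gamma symmetric numeric matrix with group names as dimnames
#'   (a scalar is taken as a single group named `"g1"`).
#' @param groupOf named character vector: individual id -> group name.
#' @return a list of class `MetafounderConfig`.
#' @export
metafounderConfig <- function(gamma, groupOf = NULL) {
  if (is.null(dim(gamma))) {
    gamma <- matrix(gamma, 1, 1, dimnames = list("g1", "g1"))
  }
  stopifnot(isSymmetric(unname(gamma)), all(gamma >= 0), all(gamma <= 2))
  if (is.null(rownames(gamma)))
    dimnames(gamma) <- list(paste0("g", seq_len(nrow(gamma))),
                            paste0("g", seq_len(nrow(gamma))))
  structure(list(gamma = gamma, groupOf = groupOf),
            class = "MetafounderConfig")
}

#' X-chromosome relationship matrix with metafounders
#'
#' Same recursion as [buildS()], but every unknown parent slot is assigned
#' to a metafounder of the matching line (male-line metafounders replace
#' unknown sires, female-line ones unknown dams) and the founder block of
#' the matrix is seeded from `gamma` instead of 0: with weights `w = 0.5`
#' for a male-line and `w = 1` for a female-line metafounder, metafounders
#' `a` and `b` start at `S(a, b) = gamma[ga, gb] * w_a * w_b` (so a
#' male-line diagonal is `gamma/4` and a female-line diagonal `gamma`).
#' This is the seeding consistent with founder gametes drawn at frequency
#' 0.5 whose pairwise identity-by-descent is structured by `gamma`; with
#' `gamma = 0` the result equals [buildS()] exactly.
#'
#' @param ped a prepared [Pedigree-class].
#' @param cfg a [metafounderConfig()].
#' @return a [RelationshipMatrix-class] with kind `"S_gamma"`, over the real
#'   individuals only (metafounder rows are dropped).
#' @export
buildSMetafounders <- function(ped, cfg) {
  stopifnot(inherits(cfg, "MetafounderConfig"))
  gamma <- cfg$gamma
  groups <- rownames(gamma)
  grpOf <- rep(groups[1], length(ped))
  names(grpOf) <- ped@id
  if (!is.null(cfg$groupOf)) {
    unknownGrp <- setdiff(unique(cfg$groupOf), groups)
    if (length(unknownGrp)) stop("group '", unknownGrp[1],
                                 "' is not a row of gamma")
    grpOf[names(cfg$groupOf)] <- cfg$groupOf
  }
  if (length(groups) > 1) {
    # only slots that enter the X recursion need an assignment
    needs <- is.na(ped@dam) | (ped@sex == "F" & is.na(ped@sire))
    miss <- ped@id[needs & !(ped@id %in% names(cfg$groupOf))]
    if (length(miss))
      stop("base individual '", miss[1], "' has no metafounder assignment")
  }
  g <- length(groups)
  mfM <- paste0(".MF_M_", groups)   # male-line (unknown-sire) metafounders
  mfF <- paste0(".MF_F_", groups)   # female-line (unknown-dam) metafounders
  if (any(c(mfM, mfF) %in% ped@id))
    stop("pedigree ids clash with reserved metafounder labels")
  nmf <- 2L * g
  id2 <- c(mfM, mfF, ped@id)
  sex2 <- c(rep("M", g), rep("F", g), ped@sex)
  sire2 <- c(rep(NA_integer_, nmf),
             ifelse(is.na(ped@sire), match(mfM[match(grpOf, groups)], id2),
                    ped@sire + nmf))
  dam2 <- c(rep(NA_integer_, nmf),
            ifelse(is.na(ped@dam), match(mfF[match(grpOf, groups)], id2),
                   ped@dam + nmf))
  ped2 <- new("Pedigree", id = id2, sire = as.integer(sire2),
              dam = as.integer(dam2), sex = sex2)
  w <- c(rep(0.5, g), rep(1, g))
  gammaFull <- gamma[rep(seq_len(g), 2), rep(seq_len(g), 2), drop = FALSE]
  init <- gammaFull * tcrossprod(w)
  S2 <- .buildSCore(ped2, initIdx = seq_len(nmf), initBlock = init)
  keep <- (nmf + 1L):length(id2)
  .newRel(S2[keep, keep, drop = FALSE], ped@sex, "S_gamma",
          params = list(gamma = gamma))
}

#' Expected relationship matrix for a pseudo-autosomal locus
#'
#' Gametic recursion over the two gametes of every individual, for a PAR
#' locus at recombination fraction `r` from the pseudo-autosomal boundary
#' (measured in male meiosis). Sires transmit their paternal (Y-side)
#' haplotype to sons and their maternal (X-side) haplotype to daughters
#' with probability `1 - r`; dams transmit either haplotype with equal
#' probability, as on autosomes. The gametic identity matrix is built by
#' conditional expectation over parental gametes; the individual-level
#' entry is `P(i,j) = 0.5 * sum` over the four gamete pairs, with diagonal
#' `1 + Gamma(pat_i, mat_i)`. At `r = 0.5` the sex-gradient vanishes and
#' `P^r` equals the autosomal matrix `A` exactly.
#'
#' @param ped a prepared [Pedigree-class].
#' @param r recombination fraction in `[0, 0.5]` (use [haldane()] to convert
#'   a cM distance).
#' @return a [RelationshipMatrix-class] with kind `"P_r"`.
#' @export
buildPPar <- function(ped, r) {
  if (length(r) != 1 || is.na(r) || r < 0 || r > 0.5)
    stop("r must be a recombination fraction in [0, 0.5]")
  n <- length(ped)
  ng <- 2L * n                      # gametes: paternal = 2i-1, maternal = 2i
  G <- matrix(0, ng, ng)
  s <- ped@sire; d <- ped@dam
  for (i in seq_len(n)) {
    gp <- 2L * i - 1L; gm <- 2L * i
    prev <- seq_len(gp - 1L)
    # paternal gamete (from sire): weights on (sire pat, sire mat)
    if (!is.na(s[i])) {
      wp <- if (ped@sex[i] == "M") c(1 - r, r) else c(r, 1 - r)
      sp <- 2L * s[i] - 1L; sm <- 2L * s[i]
      G[gp, prev] <- wp[1] * G[sp, prev] + wp[2] * G[sm, prev]
      G[prev, gp] <- G[gp, prev]
    }
    G[gp, gp] <- 1
    # maternal gamete (from dam): equal weights
    prev <- seq_len(gm - 1L)
    if (!is.na(d[i])) {
      dp <- 2L * d[i] - 1L; dm <- 2L * d[i]
      G[gm, prev] <- 0.5 * G[dp, prev] + 0.5 * G[dm, prev]
      G[prev, gm] <- G[gm, prev]
    }
    G[gm, gm] <- 1
  }
  pat <- 2L * seq_len(n) - 1L; mat <- 2L * seq_len(n)
  P <- 0.5 * (G[pat, pat] + G[pat, mat] + G[mat, pat] + G[mat, mat])
  diag(P) <- 1 + G[cbind(pat, mat)]
  dimnames(P) <- list(ped@id, ped@id)
  .newRel(P, ped@sex, "P_r", params = list(r = r))
}

#' Rescale S to a different male gene-content coding
#'
#' When males are coded `{0, k}` instead of `{0, 1}` (for instance the
#' common `{0, 2}` dairy-cattle coding, `k = 2`), the compatible pedigree
#' matrix is obtained by multiplying the (male, male) block of S by `k^2`
#' and the (male, female) blocks by `k`; the female block is unchanged.
#'
#' @param S a [RelationshipMatrix-class] of kind `"S"` or `"S_gamma"`.
#' @param k positive scaling of the male coding.
#' @return a rescaled [RelationshipMatrix-class].
#' @export
rescaleS <- function(S, k) {
  stopifnot(is(S, "RelationshipMatrix"))
  if (!relKind(S) %in% c("S", "S_gamma"))
    stop("rescaleS expects a matrix of kind 'S' or 'S_gamma'")
  if (length(k) != 1 || is.na(k) || k <= 0) stop("k must be positive")
  w <- ifelse(relSex(S) == "M", k, 1)
  V <- relValues(S) * tcrossprod(w)
  .newRel(V, relSex(S), relKind(S), params = c(relParams(S), list(k = k)))
}
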