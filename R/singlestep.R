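#' Partition a pedigree relationship matrix by genotyped status
#'
#' Splits S (or any relationship matrix) into the blocks S11 (ungenotyped),
#' S12 and S22 (genotyped), the layout used by gene-content prediction and
#' the single-step matrix H^X.
#'
#' @param S a [RelationshipMatrix-class].
#' @param genotyped character ids of the genotyped individuals.
#' @return a list of class `PartitionedS`: blocks S11, S12, S22, id vectors
#'   `ungenotyped` and `genotyped`, and the parent matrix's sex/kind.
#' @export
partitionS <- function(S, genotyped) {
  stopifnot(is(S, "RelationshipMatrix"))
  ids <- relIds(S)
  if (!all(genotyped %in% ids))
    stop("genotyped ids absent from the matrix: ",
         paste(setdiff(genotyped, ids)[1], collapse = ", "))
  g <- ids %in% genotyped
  V <- relValues(S)
  structure(list(
    S11 = V[!g, !g, drop = FALSE], S12 = V[!g, g, drop = FALSE],
    S22 = V[g, g, drop = FALSE],
    ungenotyped = ids[!g], genotyped = ids[g],
    sex = relSex(S), ids = ids, kind = relKind(S)),
    class = "PartitionedS")
}

#' Predict centered gene content of ungenotyped individuals
#'
#' Best linear prediction from the pedigree covariance structure:
#' `z1_hat = S12 S22^{-1} z2`, with conditional (co)variance
#' `(S11 - S12 S22^{-1} S21) * 2pq` under multivariate normality.
#'
#' @param Spart a [partitionS()] result.
#' @param z2 numeric vector (or matrix, loci in columns) of centered gene
#'   content for the genotyped individuals, in `Spart$genotyped` order.
#' @param pq per-locus `p*q` variance term (scalar), used to scale the
#'   conditional variance.
#' @return list with `z1hat` (vector/matrix) and `condVar` (matrix).
#' @export
predictGeneContent <- function(Spart, z2, pq) {
  stopifnot(inherits(Spart, "PartitionedS"))
  z2 <- as.matrix(z2)
  if (nrow(z2) != length(Spart$genotyped))
    stop("z2 must have one row per genotyped individual")
  if (!is.null(rownames(z2))) {
    i <- match(Spart$genotyped, rownames(z2))
    if (anyNA(i)) stop("z2 row names do not cover the genotyped ids")
    z2 <- z2[i, , drop = FALSE]
  }
  S22i <- tryCatch(solve(Spart$S22),
                   error = function(e) stop(
                     "singular S22; consider blending first"))
  B <- Spart$S12 %*% S22i
  z1hat <- B %*% z2
  condVar <- (Spart$S11 - B %*% t(Spart$S12)) * 2 * pq
  rownames(z1hat) <- Spart$ungenotyped
  dimnames(condVar) <- list(Spart$ungenotyped, Spart$ungenotyped)
  list(z1hat = if (ncol(z1hat) == 1) drop(z1hat) else z1hat,
       condVar = condVar)
}

#' Single-step relationship matrix H^X
#'
#' Merges the pedigree matrix S (all individuals) with the genomic matrix
#' G^X (genotyped individuals) into one coherent matrix:
#' upper-left `S11 - S12 S22^{-1} S21 + S12 S22^{-1} G^X S22^{-1} S21`,
#' off-diagonal `S12 S22^{-1} G^X`, lower-right `G^X`. Rows/columns are
#' returned in the original pedigree order.
#'
#' @param Spart a [partitionS()] result.
#' @param GX a [RelationshipMatrix-class] over exactly the genotyped ids.
#' @return a [RelationshipMatrix-class] with kind `"HX"`.
#' @export
buildHX <- function(Spart, GX) {
  stopifnot(inherits(Spart, "PartitionedS"), is(GX, "RelationshipMatrix"))
  if (!identical(relIds(GX), Spart$genotyped))
    stop("GX ids must match the genotyped partition (same order)")
  Gv <- relValues(GX)
  S22i <- solve(Spart$S22)
  B <- Spart$S12 %*% S22i                  # S12 S22^-1
  H11 <- Spart$S11 - B %*% t(Spart$S12) + B %*% Gv %*% t(B)
  H12 <- B %*% Gv
  ids <- Spart$ids
  H <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  u <- match(Spart$ungenotyped, ids); g <- match(Spart$genotyped, ids)
  H[u, u] <- H11; H[u, g] <- H12; H[g, u] <- t(H12); H[g, g] <- Gv
  .newRel(H, Spart$sex, "HX", params = relParams(GX))
}

#' Inverse of the single-step matrix H^X
#'
#' `(H^X)^{-1} = S^{-1} + [[0, 0], [0, G_X^{-1} - S22^{-1}]]`: the sparse
#' pedigree inverse plus a dense correction on the genotyped block.
#' Requires an invertible G^X (blend with S first when the GRM is rank
#' deficient, e.g. because several males share an identical X).
#'
#' @param Sinv sparse inverse of S from [buildSInverse()], over all ids.
#' @param S22 the genotyped block of S (e.g. `Spart$S22`).
#' @param GX a [RelationshipMatrix-class] over the genotyped ids.
#' @param condMax condition-number threshold above which G^X is declared
#'   numerically singular (default 1e10).
#' @return a symmetric sparse matrix (`Matrix::dsCMatrix`) over all ids.
#' @export
buildHXInverse <- function(Sinv, S22, GX, condMax = 1e10) {
  stopifnot(is(GX, "RelationshipMatrix"))
  Gv <- relValues(GX)
  ev <- eigen(Gv, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > condMax)
    stop("G^X is numerically singular (condition number above ",
         format(condMax), "); blend with S first")
  ids <- rownames(Sinv)
  g <- match(relIds(GX), ids)
  if (anyNA(g)) stop("GX ids absent from S inverse")
  corr <- solve(Gv) - solve(S22)
  Hi <- as(Sinv, "generalMatrix")
  Hi[g, g] <- Hi[g, g] + corr
  Matrix::forceSymmetric((Hi + Matrix::t(Hi)) / 2)
}

#' Blend a genomic matrix with its pedigree expectation
#'
#' Two-stage compatibility adjustment followed by a convex combination.
#' First both matrices are put on a variance-equalized scale (the male
#' blocks are multiplied by `sqrt(2)` per male involved, equalizing male
#' and female variances); on that scale G^X is moved by the exact
#' two-equation linear adjustment `a + b * G` that matches its mean
#' diagonal and overall mean to those of S. The blend
#' `alpha * S + (1 - alpha) * G*` is then transformed back to the original
#' coding scale. A small `alpha` (0.05-0.10) restores positive
#' definiteness when individuals share identical X copies.
#'
#' @param S pedigree [RelationshipMatrix-class] (kind `"S"`/`"S_gamma"`).
#' @param GX genomic [RelationshipMatrix-class] over the same ids.
#' @param alpha weight on S, in `[0, 1]`; `beta` defaults to `1 - alpha`.
#' @param beta weight on G^X (overridable; default `1 - alpha`).
#' @return a [RelationshipMatrix-class] with kind `"blended"`; the fitted
#'   intercept/slope are reported in `params`.
#' @export
blendGRM <- function(S, GX, alpha = 0.05, beta = 1 - alpha) {
  stopifnot(is(S, "RelationshipMatrix"), is(GX, "RelationshipMatrix"))
  .checkSameIds(S, GX)
  if (length(alpha) != 1 || is.na(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]")
  w <- ifelse(relSex(S) == "M", sqrt(2), 1)   # variance-equalizing scale
  W <- tcrossprod(w)
  Sv <- relValues(S) * W
  Gv <- relValues(GX) * W
  mdS <- mean(diag(Sv)); maS <- mean(Sv)
  mdG <- mean(diag(Gv)); maG <- mean(Gv)
  if (abs(mdG - maG) < 1e-12) { b <- 1; a <- mdS - mdG }
  else { b <- (mdS - maS) / (mdG - maG); a <- mdS - b * mdG }
  Gstar <- a + b * Gv
  H <- (alpha * Sv + beta * Gstar) / W
  .newRel(H, relSex(S), "blended",
          params = list(alpha = alpha, beta = beta,
                        intercept = a, slope = b))
}
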