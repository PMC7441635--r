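#' Construct a GenotypeMatrix
#'
#' @param geno numeric matrix, individuals x loci (dimnames recommended).
#' @param sex character `"M"`/`"F"` per individual.
#' @param map optional data.frame with columns locus, region, bp, cM; by
#'   default every locus is taken as X-specific at unknown positions.
#' @return a [GenotypeMatrix-class].
#' @export
genotypeMatrix <- function(geno, sex, map = NULL) {
  geno <- as.matrix(geno)
  if (is.null(rownames(geno))) rownames(geno) <- paste0("ind", seq_len(nrow(geno)))
  if (is.null(colnames(geno))) colnames(geno) <- paste0("snp", seq_len(ncol(geno)))
  if (is.null(map))
    map <- data.frame(locus = colnames(geno), region = "X",
                      bp = NA_real_, cM = NA_real_)
  new("GenotypeMatrix", geno = geno, sex = sex, map = map)
}

#' Allele frequencies on the X-specific region
#'
#' Counts male genotypes as one allele and female genotypes as two:
#' `p = (sum male copies + sum female copies) / (n_males + 2 n_females)`,
#' per locus, excluding missing entries. Monomorphic loci (p = 0 or 1) are
#' flagged; they carry no variance and are dropped by the GRM builders.
#'
#' @param G a [GenotypeMatrix-class] (X-specific loci are used).
#' @param region which region's loci to use (default `"X"`).
#' @return data.frame with columns locus, p, monomorphic.
#' @export
estimateAlleleFreqX <- function(G, region = "X") {
  keep <- genoMap(G)$region == region
  if (!any(keep)) stop("no loci in region ", region)
  m <- genoValues(G)[, keep, drop = FALSE]
  male <- genoSex(G) == "M"
  copies <- colSums(m, na.rm = TRUE)
  denomPer <- ifelse(male, 1, 2)
  denom <- colSums((!is.na(m)) * denomPer)
  if (any(denom == 0))
    stop("locus with all entries missing: ",
         paste(colnames(m)[denom == 0], collapse = ", "))
  p <- copies / denom
  data.frame(locus = colnames(m), p = p,
             monomorphic = p <= 0 | p >= 1, row.names = NULL)
}

# Center gene content by sex and impute missing entries to the per-locus,
# per-sex mean (keeps E[Z] = 0 within each sex); returns the Z matrix.
.centerX <- function(m, sex, p, k = 1) {
  male <- sex == "M"
  Z <- m
  Z[male, ]  <- sweep(m[male, , drop = FALSE],  2, p, "-") * k
  Z[!male, ] <- sweep(m[!male, , drop = FALSE], 2, 2 * p, "-")
  if (anyNA(Z)) {
    for (sx in list(male, !male)) {
      sub <- Z[sx, , drop = FALSE]
      if (anyNA(sub)) {
        mu <- colMeans(sub, na.rm = TRUE)
        mu[is.nan(mu)] <- 0
        idx <- which(is.na(sub), arr.ind = TRUE)
        sub[idx] <- mu[idx[, 2]]
        Z[sx, ] <- sub
      }
    }
  }
  Z
}

#' Genomic relationship matrix for the X-specific region
#'
#' Gene content is centered by `p` in males (coded 0/1) and by `2p` in
#' females (coded 0/1/2); male rows are additionally scaled by the
#' dosage-compensation factor `k` (1 = none). The cross-product is divided
#' by `2 * sum(p_j q_j)`, referring relationships to the genetic variance
#' of an ideal female population:
#' `G^X = Z^X Z^X' / (2 sum p q)`.
#' Under the generating frequencies the male diagonal averages 0.5, the
#' female diagonal 1, and the overall mean is 0. With `weighted = TRUE`
#' each locus is divided by its own `2 p q` before an unweighted
#' cross-product, giving more weight to rare alleles.
#'
#' @param G a [GenotypeMatrix-class]; only X-specific loci are used.
#' @param p allele frequencies: a data.frame from [estimateAlleleFreqX()],
#'   a numeric vector (one per X locus), a single number (e.g. 0.5 for the
#'   metafounder-compatible similarity), or `NULL` to estimate from the
#'   sample.
#' @param k positive dosage-compensation scaling of male rows (default 1).
#' @param weighted logical; per-locus `2pq` weighting (default FALSE).
#' @return a [RelationshipMatrix-class] with kind `"GX"`.
#' @export
buildGX <- function(G, p = NULL, k = 1, weighted = FALSE) {
  stopifnot(is(G, "GenotypeMatrix"))
  if (length(k) != 1 || is.na(k) || k <= 0) stop("k must be positive")
  keep <- genoMap(G)$region == "X"
  if (!any(keep)) stop("no X-specific loci")
  m <- genoValues(G)[, keep, drop = FALSE]
  if (any(m[genoSex(G) == "M", ] > 1 + 1e-9, na.rm = TRUE))
    stop("male X gene content exceeds 1; normalize the {0,2} coding with ",
         "recodeMaleCoding() first")
  p <- .resolveFreq(p, G, m)
  freqSource <- attr(p, "source")
  poly <- p > 0 & p < 1
  nDrop <- sum(!poly)
  if (nDrop) message(nDrop, " monomorphic loci dropped")
  m <- m[, poly, drop = FALSE]; p <- p[poly]
  if (!ncol(m)) stop("all loci monomorphic: zero denominator")
  Z <- .centerX(m, genoSex(G), p, k)
  denom <- 2 * sum(p * (1 - p))
  Gm <- if (weighted) {
    Zw <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
    tcrossprod(Zw) / ncol(Zw)
  } else tcrossprod(Z) / denom
  .newRel(Gm, genoSex(G), "GX",
          params = list(k = k, weighted = weighted, nLoci = ncol(m),
                        freqSource = freqSource))
}

.resolveFreq <- function(p, G, m) {
  src <- "user"
  if (is.null(p)) {
    af <- estimateAlleleFreqX(G)
    p <- af$p[match(colnames(m), af$locus)]
    src <- "sample"
  } else if (is.data.frame(p)) {
    p <- p$p[match(colnames(m), p$locus)]
    if (anyNA(p)) stop("allele-frequency table misses some loci")
  } else if (length(p) == 1) {
    p <- rep(p, ncol(m)); src <- "fixed"
  } else if (length(p) != ncol(m)) {
    stop("length of p must match the number of loci used")
  }
  structure(as.numeric(p), source = src)
}

#' Autosomal genomic relationship matrix (VanRaden method 1)
#'
#' Both sexes coded 0/1/2, centered by `2p`:
#' `G = Z Z' / (2 sum p q)`. PAR loci follow autosomal rules and are
#' routed here (select them with `region = "PAR"`); X-specific loci never
#' are.
#'
#' @param G a [GenotypeMatrix-class].
#' @param p numeric frequencies (one per used locus), a frequency table,
#'   or `NULL` for sample frequencies (`colMeans/2`).
#' @param region `"A"` (default) or `"PAR"`.
#' @return a [RelationshipMatrix-class] with kind `"G"`.
#' @export
buildGAuto <- function(G, p = NULL, region = "A") {
  stopifnot(is(G, "GenotypeMatrix"), region %in% c("A", "PAR"))
  keep <- genoMap(G)$region == region
  if (!any(keep)) stop("no loci in region ", region)
  m <- genoValues(G)[, keep, drop = FALSE]
  if (is.null(p)) p <- colMeans(m, na.rm = TRUE) / 2
  else if (is.data.frame(p)) p <- p$p[match(colnames(m), p$locus)]
  else if (length(p) == 1) p <- rep(p, ncol(m))
  poly <- p > 0 & p < 1
  m <- m[, poly, drop = FALSE]; p <- p[poly]
  if (!ncol(m)) stop("all loci monomorphic: zero denominator")
  Z <- sweep(m, 2, 2 * p, "-")
  if (anyNA(Z)) {
    mu <- colMeans(Z, na.rm = TRUE)
    idx <- which(is.na(Z), arr.ind = TRUE)
    Z[idx] <- mu[idx[, 2]]
  }
  Gm <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  .newRel(Gm, genoSex(G), "G", params = list(region = region, nLoci = ncol(m)))
}

#' Recode male X gene content between codings
#'
#' Converts male entries at X-specific loci from the `{0, 2}` coding to
#' `{0, 1}` (halving) or back (doubling). A male entry of 1 under the
#' `{0, 2}` coding is a heterozygous call on a hemizygous region and is
#' rejected.
#'
#' @param G a [GenotypeMatrix-class].
#' @param from,to codings, `"0-2"` and `"0-1"` (either direction).
#' @return a recoded [GenotypeMatrix-class]; females unchanged.
#' @export
recodeMaleCoding <- function(G, from = "0-2", to = "0-1") {
  stopifnot(is(G, "GenotypeMatrix"),
            from %in% c("0-1", "0-2"), to %in% c("0-1", "0-2"))
  if (from == to) return(G)
  m <- genoValues(G)
  male <- genoSex(G) == "M"
  xc <- genoMap(G)$region == "X"
  blk <- m[male, xc, drop = FALSE]
  if (from == "0-2") {
    bad <- which(abs(blk - 1) < 1e-9, arr.ind = TRUE)
    if (nrow(bad))
      stop("heterozygous male call(s) on the X-specific region at locus ",
           colnames(blk)[bad[1, 2]])
    m[male, xc] <- blk / 2
  } else {
    m[male, xc] <- blk * 2
  }
  genotypeMatrix(m, genoSex(G), genoMap(G))
}
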