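#' Rescale relationships to correlations between individuals
#'
#' Divides each entry by the square root of the product of the two
#' diagonal elements: `c_ij = m_ij / sqrt(m_ii m_jj)`. On the X this puts
#' males (diagonal 0.5 in S) and females (diagonal 1) on a common scale:
#' e.g. a dam/son relationship of 0.5 becomes a correlation of 0.71, and
#' maternal half-brothers move from 0.25 to 0.50.
#'
#' @param M a [RelationshipMatrix-class] with strictly positive diagonal.
#' @return a [RelationshipMatrix-class] of kind `"correlation"` (unit
#'   diagonal).
#' @export
toCorrelation <- function(M) {
  stopifnot(is(M, "RelationshipMatrix"))
  V <- relValues(M)
  d <- diag(V)
  if (any(d <= 0))
    stop("non-positive diagonal for individual '",
         relIds(M)[which(d <= 0)[1]], "'")
  C <- V / tcrossprod(sqrt(d))
  diag(C) <- 1
  .newRel(C, relSex(M), "correlation",
          params = c(relParams(M), list(source = relKind(M))))
}

#' Classify individual pairs by pedigree relationship
#'
#' Labels pairs from parent links only: parent/offspring by parent sex and
#' offspring sex, full sibs (same known sire and dam), paternal and
#' maternal half sibs (one shared known parent, the other parents
#' distinct), each split by the sexes of the pair (MM/MF/FF), plus the
#' male/female diagonals. Full sibs are not double-counted as half sibs.
#' Pairs fitting no class are labeled `"other"`.
#'
#' @param ped a prepared [Pedigree-class].
#' @param keepOther keep the (large) "other" class rows (default FALSE).
#' @return data.frame with columns class, id1, id2.
#' @export
classifyPairs <- function(ped, keepOther = FALSE) {
  n <- length(ped)
  s <- ped@sire; d <- ped@dam; sex <- ped@sex; id <- ped@id
  rows <- list()
  add <- function(cls, i, j)
    rows[[length(rows) + 1L]] <<- data.frame(class = cls, id1 = id[i],
                                             id2 = id[j])
  sexPair <- function(i, j) {
    k <- sort(c(sex[i], sex[j]), decreasing = TRUE)  # M before F
    paste0(k[1], k[2])
  }
  sibTag <- c(MM = "two males", MF = "male/female", FF = "two females")
  for (i in seq_len(n)) add(
    if (sex[i] == "M") "male diagonal" else "female diagonal", i, i)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    cls <- NULL
    if (!is.na(s[j]) && s[j] == i)
      cls <- if (sex[j] == "M") "sire/son" else "sire/daughter"
    else if (!is.na(d[j]) && d[j] == i)
      cls <- if (sex[j] == "M") "dam/son" else "dam/daughter"
    else if (!is.na(s[i]) && !is.na(s[j]) && s[i] == s[j] &&
             !is.na(d[i]) && !is.na(d[j]) && d[i] == d[j])
      cls <- paste0("full-sibs (", sibTag[sexPair(i, j)], ")")
    else if (!is.na(s[i]) && !is.na(s[j]) && s[i] == s[j] &&
             !(!is.na(d[i]) && !is.na(d[j]) && d[i] == d[j]))
      cls <- paste0("paternal half-sibs (", sibTag[sexPair(i, j)], ")")
    else if (!is.na(d[i]) && !is.na(d[j]) && d[i] == d[j] &&
             !(!is.na(s[i]) && !is.na(s[j]) && s[i] == s[j]))
      cls <- paste0("maternal half-sibs (", sibTag[sexPair(i, j)], ")")
    if (!is.null(cls)) add(cls, i, j)
    else if (keepOther) add("other", i, j)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Per-class summary of relationship values
#'
#' Mean and standard deviation of the matrix entries within each pedigree
#' relationship class. Empty classes are absent from the output.
#'
#' @param M a [RelationshipMatrix-class].
#' @param classes a [classifyPairs()] table (ids must exist in `M`).
#' @return data.frame: class, n, mean, sd.
#' @export
classSummary <- function(M, classes) {
  stopifnot(is(M, "RelationshipMatrix"))
  V <- relValues(M)
  i <- match(classes$id1, relIds(M)); j <- match(classes$id2, relIds(M))
  ok <- !is.na(i) & !is.na(j)
  if (!all(ok)) message(sum(!ok), " pairs dropped (ids absent from matrix)")
  v <- V[cbind(i[ok], j[ok])]
  cls <- classes$class[ok]
  out <- do.call(rbind, lapply(split(v, cls), function(x)
    data.frame(n = length(x), mean = mean(x), sd = sd(x))))
  data.frame(class = rownames(out), out, row.names = NULL)
}

#' Correlation between two relationship matrices
#'
#' Pearson correlation of matching entries, over all entries, off-diagonal
#' entries only, or off-diagonal entries between males only.
#'
#' @param Mexp,Mreal [RelationshipMatrix-class] objects over the same ids.
#' @param scope `"all"`, `"offdiag"` or `"offdiag-males"`.
#' @return a single correlation.
#' @export
matrixCorrelation <- function(Mexp, Mreal,
                              scope = c("all", "offdiag", "offdiag-males")) {
  scope <- match.arg(scope)
  .checkSameIds(Mexp, Mreal)
  A <- relValues(Mexp); B <- relValues(Mreal)
  keep <- upper.tri(A, diag = scope == "all")
  if (scope == "offdiag-males") {
    male <- relSex(Mexp) == "M"
    keep <- keep & tcrossprod(male) > 0
  }
  cor(A[keep], B[keep])
}

#' SVD dimensionality of a relationship matrix
#'
#' Shares of total variance carried by each singular value are
#' `sv_i^2 / sum(sv_j^2)`; the report counts how many singular values are
#' needed to capture each variance threshold, plus the number of positive
#' singular values (numerical rank, values below `1e-10 * max` counted as
#' zero).
#'
#' @param M a [RelationshipMatrix-class].
#' @param thresholds variance fractions (default 0.90, 0.95, 0.99, 0.999).
#' @return list with `sv` (singular values), `counts` (named integer
#'   vector per threshold) and `nPositive`.
#' @export
svdDimensionality <- function(M, thresholds = c(0.90, 0.95, 0.99, 0.999)) {
  stopifnot(is(M, "RelationshipMatrix"))
  sv <- svd(relValues(M), nu = 0, nv = 0)$d
  share <- cumsum(sv^2) / sum(sv^2)
  counts <- vapply(thresholds, function(t) which(share >= t - 1e-12)[1],
                   integer(1))
  names(counts) <- paste0(thresholds * 100, "%")
  list(sv = sv, counts = counts, nPositive = sum(sv > 1e-10 * max(sv)))
}

#' Proportion of highly related pairs
#'
#' Fraction of unordered off-diagonal pairs whose (correlation-scaled)
#' relationship reaches each threshold; the denominator is `n(n-1)/2`, or
#' the male-male pair count for `subset = "males"`. On the X-specific
#' region these proportions are strongly inflated relative to an autosome
#' of the same map length, because males carry a single copy transmitted
#' without recombination.
#'
#' @param M a [RelationshipMatrix-class] (typically [toCorrelation()]
#'   output).
#' @param thresholds numeric thresholds (default 0.90, 0.95, 0.99).
#' @param subset `"all"` or `"males"`.
#' @return named numeric vector of proportions.
#' @export
highRelationshipProportions <- function(M, thresholds = c(0.90, 0.95, 0.99),
                                        subset = c("all", "males")) {
  subset <- match.arg(subset)
  stopifnot(is(M, "RelationshipMatrix"))
  V <- relValues(M)
  keep <- upper.tri(V)
  if (subset == "males") keep <- keep & tcrossprod(relSex(M) == "M") > 0
  v <- V[keep]
  out <- vapply(thresholds, function(t) mean(v >= t), numeric(1))
  names(out) <- paste0(">=", thresholds)
  out
}
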