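#' REML for a single-kinship animal model
#'
#' Fits `y = X b + u + e` with `u ~ N(0, sigma2u K)` and
#' `e ~ N(0, sigma2e I)` by restricted maximum likelihood. The model has a
#' single kinship matrix plus an identity residual, so the REML criterion
#' is maximized exactly by a one-dimensional profile search over the
#' variance ratio `lambda = sigma2u / sigma2e` after a one-time
#' eigendecomposition of K: no iterative convergence tuning is involved.
#' The ratio is searched on the log scale in `[1e-6, 1e6]`; estimates at
#' the search boundary are flagged but reported as converged (they are the
#' restricted-likelihood maximum on the interval, which is where the
#' optimum lies when the residual variance is essentially zero, e.g. for
#' gene content fitted with the correct relationship matrix).
#'
#' @param y numeric response vector.
#' @param K a [RelationshipMatrix-class] or symmetric matrix, same order
#'   as `y`; must be positive definite on the analyzed subset.
#' @param X fixed-effect design matrix (default: intercept only).
#' @param eig optional precomputed `eigen(K)` (used by [h2Scan()] to
#'   decompose once across loci).
#' @return a [VarianceComponents-class].
#' @export
remlSingleKinship <- function(y, K, X = NULL, eig = NULL) {
  if (is(K, "RelationshipMatrix")) K <- relValues(K)
  n <- length(y)
  if (is.null(eig)) {
    if (nrow(K) != n) stop("length of y must match K")
    eig <- eigen(K, symmetric = TRUE)
    if (min(eig$values) < 1e-10 * max(eig$values))
      stop("K is singular on this subset; consider blending first")
  }
  if (is.null(X)) X <- matrix(1, n, 1)
  ytil <- drop(crossprod(eig$vectors, y))
  Xtil <- crossprod(eig$vectors, X)
  d <- eig$values
  p <- ncol(X)
  nllk <- function(logLambda) {
    lam <- exp(logLambda)
    wInv <- lam * d + 1                    # Var(y*)/sigma2e
    w <- 1 / wInv
    XtWX <- crossprod(Xtil, Xtil * w)
    XtWy <- crossprod(Xtil, ytil * w)
    beta <- solve(XtWX, XtWy)
    r <- ytil - drop(Xtil %*% beta)
    rss <- sum(w * r^2)
    s2e <- rss / (n - p)
    0.5 * ((n - p) * log(s2e) + sum(log(wInv)) +
             as.numeric(determinant(XtWX, logarithm = TRUE)$modulus) + (n - p))
  }
  lo <- log(1e-6); hi <- log(1e6)
  opt <- optimize(nllk, c(lo, hi), tol = 1e-9)
  lam <- exp(opt$minimum)
  wInv <- lam * d + 1; w <- 1 / wInv
  XtWX <- crossprod(Xtil, Xtil * w)
  beta <- solve(XtWX, crossprod(Xtil, ytil * w))
  r <- ytil - drop(Xtil %*% beta)
  s2e <- sum(w * r^2) / (n - p)
  s2u <- lam * s2e
  boundary <- opt$minimum < lo + 1e-3 || opt$minimum > hi - 1e-3
  new("VarianceComponents", sigma2u = s2u, sigma2e = s2e,
      h2 = s2u / (s2u + s2e), logLik = -opt$objective,
      converged = TRUE, boundary = boundary)
}

#' Heritability-of-gene-content scan
#'
#' Quality-control statistic: fits [remlSingleKinship()] per locus with the
#' raw gene content (0/1 males, 0/1/2 females) as the response. When the
#' kinship matrix correctly models the locus's inheritance (S for
#' X-specific loci), the heritability of gene content is 1; the autosomal
#' matrix A misdescribes X inheritance and yields lower estimates. Loci
#' are filtered by minor allele frequency computed on the analyzed subset
#' (which matters for males-only runs).
#'
#' @param G a [GenotypeMatrix-class]; X-specific loci are scanned.
#' @param K a [RelationshipMatrix-class] covering the individuals of `G`.
#' @param mafMin minimum minor allele frequency (default 0.05).
#' @param subset `"all"` or `"males"`.
#' @param region map region to scan (default `"X"`).
#' @return data.frame: locus, maf, sigma2u, sigma2e, h2, boundary; with a
#'   `summary` attribute (mean/min h2, counts below 0.95 and 0.99).
#' @export
h2Scan <- function(G, K, mafMin = 0.05, subset = c("all", "males"),
                   region = "X") {
  subset <- match.arg(subset)
  stopifnot(is(G, "GenotypeMatrix"), is(K, "RelationshipMatrix"))
  ids <- genoIds(G)
  keepInd <- if (subset == "males") genoSex(G) == "M" else rep(TRUE, length(ids))
  if (!any(keepInd)) stop("empty individual subset")
  i <- match(ids[keepInd], relIds(K))
  if (anyNA(i)) stop("individuals missing from the kinship matrix")
  Kv <- relValues(K)[i, i]
  sex <- genoSex(G)[keepInd]
  keepLoc <- genoMap(G)$region == region
  m <- genoValues(G)[keepInd, keepLoc, drop = FALSE]
  denom <- sum(ifelse(sex == "M", 1, 2))
  p <- colSums(m) / denom
  maf <- pmin(p, 1 - p)
  sel <- maf >= mafMin
  if (!any(sel)) stop("no locus passes the MAF filter on this subset")
  m <- m[, sel, drop = FALSE]; maf <- maf[sel]
  eig <- eigen(Kv, symmetric = TRUE)
  if (min(eig$values) < 1e-10 * max(eig$values))
    stop("kinship matrix singular on this subset; consider blending first")
  fits <- lapply(seq_len(ncol(m)), function(j)
    remlSingleKinship(m[, j], Kv, eig = eig))
  out <- data.frame(
    locus = colnames(m), maf = maf,
    sigma2u = vapply(fits, slot, numeric(1), "sigma2u"),
    sigma2e = vapply(fits, slot, numeric(1), "sigma2e"),
    h2 = vapply(fits, slot, numeric(1), "h2"),
    boundary = vapply(fits, slot, logical(1), "boundary"),
    row.names = NULL)
  attr(out, "summary") <- data.frame(
    nLoci = nrow(out), meanH2 = mean(out$h2), minH2 = min(out$h2),
    nBelow095 = sum(out$h2 < 0.95), nBelow099 = sum(out$h2 < 0.99))
  out
}
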