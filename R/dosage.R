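#' Assemble a SexCovariance from raw components
#'
#' Computes the derived quantities (cross-sex genetic correlation and the
#' two dosage-compensation readouts `kVar = sqrt(2 sigma2m / sigma2f)`,
#' `kCov = sqrt(2) sigmamf / sigma2f`) from a 2x2 genetic covariance.
#'
#' @param sigma2m,sigmamf,sigma2f male variance, cross-sex covariance and
#'   female variance of the X-linked genetic effects.
#' @param sigma2eM,sigma2eF residual variances (default `NA`).
#' @param logLik,converged bookkeeping (defaults `NA`/`TRUE`).
#' @return a [SexCovariance-class].
#' @export
sexCovariance <- function(sigma2m, sigmamf, sigma2f,
                          sigma2eM = NA_real_, sigma2eF = NA_real_,
                          logLik = NA_real_, converged = TRUE) {
  rG <- if (sigma2m > 0 && sigma2f > 0)
    sigmamf / sqrt(sigma2m * sigma2f) else NA_real_
  new("SexCovariance", sigma2m = sigma2m, sigmamf = sigmamf,
      sigma2f = sigma2f, sigma2eM = sigma2eM, sigma2eF = sigma2eF,
      rG = rG,
      kVar = if (sigma2f > 0) sqrt(2 * max(sigma2m, 0) / sigma2f) else NA_real_,
      kCov = if (sigma2f > 0) sqrt(2) * sigmamf / sigma2f else NA_real_,
      logLik = logLik, converged = converged)
}

#' Bivariate REML for sex-specific X-linked genetic (co)variances
#'
#' Treats the phenotype of each sex as a separate trait; each individual
#' carries one record, assigned to the trait of its sex. The genetic
#' covariance structure is the 2x2 sex covariance matrix applied over the
#' X-chromosome GRM (`Var(u_i, u_j) = Sigma[sex_i, sex_j] * GX_ij`), with
#' per-sex intercepts and per-sex residual variances. The restricted
#' log-likelihood is maximized directly over a Cholesky parameterization
#' of the 2x2 genetic covariance (which keeps it positive semidefinite)
#' and log residual variances; the likelihood is evaluated exactly through
#' a low-rank Woodbury representation built on a pivoted Cholesky factor
#' of the GRM, so each evaluation costs O(r^3) with r = rank(G^X).
#' Deterministic given data and starting values (half the phenotypic
#' variance per component, zero covariance).
#'
#' Components are reported on the variance-equalized GRM scale (male
#' blocks scaled so that every sex's diagonal averages 1): the scale on
#' which the sex covariance matrix under a cross-sex correlation of 1 is
#' `sigma2u * [[k^2/2, k/sqrt(2)], [k/sqrt(2), 1]]`.
#'
#' Under full dosage compensation the male genetic variance is `k^2/2`
#' times the female one and the covariance `k/sqrt(2)` times it; the
#' factor k is recovered with [solveK()].
#'
#' @param y numeric phenotype vector aligned with `relIds(GX)`.
#' @param sex character `"M"`/`"F"` per record (default: taken from the
#'   GRM's sex slot).
#' @param GX a positive semidefinite [RelationshipMatrix-class].
#' @param maxit maximum optimizer iterations (default 2000).
#' @param reltol relative convergence tolerance (default 1e-8).
#' @return a [SexCovariance-class].
#' @export
bivariateReml <- function(y, sex = relSex(GX), GX, maxit = 2000,
                          reltol = 1e-8) {
  stopifnot(is(GX, "RelationshipMatrix"))
  n <- length(y)
  if (nrow(relValues(GX)) != n || length(sex) != n)
    stop("y, sex and GX must cover the same individuals")
  if (length(unique(sex)) < 2)
    stop("phenotypes from a single sex: k is irrelevant for sex-specific ",
         "traits; fit a univariate model instead")
  isM <- sex == "M"
  # Variance-equalized GRM: male blocks scaled by sqrt(2) per male, so the
  # diagonal averages 1 within each sex. On this scale the sex covariance
  # matrix is the (k^2/2, k/sqrt(2), 1) * sigma2u parameterization from
  # which k is solved.
  w <- ifelse(isM, sqrt(2), 1)
  Gt <- relValues(GX) * tcrossprod(w)
  ch <- suppressWarnings(chol(Gt, pivot = TRUE, tol = 1e-9 * nrow(Gt)))
  r <- attr(ch, "rank")
  piv <- attr(ch, "pivot")
  Tm <- matrix(0, n, r)
  Tm[piv, ] <- t(ch[seq_len(r), , drop = FALSE])
  pre <- lapply(list(M = isM, F = !isM), function(sx) {
    Ts <- Tm[sx, , drop = FALSE]
    list(A = crossprod(Ts), Tty = drop(crossprod(Ts, y[sx])),
         Tt1 = colSums(Ts), n = sum(sx), sumy = sum(y[sx]),
         yty = sum(y[sx]^2))
  })
  negll <- function(th) {
    L <- matrix(c(exp(th[1]), th[2], 0, exp(th[3])), 2, 2)  # rows: M, F
    se <- exp(th[4:5])                                      # resid M, F
    rM <- 1 / se[1]; rF <- 1 / se[2]
    cM <- L[1, ]; cF <- L[2, ]
    blk <- function(k, l)
      (cM[k] * cM[l] * rM) * pre$M$A + (cF[k] * cF[l] * rF) * pre$F$A
    M11 <- blk(1, 1); M12 <- blk(1, 2); M22 <- blk(2, 2)
    Mfull <- rbind(cbind(M11, M12), cbind(t(M12), M22))
    diag(Mfull) <- diag(Mfull) + 1
    ch <- tryCatch(chol(Mfull), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    wy <- c(cM[1] * rM * pre$M$Tty + cF[1] * rF * pre$F$Tty,
            cM[2] * rM * pre$M$Tty + cF[2] * rF * pre$F$Tty)
    wx <- cbind(c(cM[1] * rM * pre$M$Tt1, cM[2] * rM * pre$M$Tt1),
                c(cF[1] * rF * pre$F$Tt1, cF[2] * rF * pre$F$Tt1))
    solveCh <- function(v) backsolve(ch, backsolve(ch, v, transpose = TRUE))
    MiWy <- solveCh(wy); MiWx <- solveCh(wx)
    yVy <- rM * pre$M$yty + rF * pre$F$yty - sum(wy * MiWy)
    XVy <- c(rM * pre$M$sumy, rF * pre$F$sumy) - drop(crossprod(wx, MiWy))
    XVX <- diag(c(rM * pre$M$n, rF * pre$F$n)) - crossprod(wx, MiWx)
    beta <- tryCatch(solve(XVX, XVy), error = function(e) NULL)
    if (is.null(beta)) return(1e10)
    yPy <- yVy - sum(beta * XVy)
    logDetV <- pre$M$n * log(se[1]) + pre$F$n * log(se[2]) +
      2 * sum(log(diag(ch)))
    ldXVX <- as.numeric(determinant(XVX, logarithm = TRUE)$modulus)
    0.5 * (logDetV + ldXVX + yPy)
  }
  vm <- var(y[isM]); vf <- var(y[!isM])
  th0 <- c(0.5 * log(vm / 2), 0, 0.5 * log(vf / 2),
           log(vm / 2), log(vf / 2))
  opt <- optim(th0, negll, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = reltol))
  th <- opt$par
  L <- matrix(c(exp(th[1]), th[2], 0, exp(th[3])), 2, 2)
  Sg <- tcrossprod(L)
  sexCovariance(Sg[1, 1], Sg[1, 2], Sg[2, 2],
                sigma2eM = exp(th[4]), sigma2eF = exp(th[5]),
                logLik = -opt$value, converged = opt$convergence == 0)
}

#' Solve the dosage-compensation factor k
#'
#' Under a cross-sex genetic correlation of 1 the sex covariance matrix is
#' `sigma2u * [[k^2/2, k/sqrt(2)], [k/sqrt(2), 1]]`, so k can be solved
#' from the variances (`kVar`) or from the covariance (`kCov`). The two
#' readouts are compared: the estimate is flagged consistent when they
#' agree within `tol` (relative) and the genetic correlation is within
#' `tol` of 1. `k` is reported as `kVar` either way. The canonical cases
#' are `k = 1` (no compensation), `k = sqrt(2)` (equal variance across
#' sexes) and `k = 2` (full compensation: equal means, doubled male
#' variance).
#'
#' @param cov a [SexCovariance-class].
#' @param tol relative agreement tolerance (default 0.05).
#' @return list with `k` and logical `consistent`.
#' @export
solveK <- function(cov, tol = 0.05) {
  stopifnot(is(cov, "SexCovariance"))
  if (cov@sigma2f <= 0) stop("female genetic variance must be positive")
  consistent <- is.finite(cov@kCov) &&
    abs(cov@kVar - cov@kCov) / cov@kVar <= tol &&
    abs(cov@rG - 1) <= tol
  list(k = cov@kVar, consistent = consistent)
}

#' Ridge (SNP-BLUP) estimation of X-linked marker effects
#'
#' Solves the mixed-model equations for marker effects with an intercept
#' (per sex when both sexes are present): male design rows are the centered
#' gene content scaled by the dosage-compensation factor `k`, female rows
#' are centered by `2p`. With `Var(alpha) = sigma2a I` and residual
#' `sigma2e I`, `lambda = sigma2e / sigma2a`. The fitted genotypic values
#' `g = Z alpha_hat` reproduce GBLUP predictions computed with
#' [buildGX()] at the same `k` and a matched variance ratio
#' (`lambdaG = lambda / (2 sum pq)`).
#'
#' @param y numeric phenotypes aligned with the rows of `G`.
#' @param G a [GenotypeMatrix-class]; X-specific loci are used.
#' @param lambda ridge parameter `sigma2e / sigma2a` (> 0).
#' @param k male scaling factor (default 1).
#' @param p allele frequencies as in [buildGX()] (`NULL` = sample).
#' @return list with `alpha` (marker effects), `beta` (fixed effects) and
#'   `g` (genotypic values `Z alpha`).
#' @export
snpBlup <- function(y, G, lambda, k = 1, p = NULL) {
  stopifnot(is(G, "GenotypeMatrix"), lambda > 0)
  keep <- genoMap(G)$region == "X"
  m <- genoValues(G)[, keep, drop = FALSE]
  p <- .resolveFreq(p, G, m)
  poly <- p > 0 & p < 1
  m <- m[, poly, drop = FALSE]; p <- p[poly]
  Z <- .centerX(m, genoSex(G), p, k)
  sexes <- unique(genoSex(G))
  X <- if (length(sexes) == 2)
    cbind(M = as.numeric(genoSex(G) == "M"),
          F = as.numeric(genoSex(G) == "F"))
  else matrix(1, nrow(Z), 1)
  nl <- ncol(Z)
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + diag(lambda, nl)))
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  sol <- tryCatch(solve(C, rhs), error = function(e)
    stop("singular mixed-model equations"))
  beta <- sol[seq_len(ncol(X))]
  alpha <- sol[-seq_len(ncol(X))]
  list(alpha = alpha, beta = beta,
       g = drop(Z %*% alpha))
}
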