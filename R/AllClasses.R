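#' Pedigree of individuals with sex and parent links
#'
#' Topologically ordered pedigree: every parent precedes its offspring.
#' Parent slots hold integer indices into the pedigree itself;
#' `NA` marks an unknown parent (the base-population convention: unknown
#' parents contribute nothing to relationship recursions).
#'
#' @slot id character vector of unique individual labels.
#' @slot sire integer vector of sire indices (`NA` = unknown).
#' @slot dam integer vector of dam indices (`NA` = unknown).
#' @slot sex character vector, `"M"` or `"F"`.
#'
#' @seealso [preparePedigree()] to construct one from a raw table.
#' @export
setClass("Pedigree",
  representation(id = "character", sire = "integer", dam = "integer",
                 sex = "character"),
  validity = function(object) {
    n <- length(object@id)
    msg <- character()
    if (length(object@sire) != n || length(object@dam) != n ||
        length(object@sex) != n)
      msg <- c(msg, "id, sire, dam and sex must have equal length")
    if (anyDuplicated(object@id))
      msg <- c(msg, "duplicated individual ids")
    if (!all(object@sex %in% c("M", "F")))
      msg <- c(msg, "sex must be 'M' or 'F'")
    ok <- function(p) all(is.na(p) | (p >= 1 & p <= n))
    if (!ok(object@sire) || !ok(object@dam))
      msg <- c(msg, "parent indices out of range")
    # parents precede offspring
    i <- seq_len(n)
    if (any(object@sire >= i, na.rm = TRUE) || any(object@dam >= i, na.rm = TRUE))
      msg <- c(msg, "pedigree is not topologically sorted (parent after offspring)")
    if (any(object@sex[object@sire[!is.na(object@sire)]] != "M"))
      msg <- c(msg, "a recorded sire is not male")
    if (any(object@sex[object@dam[!is.na(object@dam)]] != "F"))
      msg <- c(msg, "a recorded dam is not female")
    if (length(msg)) msg else TRUE
  })

#' Labeled symmetric relationship matrix
#'
#' Holds a dense symmetric matrix of (co)relationships between individuals,
#' together with the individuals' sexes and a tag recording which
#' construction produced it (`"A"`, `"S"`, `"S_gamma"`, `"P_r"`, `"G"`,
#' `"GX"`, `"HX"`, `"blended"`, `"correlation"`). Free-form parameters
#' (recombination fraction, dosage-compensation factor k, blending weight,
#' allele-frequency source) live in `params`.
#'
#' @slot values numeric matrix with individual ids as dimnames.
#' @slot sex character vector, `"M"`/`"F"` per individual.
#' @slot kind character tag naming the construction.
#' @slot params list of construction parameters.
#' @export
setClass("RelationshipMatrix",
  representation(values = "matrix", sex = "character", kind = "character",
                 params = "list"),
  prototype(params = list()),
  validity = function(object) {
    v <- object@values
    msg <- character()
    if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
    if (is.null(rownames(v)) || is.null(colnames(v)) ||
        !identical(rownames(v), colnames(v)))
      msg <- c(msg, "matrix must carry identical row and column ids")
    if (length(object@sex) != nrow(v))
      msg <- c(msg, "sex vector length must match matrix dimension")
    if (nrow(v) && max(abs(v - t(v))) > 1e-12)
      msg <- c(msg, "matrix is not symmetric within 1e-12")
    if (length(msg)) msg else TRUE
  })

#' Sex-aware gene-content matrix with a marker map
#'
#' Individuals by loci gene content: males carry 0/1 copies at X-specific
#' loci (hemizygous), females 0/1/2. `NA` marks a missing genotype. The
#' map assigns each locus to a region (`"X"` for the X-specific part,
#' `"PAR"`, `"A"` for autosomes) with physical (bp) and genetic (cM)
#' positions; for PAR loci, cM is the male genetic distance to the
#' pseudo-autosomal boundary.
#'
#' @slot geno numeric matrix, individuals x loci, with dimnames.
#' @slot sex character vector `"M"`/`"F"` per individual.
#' @slot map data.frame with columns locus, region, bp, cM.
#' @export
setClass("GenotypeMatrix",
  representation(geno = "matrix", sex = "character", map = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (length(object@sex) != nrow(object@geno))
      msg <- c(msg, "sex length must match number of individuals")
    if (!all(object@sex %in% c("M", "F")))
      msg <- c(msg, "sex must be 'M' or 'F'")
    if (nrow(object@map) != ncol(object@geno))
      msg <- c(msg, "map must have one row per locus")
    need <- c("locus", "region", "bp", "cM")
    if (!all(need %in% names(object@map)))
      msg <- c(msg, "map needs columns locus, region, bp, cM")
    else {
      if (!all(object@map$region %in% c("X", "PAR", "A")))
        msg <- c(msg, "map region must be 'X', 'PAR' or 'A'")
      xc <- object@map$region == "X"
      if (any(xc) && length(object@sex)) {
        # {0,2}-coded male input is tolerated here so it can be normalized
        # with recodeMaleCoding(); the GRM builders insist on {0,1}
        m <- object@geno[object@sex == "M", xc, drop = FALSE]
        if (any(m > 2 + 1e-9, na.rm = TRUE))
          msg <- c(msg, "male gene content exceeds 2 at an X-specific locus")
      }
    }
    if (length(msg)) msg else TRUE
  })

#' REML variance components for a single-kinship model
#'
#' @slot sigma2u genetic variance attached to the kinship matrix.
#' @slot sigma2e residual variance.
#' @slot h2 sigma2u / (sigma2u + sigma2e).
#' @slot logLik restricted log-likelihood at the optimum.
#' @slot converged logical.
#' @slot boundary logical; TRUE when the variance ratio hit the search bound.
#' @export
setClass("VarianceComponents",
  representation(sigma2u = "numeric", sigma2e = "numeric", h2 = "numeric",
                 logLik = "numeric", converged = "logical",
                 boundary = "logical"))

#' Sex-specific genetic covariance structure on the X
#'
#' Output of the bivariate (male-trait / female-trait) REML model with the
#' X-chromosome GRM. The dosage-compensation factor is derived two ways:
#' `kVar = sqrt(2 sigma2m / sigma2f)` from the variances and
#' `kCov = sqrt(2) sigmamf / sigma2f` from the cross-sex covariance; the
#' two agree when the cross-sex genetic correlation is 1.
#'
#' @slot sigma2m male genetic variance.
#' @slot sigmamf cross-sex genetic covariance.
#' @slot sigma2f female genetic variance.
#' @slot sigma2eM,sigma2eF residual variances per sex.
#' @slot rG cross-sex genetic correlation.
#' @slot kVar,kCov dosage-compensation factor from variances / covariance.
#' @slot logLik restricted log-likelihood.
#' @slot converged logical.
#' @export
setClass("SexCovariance",
  representation(sigma2m = "numeric", sigmamf = "numeric", sigma2f = "numeric",
                 sigma2eM = "numeric", sigma2eF = "numeric", rG = "numeric",
                 kVar = "numeric", kCov = "numeric", logLik = "numeric",
                 converged = "logical"))

#' Gene-dropping simulation configuration
#'
#' Defines pedigree structure, marker panels and trait architecture for the
#' simulator. Loci are independent (inter-locus recombination 1/2) when the
#' relevant map is `NULL`; otherwise Haldane crossovers are laid on the map.
#'
#' @slot generations,nMales,nFemales discrete-generation pedigree layout.
#' @slot nLoci number of loci to drop.
#' @slot p base allele frequency (scalar, recycled, or one per locus).
#' @slot mapLengthX female X-specific map length in Morgan (0 = full linkage;
#'   `NA` = independent loci).
#' @slot parMap numeric vector of male cM distances from each PAR locus to
#'   the pseudo-autosomal boundary (`NA` = single locus at the PAB).
#' @slot k dosage-compensation factor for simulated phenotypes.
#' @slot rG cross-sex genetic correlation for simulated phenotypes.
#' @slot h2Target heritability of the simulated trait in females.
#' @slot seed integer seed; mandatory, every run is reproducible.
#' @export
setClass("SimConfig",
  representation(generations = "numeric", nMales = "numeric",
                 nFemales = "numeric", nLoci = "numeric", p = "numeric",
                 mapLengthX = "numeric", parMap = "numeric", k = "numeric",
                 rG = "numeric", h2Target = "numeric", seed = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@seed) != 1 || is.na(object@seed))
      msg <- c(msg, "a scalar seed is mandatory")
    if (any(object@p <= 0 | object@p >= 1))
      msg <- c(msg, "base allele frequencies must lie in (0,1)")
    if (object@generations < 1) msg <- c(msg, "need at least one generation")
    if (object@nMales < 1 || object@nFemales < 1)
      msg <- c(msg, "each generation needs males and females")
    if (length(msg)) msg else TRUE
  })

#' Per-meiosis gamete-origin record
#'
#' One row of `meioses` per (parent, offspring) transmission; `origin` has
#' one row per meiosis and one column per locus, with 1 when the transmitted
#' allele came from the parent's paternal haplotype and 0 for maternal.
#' For the X-specific region, sire-to-daughter meioses carry the sire's
#' single (maternal) X intact with zero crossovers, and sires transmit no
#' X-specific gamete to sons.
#'
#' @slot meioses data.frame: parent, offspring, parentSex, offspringSex,
#'   crossovers.
#' @slot origin integer matrix, meioses x loci (NA where undefined).
#' @slot cM numeric vector of locus positions (cM to the PAB for PAR loci).
#' @export
setClass("GameteRecord",
  representation(meioses = "data.frame", origin = "matrix", cM = "numeric"))
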