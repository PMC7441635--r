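#' @name accessors
#' @title Accessors for xkin classes
#' @description Small accessor layer: prefer these over direct slot access.
#' @param x an xkin object.
#' @return the requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("pedIds", function(x) standardGeneric("pedIds"))
#' @rdname accessors
#' @export
setGeneric("pedSex", function(x) standardGeneric("pedSex"))
#' @rdname accessors
#' @export
setGeneric("pedSire", function(x) standardGeneric("pedSire"))
#' @rdname accessors
#' @export
setGeneric("pedDam", function(x) standardGeneric("pedDam"))

#' @rdname accessors
#' @export
setGeneric("relValues", function(x) standardGeneric("relValues"))
#' @rdname accessors
#' @export
setGeneric("relIds", function(x) standardGeneric("relIds"))
#' @rdname accessors
#' @export
setGeneric("relSex", function(x) standardGeneric("relSex"))
#' @rdname accessors
#' @export
setGeneric("relKind", function(x) standardGeneric("relKind"))
#' @rdname accessors
#' @export
setGeneric("relParams", function(x) standardGeneric("relParams"))

#' @rdname accessors
#' @export
setGeneric("genoValues", function(x) standardGeneric("genoValues"))
#' @rdname accessors
#' @export
setGeneric("genoIds", function(x) standardGeneric("genoIds"))
#' @rdname accessors
#' @export
setGeneric("genoSex", function(x) standardGeneric("genoSex"))
#' @rdname accessors
#' @export
setGeneric("genoMap", function(x) standardGeneric("genoMap"))

#' @rdname accessors
#' @export
setMethod("pedIds", "Pedigree", function(x) x@id)
#' @rdname accessors
#' @export
setMethod("pedSex", "Pedigree", function(x) x@sex)
#' @rdname accessors
#' @export
setMethod("pedSire", "Pedigree", function(x) x@sire)
#' @rdname accessors
#' @export
setMethod("pedDam", "Pedigree", function(x) x@dam)

#' @rdname accessors
#' @export
setMethod("relValues", "RelationshipMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("relIds", "RelationshipMatrix", function(x) rownames(x@values))
#' @rdname accessors
#' @export
setMethod("relSex", "RelationshipMatrix", function(x) x@sex)
#' @rdname accessors
#' @export
setMethod("relKind", "RelationshipMatrix", function(x) x@kind)
#' @rdname accessors
#' @export
setMethod("relParams", "RelationshipMatrix", function(x) x@params)

#' @rdname accessors
#' @export
setMethod("genoValues", "GenotypeMatrix", function(x) x@geno)
#' @rdname accessors
#' @export
setMethod("genoIds", "GenotypeMatrix", function(x) rownames(x@geno))
#' @rdname accessors
#' @export
setMethod("genoSex", "GenotypeMatrix", function(x) x@sex)
#' @rdname accessors
#' @export
setMethod("genoMap", "GenotypeMatrix", function(x) x@map)

#' @describeIn accessors number of individuals in a pedigree.
#' @export
setMethod("length", "Pedigree", function(x) length(x@id))

setMethod("show", "Pedigree", function(object) {
  n <- length(object@id)
  cat("Pedigree with", n, "individuals (",
      sum(object@sex == "M"), "males,", sum(object@sex == "F"), "females );",
      sum(is.na(object@sire) & is.na(object@dam)), "founders\n")
})

setMethod("show", "RelationshipMatrix", function(object) {
  cat(sprintf("RelationshipMatrix '%s' over %d individuals\n",
              object@kind, nrow(object@values)))
  if (length(object@params))
    cat("  params:", paste(names(object@params), unlist(lapply(object@params,
        function(p) paste(format(p), collapse = ","))), sep = "=",
        collapse = "; "), "\n")
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d individuals x %d loci (regions: %s)\n",
              nrow(object@geno), ncol(object@geno),
              paste(names(table(object@map$region)),
                    table(object@map$region), collapse = ", ")))
})

setMethod("show", "VarianceComponents", function(object) {
  cat(sprintf(
    "VarianceComponents: sigma2u=%.4g sigma2e=%.4g h2=%.4f logLik=%.3f%s\n",
    object@sigma2u, object@sigma2e, object@h2, object@logLik,
    if (object@boundary) " (boundary)" else ""))
})

setMethod("show", "SexCovariance", function(object) {
  cat(sprintf(
    "SexCovariance: sigma2m=%.4g sigmamf=%.4g sigma2f=%.4g rG=%.3f\n",
    object@sigma2m, object@sigmamf, object@sigma2f, object@rG))
  cat(sprintf("  kVar=%.4f kCov=%.4f logLik=%.3f converged=%s\n",
              object@kVar, object@kCov, object@logLik, object@converged))
})
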