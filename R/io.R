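#' Read a pedigree file
#'
#' CSV or TSV with header `id,sire,dam,sex`; unknown parents coded 0, NA
#' or empty; sex coded M/F or 1/2 (1 = male). The separator is sniffed
#' from the header line.
#'
#' @param path file path.
#' @return a prepared [Pedigree-class].
#' @export
readPedigree <- function(path) {
  sep <- .sniffSep(path)
  raw <- read.table(path, header = TRUE, sep = sep,
                    colClasses = "character", check.names = FALSE)
  names(raw) <- tolower(names(raw))
  preparePedigree(raw)
}

.sniffSep <- function(path) {
  hdr <- readLines(path, n = 1)
  if (grepl("\t", hdr)) "\t" else if (grepl(",", hdr)) "," else ""
}

#' Read genotypes from PLINK .raw-style or plain TSV
#'
#' `format = "raw"`: PLINK additive export with columns FID IID PAT MAT
#' SEX PHENOTYPE followed by one column per SNP (`name_allele`); sex is
#' taken from the SEX column (1 = male, 2 = female).
#' `format = "tsv"`: individuals in rows, first column `id`, one column
#' per locus; `sex` must then be supplied (named vector or a
#' [Pedigree-class]).
#'
#' Region assignment: with a `map` (data.frame `chrom, locus, cM, bp`) and
#' a pseudo-autosomal boundary `pab`, loci on `xChrom` at `bp <= pab` are
#' X-specific and loci beyond it PAR; other chromosomes are autosomal.
#' Without a map all loci are treated as X-specific. Male entries of 2 at
#' X-specific loci are interpreted as the `{0,2}` coding and halved with a
#' notice; a male entry of 1 under that coding would be a heterozygous
#' call on a hemizygous region and raises an error listing the loci.
#'
#' @param path genotype file.
#' @param format `"raw"` or `"tsv"`.
#' @param sex named character vector (`"M"`/`"F"`) or a [Pedigree-class];
#'   required for `"tsv"`.
#' @param map optional marker map data.frame (`chrom, locus, cM, bp`).
#' @param pab pseudo-autosomal boundary position in bp (the X-specific
#'   region ends at the PAB; e.g. 133300518 on the cattle X).
#' @param xChrom chromosome label(s) treated as X (default `c("X","30")`).
#' @return a [GenotypeMatrix-class] in `{0,1}` male coding.
#' @export
readGenotypes <- function(path, format = c("raw", "tsv"), sex = NULL,
                          map = NULL, pab = Inf, xChrom = c("X", "30")) {
  format <- match.arg(format)
  if (format == "raw") {
    tab <- read.table(path, header = TRUE, check.names = FALSE)
    meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(meta %in% names(tab)))
      stop("not a .raw file: missing header columns ",
           paste(setdiff(meta, names(tab)), collapse = ", "))
    ids <- as.character(tab$IID)
    sx <- ifelse(tab$SEX == 1, "M", ifelse(tab$SEX == 2, "F", NA))
    m <- as.matrix(tab[, setdiff(names(tab), meta), drop = FALSE])
    colnames(m) <- sub("_[ACGT0-9]+$", "", colnames(m))
    rownames(m) <- ids
  } else {
    sep <- .sniffSep(path)
    tab <- read.table(path, header = TRUE, sep = sep, check.names = FALSE)
    ids <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- ids
    sx <- rep(NA_character_, length(ids))
  }
  if (!is.null(sex)) {
    if (is(sex, "Pedigree")) sex <- setNames(pedSex(sex), pedIds(sex))
    sx <- unname(sex[ids])
  }
  if (anyNA(sx))
    stop("missing sex for individual(s): ",
         paste(ids[is.na(sx)][1], collapse = ", "))
  mapDf <- .resolveMap(colnames(m), map, pab, xChrom)
  # normalize male coding on the X-specific part
  male <- sx == "M"; xc <- mapDf$region == "X"
  if (any(male) && any(xc)) {
    blk <- m[male, xc, drop = FALSE]
    if (any(blk > 1, na.rm = TRUE)) {
      odd <- colnames(blk)[apply(abs(blk - 1) < 1e-9, 2, any, na.rm = TRUE)]
      if (length(odd))
        stop("heterozygous male calls on X-specific loci: ",
             paste(utils::head(odd, 5), collapse = ", "))
      message("male {0,2} coding detected on the X-specific region; halved")
      m[male, xc] <- blk / 2
    }
  }
  genotypeMatrix(m, sx, mapDf)
}

.resolveMap <- function(loci, map, pab, xChrom) {
  if (is.null(map))
    return(data.frame(locus = loci, region = "X", bp = NA_real_,
                      cM = NA_real_))
  i <- match(loci, map$locus)
  if (anyNA(i)) stop("loci absent from the map: ",
                     paste(loci[is.na(i)][1], collapse = ", "))
  map <- map[i, ]
  onX <- as.character(map$chrom) %in% xChrom
  region <- ifelse(!onX, "A", ifelse(map$bp <= pab, "X", "PAR"))
  data.frame(locus = loci, region = region, bp = map$bp, cM = map$cM)
}

#' Write / read a relationship matrix
#'
#' Formats: `"square"` (TSV, row labels in the first column, header of
#' column labels), `"triplet"` (id1, id2, value for the upper triangle,
#' entries below 1e-12 omitted with a count in a header comment), and
#' `"gcta-text"` (index pairs, non-missing locus count, value, plus a
#' companion `.id` file). Square and triplet round-trip to full printed
#' precision (12 significant digits).
#'
#' @param M a [RelationshipMatrix-class].
#' @param path output path.
#' @param format `"square"`, `"triplet"` or `"gcta-text"`.
#' @param sex needed when re-reading (`readGRM`) since files carry no sex.
#' @param nLoci locus count written in gcta-text (default from params).
#' @return `writeGRM` returns `path` invisibly; `readGRM` returns a
#'   [RelationshipMatrix-class].
#' @export
writeGRM <- function(M, path, format = c("square", "triplet", "gcta-text"),
                     nLoci = NULL) {
  format <- match.arg(format)
  stopifnot(is(M, "RelationshipMatrix"))
  V <- relValues(M); ids <- relIds(M)
  fmt <- function(x) formatC(x, digits = 12, format = "g")
  if (format == "square") {
    df <- data.frame(id = ids, apply(V, 2, fmt), check.names = FALSE)
    colnames(df) <- c("id", ids)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "triplet") {
    ut <- which(upper.tri(V, diag = TRUE), arr.ind = TRUE)
    v <- V[ut]
    keep <- abs(v) >= 1e-12
    con <- file(path, "w")
    writeLines(paste0("# omitted ", sum(!keep), " near-zero entries"), con)
    write.table(data.frame(id1 = ids[ut[keep, 1]], id2 = ids[ut[keep, 2]],
                           value = fmt(v[keep])),
                con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  } else {
    if (is.null(nLoci)) nLoci <- relParams(M)$nLoci
    if (is.null(nLoci)) nLoci <- NA_integer_
    ut <- which(upper.tri(V, diag = TRUE), arr.ind = TRUE)
    # GCTA convention: i >= j, both lower-triangle indices
    write.table(data.frame(i = ut[, 2], j = ut[, 1], n = nLoci,
                           value = fmt(V[ut])),
                path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    write.table(data.frame(fid = ids, iid = ids), paste0(path, ".id"),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' @rdname writeGRM
#' @param kind kind tag to stamp on the matrix read back.
#' @export
readGRM <- function(path, format = c("square", "triplet"), sex = NULL,
                    kind = "G") {
  format <- match.arg(format)
  if (format == "square") {
    tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
    ids <- as.character(tab[[1]])
    V <- as.matrix(tab[, -1, drop = FALSE])
    dimnames(V) <- list(ids, ids)
  } else {
    tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                      colClasses = c("character", "character", "numeric"))
    ids <- unique(c(tab$id1, tab$id2))
    V <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    V[cbind(tab$id1, tab$id2)] <- tab$value
    V[cbind(tab$id2, tab$id1)] <- tab$value
  }
  if (is.null(sex)) sex <- rep("F", nrow(V))
  .newRel(V, sex, kind)
}
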