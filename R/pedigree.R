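#' Prepare a pedigree from a raw table
#'
#' Validates and topologically sorts pedigree records so that every parent
#' precedes its offspring, the substrate required by all relationship
#' recursions. Unknown parents may be coded `0`, `NA` or the empty string.
#' Sex may be coded `M`/`F` or `1`/`2` (1 = male, the PLINK convention).
#' A parent label that never appears as an individual is added as a founder
#' with the sex its role implies. Individuals recorded both as sire and as
#' dam, duplicated ids, and ancestry cycles are rejected with the offending
#' individual named.
#'
#' @param raw a data.frame with columns `id`, `sire`, `dam`, `sex`.
#' @return a [Pedigree-class] object.
#' @examples
#' ped <- preparePedigree(data.frame(
#'   id = c("o", "s", "d"), sire = c("s", 0, 0),
#'   dam = c("d", 0, 0), sex = c("M", "M", "F")))
#' pedIds(ped)  # parents first
#' @export
preparePedigree <- function(raw) {
  raw <- as.data.frame(raw)
  need <- c("id", "sire", "dam", "sex")
  if (!all(need %in% names(raw)))
    stop("pedigree table needs columns id, sire, dam, sex")
  id   <- trimws(as.character(raw$id))
  sire <- .normParent(raw$sire)
  dam  <- .normParent(raw$dam)
  sex  <- .normSex(raw$sex)
  if (any(id == "" | is.na(id))) stop("empty individual id")
  if (anyDuplicated(id))
    stop("duplicated id: ", id[duplicated(id)][1])

  both <- intersect(stats::na.omit(unique(sire)), stats::na.omit(unique(dam)))
  if (length(both))
    stop("individual '", both[1], "' is recorded both as sire and as dam")

  # implicit founders for parent labels absent from the id column
  addS <- setdiff(stats::na.omit(unique(sire)), id)
  addF <- setdiff(stats::na.omit(unique(dam)), id)
  if (length(addS) || length(addF)) {
    id   <- c(addS, addF, id)
    sire <- c(rep(NA_character_, length(addS) + length(addF)), sire)
    dam  <- c(rep(NA_character_, length(addS) + length(addF)), dam)
    sex  <- c(rep("M", length(addS)), rep("F", length(addF)), sex)
  }

  # role vs recorded sex
  badS <- id[id %in% sire & sex == "F"]
  if (length(badS)) stop("sire '", badS[1], "' is recorded as female")
  badD <- id[id %in% dam & sex == "M"]
  if (length(badD)) stop("dam '", badD[1], "' is recorded as male")

  # Kahn topological sort on parent -> offspring edges
  n <- length(id)
  si <- match(sire, id)
  di <- match(dam, id)
  nParents <- (!is.na(si)) + (!is.na(di))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) if (!is.na(p))
      children[[p]] <- c(children[[p]], i)
  }
  order <- integer(0)
  ready <- which(nParents == 0)
  remaining <- nParents
  while (length(ready)) {
    v <- ready[1]; ready <- ready[-1]
    order <- c(order, v)
    for (ch in children[[v]]) {
      remaining[ch] <- remaining[ch] - 1L
      if (remaining[ch] == 0L) ready <- c(ready, ch)
    }
  }
  if (length(order) < n) {
    onCycle <- setdiff(seq_len(n), order)
    stop("pedigree cycle detected involving '", id[onCycle[1]], "'")
  }
  # stable: keep input order among individuals whose parents are all placed
  id <- id[order]; sex <- sex[order]
  new("Pedigree", id = id,
      sire = match(sire[order], id), dam = match(dam[order], id),
      sex = sex)
}

.normParent <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("0", "", "NA", ".") | is.na(x)] <- NA_character_
  x
}

.normSex <- function(x) {
  x <- toupper(trimws(as.character(x)))
  out <- ifelse(x %in% c("M", "1"), "M", ifelse(x %in% c("F", "2"), "F", NA))
  if (anyNA(out)) stop("unrecognized sex code: ", x[is.na(out)][1])
  out
}

#' Subset pedigree-derived matrices and pedigrees by individual
#'
#' @param ped a [Pedigree-class].
#' @param ids character ids to look up.
#' @return integer indices of `ids` in the pedigree (error if absent).
#' @keywords internal
.pedIndex <- function(ped, ids) {
  i <- match(ids, ped@id)
  if (anyNA(i)) stop("unknown individual(s): ",
                     paste(ids[is.na(i)], collapse = ", "))
  i
}
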