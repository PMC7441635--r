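#' Haldane map function and its inverse
#'
#' Converts a genetic distance in centiMorgan to a recombination fraction
#' under Haldane's model (no interference), `c = (1 - exp(-2 d/100))/2`,
#' and back.
#'
#' @param cM genetic distance in centiMorgan.
#' @param c recombination fraction in `[0, 0.5)`.
#' @return recombination fraction (for `haldane`) or distance in cM
#'   (for `haldaneInv`).
#' @examples
#' haldane(0)      # 0
#' haldane(Inf)    # 0.5
#' haldaneInv(haldane(25))
#' @export
haldane <- function(cM) (1 - exp(-2 * cM / 100)) / 2

#' @rdname haldane
#' @export
haldaneInv <- function(c) {
  stopifnot(all(c >= 0 & c < 0.5))
  -50 * log(1 - 2 * c)
}

# Symmetrize: average the matrix with its transpose (guards accumulated
# floating-point asymmetry after block algebra).
.sym <- function(M) (M + t(M)) / 2

# Internal constructor used everywhere a RelationshipMatrix is produced.
.newRel <- function(values, sex, kind, params = list()) {
  new("RelationshipMatrix", values = .sym(values), sex = sex, kind = kind,
      params = params)
}

.checkSameIds <- function(a, b, what = "matrices") {
  if (!identical(relIds(a), relIds(b)))
    stop(what, " must share the same individuals in the same order")
}
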