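#' @keywords internal
"_PACKAGE"

## Allele universe ------------------------------------------------------------

## Stigma-level (di-allelic) locus: two alleles only.  S2 is dominant over S1
## in the stigma, so the stigma phenotype of a heterozygote is S2.  S2S2 does
## not occur: the dominant allele behaves as if lethal when homozygous, which
## is why every tree is S1S1 (group G2) or S1S2 (group G1).
DSI_ALLELES <- c("S1", "S2")

## Ovary-level (poly-allelic) locus: six alleles under the transitive
## dominance hierarchy R6 > R2 > R1 = R3 = R5 > R4, acting on the pollen side
## only (all six are codominant in the pistil).  R6R6 is inadmissible.
PASI_ALLELES <- c("R1", "R2", "R3", "R4", "R5", "R6")
PASI_RANK <- c(R1 = 2L, R2 = 3L, R3 = 2L, R4 = 1L, R5 = 2L, R6 = 4L)

## Alleles whose determinants degrade within a few days of pollination;
## R1 and R3 determinants are stable through the whole receptive window.
SHORT_LIVED_DEFAULT <- c("R2", "R4", "R5", "R6")

#' Allele sets of the two self-incompatibility loci
#'
#' The stigma screen uses two alleles (`S1`, `S2`); the ovary screen uses six
#' (`R1`..`R6`) ranked by the pollen-side dominance hierarchy
#' `R6 > R2 > R1 = R3 = R5 > R4`.
#'
#' @return `dsi_alleles()` and `pasi_alleles()` return character vectors of
#'   allele names; `pasi_dominance_rank()` returns a named integer vector of
#'   dominance ranks (larger dominates smaller, equal ranks are codominant).
#' @examples
#' pasi_dominance_rank()
#' @export
pasi_alleles <- function() PASI_ALLELES

#' @rdname pasi_alleles
#' @export
dsi_alleles <- function() DSI_ALLELES

#' @rdname pasi_alleles
#' @export
pasi_dominance_rank <- function() PASI_RANK

sort_pasi <- function(pair) pair[order(match(pair, PASI_ALLELES))]

pair_label <- function(pair) paste(sort_pasi(pair), collapse = "")

set_label <- function(dets) paste(sort_pasi(dets), collapse = "")

check_pasi_pair <- function(pair, what = "PASI genotype") {
  if (!is.character(pair) || length(pair) != 2L) {
    stop(what, " must be two allele names, e.g. c(\"R2\", \"R3\")", call. = FALSE)
  }
  bad <- setdiff(pair, PASI_ALLELES)
  if (length(bad)) {
    stop(what, ": unknown allele(s) ", paste(bad, collapse = ", "),
         "; expected ", paste(PASI_ALLELES, collapse = ", "), call. = FALSE)
  }
  if (all(pair == "R6")) {
    stop(what, ": R6R6 is inadmissible (the top dominant allele cannot occur ",
         "homozygous)", call. = FALSE)
  }
  sort_pasi(pair)
}

check_dsi_group <- function(group) {
  if (length(group) != 1L || !group %in% c("G1", "G2")) {
    stop("dsi_group must be \"G1\" (S1S2) or \"G2\" (S1S1); S2S2 does not exist",
         call. = FALSE)
  }
  group
}
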