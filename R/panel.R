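## Packaged reference data ----------------------------------------------------

## Occurrence counts of ovary-locus allele pairs among deciphered olive
## varieties, split by stigma-locus group (26 G1 + 39 G2 varieties).  R5R6 has
## not been encountered in either group; R4R4 never at all.
PAIR_COUNTS <- data.frame(
  pasi_pair = rep(c("R1R2", "R1R3", "R1R4", "R1R5", "R1R6",
                    "R2R3", "R2R4", "R2R5", "R2R6", "R3R4",
                    "R3R5", "R3R6", "R4R5", "R4R6", "R5R6"), times = 2),
  dsi_group = rep(c("G1", "G2"), each = 15),
  count = c(0, 3, 7, 2, 1, 2, 3, 0, 2, 1, 1, 0, 3, 1, 0,
            3, 0, 0, 0, 0, 7, 10, 1, 4, 3, 1, 1, 8, 1, 0),
  stringsAsFactors = FALSE
)

#' Reference genotype-frequency panel of deciphered olive varieties
#'
#' Occurrence counts of the fifteen heterozygous ovary-locus allele pairs
#' among deciphered varieties of each stigma-locus group, with normalized
#' weights.  Both groups contain pairs built from all six alleles, consistent
#' with the two loci assorting independently; the pair spectra differ (e.g.
#' `R1R3`/`R1R4` are frequent in G1, `R2`-carrying pairs dominate G2), which
#' is why mate availability is genotype-dependent.
#'
#' @return Data frame with columns `dsi_group`, `pasi_pair`, `count`, and
#'   `weight` (counts normalized over the whole panel).
#' @examples
#' head(reference_panel_frequencies())
#' @seealso [mate_availability()], [generate_fixture()]
#' @export
reference_panel_frequencies <- function() {
  p <- PAIR_COUNTS[, c("dsi_group", "pasi_pair", "count")]
  p$weight <- p$count / sum(p$count)
  p
}

#' Packaged panel of named reference varieties
#'
#' Genotypes of the olive varieties used in the worked examples and in the
#' paternity diagnostics.  The `source` column distinguishes genotypes
#' published as such (`"stated"`) from genotypes inferred here as the
#' minimal assignment consistent with the published cross and paternity
#' outcomes (`"inferred"`).
#'
#' @return Data frame with columns `name`, `dsi_group`, `pasi_pair`, `source`.
#' @examples
#' ref <- reference_varieties()
#' ref[ref$name == "Tanche", ]
#' @export
reference_varieties <- function() {
  read_panel(system.file("extdata", "variety_panel.csv", package = "oliveSI"))
}

#' Look up a reference variety as a genotype object
#'
#' @param name Variety name present in [reference_varieties()].
#' @return A [variety_genotype()].
#' @examples
#' ref_variety("Picholine")
#' @export
ref_variety <- function(name) {
  ref <- reference_varieties()
  i <- match(name, ref$name)
  if (is.na(i)) stop("unknown reference variety '", name, "'", call. = FALSE)
  variety_genotype(ref$name[i], ref$dsi_group[i], ref$pasi_pair[i])
}
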