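## The two successive screens -------------------------------------------------

#' The stigma-level and ovary-level compatibility screens
#'
#' `dsi_screen()` is the first screen, acting at pollen germination on the
#' stigma: pollen carrying the same S determinant as the host stigma is
#' rejected.  Because G1 stigmas and G1 pollen both present `S2` (and G2 both
#' present `S1`), germination succeeds exactly when host and donor belong to
#' different groups.
#'
#' `pasi_screen()` is the second screen, acting on pollen tubes at the ovary:
#' the tube is rejected if any of its expressed (dominance-filtered) R
#' determinants matches either allele of the host's ovary pair, which are
#' codominantly expressed female-side.
#'
#' @param host,donor [variety_genotype()] objects; `host` is the seed (female)
#'   parent, `donor` the pollen source.
#' @return Logical: `TRUE` if the pollen passes the screen.
#' @examples
#' tanche <- variety_genotype("Tanche", "G2", "R2R3")
#' cayon <- variety_genotype("Cayon", "G1", "R1R4")
#' dsi_screen(tanche, cayon)   # TRUE: G2 x G1
#' pasi_screen(tanche, cayon)  # TRUE: pollen {R1} misses ovary {R2,R3}
#' @export
dsi_screen <- function(host, donor) {
  stopifnot(inherits(host, "variety_genotype"), inherits(donor, "variety_genotype"))
  pollen_phenotype(donor)$dsi != pistil_phenotype(host)$stigma_dsi
}

#' @rdname dsi_screen
#' @export
pasi_screen <- function(host, donor) {
  stopifnot(inherits(host, "variety_genotype"), inherits(donor, "variety_genotype"))
  length(intersect(dominance_filter(donor$pasi), host$pasi)) == 0L
}

#' Cross verdict under the two successive screens
#'
#' Applies the stigma screen, then (only if it passed) the ovary screen, and
#' codes the outcome `"1-1"` (germination and fruit set), `"1-0"` (germination
#' but no fruit), or `"0-0"` (no germination).  `"0-1"` is unconstructible:
#' the ovary screen never operates on pollen that failed at the stigma, and
#' parthenocarpic fruit does not occur.
#'
#' @inheritParams dsi_screen
#' @return An object of class `cross_verdict`: list with `dsi_pass`,
#'   `pasi_pass` (`NA` when the stigma screen failed), and `code`.
#' @examples
#' tanche <- variety_genotype("Tanche", "G2", "R2R3")
#' picholine <- variety_genotype("Picholine", "G1", "R1R3")
#' dssm_verdict(tanche, picholine)  # "1-0": germinates, no fruit (shared R3)
#' @export
dssm_verdict <- function(host, donor) {
  d <- dsi_screen(host, donor)
  p <- if (d) pasi_screen(host, donor) else NA
  code <- if (!d) "0-0" else if (p) "1-1" else "1-0"
  structure(list(dsi_pass = d, pasi_pass = p, code = code,
                 host = host$name, donor = donor$name),
            class = "cross_verdict")
}

#' @export
print.cross_verdict <- function(x, ...) {
  cat(sprintf("<cross> %s x %s : %s  (stigma %s%s)\n",
              x$host, x$donor, x$code,
              if (x$dsi_pass) "pass" else "reject",
              if (is.na(x$pasi_pass)) "" else
                paste0(", ovary ", if (x$pasi_pass) "pass" else "reject")))
  invisible(x)
}

#' Shorthand for the verdict code of a cross
#'
#' @inheritParams dsi_screen
#' @return `"1-1"`, `"1-0"`, or `"0-0"`.
#' @export
verdict_code <- function(host, donor) dssm_verdict(host, donor)$code

## Matrix, asymmetry, availability --------------------------------------------

#' Female genotype x pollen class compatibility matrix
#'
#' The 20 admissible female ovary genotypes crossed with the 9 pollen classes
#' give 180 combinations.  A cell is 1 when the pollen class shares no
#' determinant with the female pair (ovary screen passes), 0 otherwise.  The
#' stigma screen is not folded in: it depends only on the G groups and is
#' reported separately by [dsi_screen()].
#'
#' @return A 20 x 9 integer matrix with genotype row names and pollen-class
#'   column names.
#' @examples
#' m <- compatibility_matrix()
#' m["R2R3", "R1"]    # 1: Tanche-type ovary accepts R1 pollen
#' m["R2R3", "R1R3"]  # 0: codominant R1R3 pollen shares R3
#' @export
compatibility_matrix <- function() {
  females <- enumerate_female_genotypes()
  classes <- enumerate_pollen_classes()
  m <- matrix(0L, nrow = length(females), ncol = length(classes),
              dimnames = list(names(females), names(classes)))
  for (i in seq_along(females)) {
    for (j in seq_along(classes)) {
      m[i, j] <- as.integer(length(intersect(classes[[j]], females[[i]])) == 0L)
    }
  }
  m
}

#' Reciprocal-cross asymmetry
#'
#' Pollen-side dominance makes some variety pairs fruit in one direction only:
#' the dominance filter can hide, in one partner's pollen, the allele that its
#' own ovary still presents.  Returns both directed verdicts and whether the
#' pair is asymmetric.
#'
#' @param a,b [variety_genotype()] objects.
#' @return List with `ab` (verdict for a as host), `ba`, and logical
#'   `asymmetric`.
#' @examples
#' manz <- variety_genotype("Manzanilla", "G2", "R1R2")
#' arbe <- variety_genotype("Arbequina", "G1", "R1R3")
#' cross_asymmetry(manz, arbe)  # "1-0" vs "1-1"
#' @export
cross_asymmetry <- function(a, b) {
  ab <- dssm_verdict(a, b)
  ba <- dssm_verdict(b, a)
  list(ab = ab, ba = ba, asymmetric = ab$code != ba$code)
}

#' Probability of matching a fully compatible pollinizer
#'
#' Given a host genotype and a frequency panel of candidate donor genotypes,
#' returns the probability that a donor drawn at random from the panel passes
#' both screens (verdict `"1-1"`).  Weights are normalized internally, so raw
#' occurrence counts can be supplied directly.
#'
#' @param host A [variety_genotype()].
#' @param panel Data frame with columns `dsi_group`, `pasi_pair`, and `weight`
#'   (non-negative, not all zero), such as [reference_panel_frequencies()].
#' @return A probability in `[0, 1]`.
#' @examples
#' tanche <- variety_genotype("Tanche", "G2", "R2R3")
#' mate_availability(tanche, reference_panel_frequencies())
#' @export
mate_availability <- function(host, panel) {
  stopifnot(inherits(host, "variety_genotype"), is.data.frame(panel))
  need <- c("dsi_group", "pasi_pair", "weight")
  if (!all(need %in% names(panel))) {
    stop("panel must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(panel) == 0L) stop("empty panel", call. = FALSE)
  w <- panel$weight
  if (any(w < 0) || sum(w) <= 0) {
    stop("panel weights must be non-negative and sum to a positive value",
         call. = FALSE)
  }
  w <- w / sum(w)
  ok <- vapply(seq_len(nrow(panel)), function(i) {
    donor <- variety_genotype("panel", panel$dsi_group[i], panel$pasi_pair[i])
    verdict_code(host, donor) == "1-1"
  }, logical(1))
  sum(w[ok])
}
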