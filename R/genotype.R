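## Variety genotypes and genotype -> phenotype derivation ---------------------

#' Construct a variety genotype
#'
#' A variety is described by its di-allelic stigma-locus genotype, given as the
#' compatibility group (`"G1"` = S1S2, `"G2"` = S1S1; S2S2 does not exist), and
#' its poly-allelic ovary-locus genotype, an unordered pair drawn from
#' `R1`..`R6` (homozygotes allowed, `R6R6` excluded).
#'
#' @param name Variety name (free text).
#' @param dsi_group `"G1"` or `"G2"`.
#' @param pasi Character vector of two allele names (e.g. `c("R2","R3")`) or a
#'   compact pair label such as `"R2R3"`.
#' @return An object of class `variety_genotype`: a list with elements `name`,
#'   `dsi_group`, and `pasi` (sorted allele pair).
#' @examples
#' tanche <- variety_genotype("Tanche", "G2", "R2R3")
#' pollen_phenotype(tanche)
#' @seealso [pollen_phenotype()], [pistil_phenotype()], [dssm_verdict()]
#' @export
variety_genotype <- function(name, dsi_group, pasi) {
  stopifnot(is.character(name), length(name) == 1L)
  if (is.character(pasi) && length(pasi) == 1L) pasi <- split_pair_label(pasi)
  v <- structure(
    list(name = name,
         dsi_group = check_dsi_group(dsi_group),
         pasi = check_pasi_pair(pasi, sprintf("variety '%s'", name))),
    class = "variety_genotype")
  v
}

split_pair_label <- function(label) {
  parts <- regmatches(label, gregexpr("R[0-9]+", label))[[1]]
  if (length(parts) != 2L) {
    stop("cannot parse PASI pair label '", label,
         "'; expected e.g. \"R2R3\"", call. = FALSE)
  }
  parts
}

#' @export
print.variety_genotype <- function(x, ...) {
  cat(sprintf("<variety> %s  %s %s  (notation %s)\n",
              x$name, x$dsi_group, pair_label(x$pasi),
              format_genotype_notation(x)))
  invisible(x)
}

#' @export
format.variety_genotype <- function(x, ...) {
  sprintf("%s [%s %s]", x$name, x$dsi_group, pair_label(x$pasi))
}

same_genotype <- function(a, b) {
  a$dsi_group == b$dsi_group && identical(a$pasi, b$pasi)
}

## Dominance filtering --------------------------------------------------------

#' Pollen-side dominance filter for an ovary-locus allele pair
#'
#' On the pollen side the six ovary-locus alleles obey the transitive dominance
#' hierarchy `R6 > R2 > R1 = R3 = R5 > R4`.  The pollen of a plant (sporophytic
#' determination) expresses only the allele(s) of its diploid pair that are not
#' dominated by the partner allele: equal ranks are codominant and both are
#' expressed; a homozygote expresses its single allele.
#'
#' @param pair Allele pair as for [variety_genotype()].
#' @return Character vector of expressed allele names (length 1 or 2, sorted).
#' @examples
#' dominance_filter(c("R1", "R3"))  # codominant -> both expressed
#' dominance_filter(c("R1", "R2"))  # R2 dominates -> "R2"
#' @export
dominance_filter <- function(pair) {
  pair <- check_pasi_pair(pair)
  r <- PASI_RANK[pair]
  unique(pair[r == max(r)])
}

#' Phenotypes expressed by a variety's pollen and pistil
#'
#' `pollen_phenotype()` gives the determinants carried by the (sporophytically
#' determined, uniform) pollen of a variety: the stigma-locus determinant is
#' `S2` for G1 plants (S1S2) and `S1` for G2 plants (S1S1); the ovary-locus
#' determinants are the dominance-filtered pair (one of nine possible classes).
#'
#' `pistil_phenotype()` gives the female side: the stigma expresses `S2` for G1
#' (`S2` dominant over `S1` in the stigma) and `S1` for G2, while the ovary
#' expresses both alleles of the pair codominantly.
#'
#' @param v A [variety_genotype()].
#' @return `pollen_phenotype()`: an object of class `pollen_class`, a list with
#'   `dsi` (the S determinant) and `pasi` (expressed R determinants).
#'   `pistil_phenotype()`: a list with `stigma_dsi` and `ovary_pasi`.
#' @examples
#' picholine <- variety_genotype("Picholine", "G1", "R1R3")
#' pollen_phenotype(picholine)   # S2 pollen with codominant {R1, R3}
#' pistil_phenotype(picholine)
#' @export
pollen_phenotype <- function(v) {
  stopifnot(inherits(v, "variety_genotype"))
  structure(
    list(dsi = if (v$dsi_group == "G1") "S2" else "S1",
         pasi = dominance_filter(v$pasi)),
    class = "pollen_class")
}

#' @export
print.pollen_class <- function(x, ...) {
  cat(sprintf("<pollen class> %s_%s\n", x$dsi, set_label(x$pasi)))
  invisible(x)
}

#' @rdname pollen_phenotype
#' @export
pistil_phenotype <- function(v) {
  stopifnot(inherits(v, "variety_genotype"))
  list(stigma_dsi = if (v$dsi_group == "G1") "S2" else "S1",
       ovary_pasi = v$pasi)
}

## Enumerations ---------------------------------------------------------------

#' Enumerate admissible ovary-locus genotypes and pollen classes
#'
#' Over six alleles there are 21 unordered pairs; removing the inadmissible
#' `R6R6` leaves exactly 20 admissible female genotypes (15 heterozygotes and
#' 5 homozygotes, `R4R4` admissible though unobserved in deciphered varieties).
#' Applying the pollen-side dominance filter to all of them yields exactly 9
#' distinct pollen classes: the six singletons plus the codominant pairs
#' `{R1,R3}`, `{R1,R5}`, `{R3,R5}`.
#'
#' @return `enumerate_female_genotypes()`: a named list of 20 sorted allele
#'   pairs in lexicographic order, names like `"R2R3"`.
#'   `enumerate_pollen_classes()`: a named list of the 9 expressed-determinant
#'   sets, singletons first, names like `"R1"` / `"R1R3"`.
#' @examples
#' length(enumerate_female_genotypes())  # 20
#' names(enumerate_pollen_classes())     # 9 classes
#' @export
enumerate_female_genotypes <- function() {
  idx <- which(upper.tri(diag(6), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  pairs <- lapply(seq_len(nrow(idx)), function(i) {
    PASI_ALLELES[c(idx[i, "row"], idx[i, "col"])]
  })
  pairs <- Filter(function(p) !identical(p, c("R6", "R6")), pairs)
  names(pairs) <- vapply(pairs, pair_label, character(1))
  pairs
}

#' @rdname enumerate_female_genotypes
#' @export
enumerate_pollen_classes <- function() {
  imgs <- lapply(enumerate_female_genotypes(), dominance_filter)
  labs <- vapply(imgs, set_label, character(1))
  imgs <- imgs[!duplicated(labs)]
  names(imgs) <- labs[!duplicated(labs)]
  ## canonical order: singletons by allele index, then codominant pairs
  ord <- order(lengths(imgs), names(imgs))
  imgs[ord]
}

## Notation -------------------------------------------------------------------

#' Parse and format the compact variety-genotype notation
#'
#' Genotypes are written `<group>-[<stigma pair>]_<pollen determinants>`, e.g.
#' `"1-[R1R3]_R1R3"`: leading `1`/`2` is the stigma-locus group (G1/G2), the
#' bracketed pair is the ovary genotype (codominant in the pistil), and the
#' suffix after `_` lists the pollen-expressed determinants.  The digit-only
#' dialect (`"1-[13]_13"`, brackets optional, each digit one allele) is
#' accepted on input; output always uses explicit allele names, since two-digit
#' strings such as `"13"` would otherwise be ambiguous between `R1,R3` and a
#' hypothetical `R13`.  The pollen suffix is redundant and is validated against
#' the dominance filter; an inconsistent suffix is an error.
#'
#' @param text Notation string.
#' @param name Variety name to attach to the parsed genotype.
#' @param v A [variety_genotype()].
#' @return `parse_genotype_notation()` returns a [variety_genotype()];
#'   `format_genotype_notation()` returns the canonical string.
#' @examples
#' parse_genotype_notation("2-[23]_2", name = "Tanche")
#' format_genotype_notation(variety_genotype("Picholine", "G1", "R1R3"))
#' @export
parse_genotype_notation <- function(text, name = text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regexec("^([12])-\\[?([R0-9]+)\\]?_([R0-9]+)$", text)
  parts <- regmatches(text, m)[[1]]
  if (length(parts) != 4L) {
    stop("malformed genotype notation '", text,
         "'; expected e.g. \"1-[R1R3]_R1R3\" or \"1-[13]_13\"", call. = FALSE)
  }
  group <- if (parts[2] == "1") "G1" else "G2"
  pair <- parse_allele_tokens(parts[3], text)
  if (length(pair) != 2L) {
    stop("stigma pair in '", text, "' must list exactly two alleles", call. = FALSE)
  }
  v <- variety_genotype(name, group, pair)
  suffix <- parse_allele_tokens(parts[4], text)
  expressed <- dominance_filter(v$pasi)
  if (!setequal(suffix, expressed)) {
    stop("pollen suffix '", parts[4], "' in '", text,
         "' contradicts the dominance hierarchy; expected _",
         set_label(expressed), call. = FALSE)
  }
  v
}

parse_allele_tokens <- function(tok, context) {
  alleles <- if (grepl("R", tok, fixed = TRUE)) {
    regmatches(tok, gregexpr("R[0-9]+", tok))[[1]]
  } else {
    paste0("R", strsplit(tok, "")[[1]])
  }
  bad <- setdiff(alleles, PASI_ALLELES)
  if (length(bad)) {
    stop("unknown allele(s) ", paste(bad, collapse = ", "), " in '", context,
         "'", call. = FALSE)
  }
  sort_pasi(alleles)
}

#' @rdname parse_genotype_notation
#' @export
format_genotype_notation <- function(v) {
  stopifnot(inherits(v, "variety_genotype"))
  sprintf("%s-[%s]_%s",
          if (v$dsi_group == "G1") "1" else "2",
          pair_label(v$pasi),
          set_label(dominance_filter(v$pasi)))
}
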