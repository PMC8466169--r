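## Degradation of S-determinants (DS-D) ---------------------------------------

#' Configuration for S-determinant degradation
#'
#' Incompatibility in the olive is not strict over time: some S-determinants
#' degrade three to five days after pollination, while pollen tubes can still
#' reach ovules up to about ten days.  Degradation affects both sides of the
#' interaction (pollen-tube and pistil determinants) and, by default, also the
#' stigma-locus determinant — without which no selfing could occur at all.
#' The alleles `R2`, `R4`, `R5`, `R6` carry short-lived determinants; `R1` and
#' `R3` are stable through the receptive window, which is why `R1R3` and
#' `R1R4` varieties never self.
#'
#' @param mode `"deterministic"` (all-or-none loss of short-lived determinants
#'   at `full_day`), `"stochastic"` (per-day, per-allele loss hazards), or
#'   `"off"` (no degradation anywhere).
#' @param onset_day Day after pollen deposition at which degradation can
#'   begin (default 3).
#' @param full_day Day by which short-lived determinants are fully lost in
#'   deterministic mode (default 5).
#' @param ovule_access_day_max Last day at which a pollen tube can still
#'   fertilize an ovule (default 10).
#' @param short_lived Allele names whose determinants are degradable.
#' @param dsi_degradable Whether the stigma-locus determinant degrades on the
#'   same schedule (default `TRUE`).
#' @param rates Named per-day loss probabilities used in stochastic mode; any
#'   allele not named keeps the default (0.5/day for short-lived alleles, 0
#'   for stable ones).  Setting a small nonzero rate for `R1`/`R3` is the
#'   supported way to model the rare selfing reported for varieties such as
#'   Salonenque (`R3R5`) whose pollen retains a stable allele.
#' @return An object of class `dsd_config`.
#' @examples
#' dsd_config()             # defaults
#' dsd_config(mode = "off") # strict screens, no leakage
#' @export
dsd_config <- function(mode = c("deterministic", "stochastic", "off"),
                       onset_day = 3, full_day = 5, ovule_access_day_max = 10,
                       short_lived = SHORT_LIVED_DEFAULT,
                       dsi_degradable = TRUE,
                       rates = NULL) {
  mode <- match.arg(mode)
  stopifnot(onset_day >= 0, onset_day <= full_day,
            full_day <= ovule_access_day_max)
  short_lived <- intersect(short_lived, PASI_ALLELES)
  r <- stats::setNames(rep(0, length(PASI_ALLELES)), PASI_ALLELES)
  r[short_lived] <- 0.5
  if (!is.null(rates)) {
    bad <- setdiff(names(rates), c(PASI_ALLELES, DSI_ALLELES))
    if (length(bad)) stop("unknown allele(s) in rates: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    r[intersect(names(rates), PASI_ALLELES)] <-
      unlist(rates[intersect(names(rates), PASI_ALLELES)])
  }
  dsi_rate <- if (!is.null(rates) && "S" %in% substr(names(rates), 1, 1)) {
    max(unlist(rates[startsWith(names(rates), "S")]))
  } else 0.5
  if (any(r < 0 | r > 1) || dsi_rate < 0 || dsi_rate > 1) {
    stop("degradation rates must be probabilities in [0, 1]", call. = FALSE)
  }
  if (mode == "off") {
    short_lived <- character(0)
    dsi_degradable <- FALSE
  }
  structure(list(mode = mode, onset_day = onset_day, full_day = full_day,
                 ovule_access_day_max = ovule_access_day_max,
                 short_lived = short_lived, dsi_degradable = dsi_degradable,
                 rates = r, dsi_rate = dsi_rate),
            class = "dsd_config")
}

#' @export
print.dsd_config <- function(x, ...) {
  cat(sprintf("<dsd config> mode=%s onset=%g full=%g ovule_max=%g\n",
              x$mode, x$onset_day, x$full_day, x$ovule_access_day_max))
  cat("  short-lived:", if (length(x$short_lived))
    paste(x$short_lived, collapse = ",") else "(none)",
    " dsi_degradable:", x$dsi_degradable, "\n")
  invisible(x)
}

## TRUE iff a degradable determinant is gone by `day` (deterministic schedule).
det_degraded <- function(day, config) day >= config$full_day

#' Effective determinant set at a given day after pollination
#'
#' In deterministic mode every short-lived determinant is retained below
#' `onset_day` and lost once `day >= full_day`; stable determinants persist
#' through the whole window.  In stochastic mode each degradable determinant
#' is lost independently with its per-day hazard from `onset_day` onward (a
#' random draw; results vary between calls).
#'
#' @param determinants Character vector of R-allele determinants (a pollen
#'   class or an ovary pair).
#' @param day Whole days since pollen deposition (non-negative).
#' @param config A [dsd_config()].
#' @return Character vector of determinants still effective at `day`
#'   (possibly empty).
#' @examples
#' effective_determinants(c("R2", "R3"), day = 6)  # "R3" persists
#' @export
effective_determinants <- function(determinants, day, config = dsd_config()) {
  if (day < 0) stop("day must be non-negative", call. = FALSE)
  stopifnot(inherits(config, "dsd_config"))
  if (config$mode == "off" || day < config$onset_day) return(determinants)
  degradable <- intersect(determinants, config$short_lived)
  if (config$mode == "deterministic") {
    if (det_degraded(day, config)) setdiff(determinants, degradable)
    else determinants
  } else {
    exposed <- pmax(0, floor(day) - config$onset_day + 1)
    gone <- vapply(determinants, function(a) {
      a %in% config$short_lived &&
        stats::runif(1) < 1 - (1 - config$rates[[a]])^exposed
    }, logical(1))
    determinants[!gone]
  }
}

## Deterministic earliest day at which host pistil accepts donor pollen,
## NA if never within the ovule-access window.  Shared logic for selfing and
## late crosses; uses the deterministic schedule regardless of config$mode
## (stochastic leakage is sampled in the orchard simulator instead).
earliest_pass_day <- function(host, donor, config) {
  static_dsi <- dsi_screen(host, donor)
  pollen <- dominance_filter(donor$pasi)
  ovary <- host$pasi
  if (static_dsi && length(intersect(pollen, ovary)) == 0L) return(0)
  if (config$mode == "off") return(NA_real_)
  for (day in 0:config$ovule_access_day_max) {
    dsi_ok <- static_dsi || (config$dsi_degradable && det_degraded(day, config))
    if (!dsi_ok) next
    p_eff <- if (det_degraded(day, config)) setdiff(pollen, config$short_lived) else pollen
    o_eff <- if (det_degraded(day, config)) setdiff(ovary, config$short_lived) else ovary
    if (length(intersect(p_eff, o_eff)) == 0L) return(day)
  }
  NA_real_
}

#' Can a variety set fruit by selfing, and from which day?
#'
#' Self pollen always fails both static screens (same group; pollen
#' determinants are a subset of the ovary pair).  Selfing becomes possible
#' only if (i) the stigma-locus determinant degrades, and (ii) by some day
#' within the ovule-access window the effective pollen and ovary determinant
#' sets no longer intersect.  Under the default configuration this happens
#' exactly when the variety's expressed pollen class contains no stable
#' allele: e.g. `R2R3` (pollen `{R2}`) selfs from `full_day`, while `R1R3`
#' and `R1R4` never do.
#'
#' @param v A [variety_genotype()].
#' @param config A [dsd_config()]; the deterministic schedule is used.
#' @return List with `possible` (logical) and `earliest_day` (`NA` when
#'   impossible).
#' @examples
#' selfing_possible(variety_genotype("Tanche", "G2", "R2R3"))
#' selfing_possible(variety_genotype("Picholine", "G1", "R1R3"))
#' @export
selfing_possible <- function(v, config = dsd_config()) {
  stopifnot(inherits(v, "variety_genotype"))
  day <- earliest_pass_day(v, v, config)
  list(possible = !is.na(day), earliest_day = day)
}

#' Can an incompletely compatible cross still set fruit late?
#'
#' A `"1-1"` cross succeeds immediately (day 0).  A `"1-0"` cross can succeed
#' once the shared ovary-locus determinants have degraded on both sides; a
#' `"0-0"` cross additionally requires the stigma-locus determinant to
#' degrade.  Returns the earliest day under the deterministic schedule.
#'
#' @inheritParams dsi_screen
#' @param config A [dsd_config()].
#' @return List with `possible`, `earliest_day`, and the static `code`.
#' @examples
#' tanche <- variety_genotype("Tanche", "G2", "R2R3")
#' bouteillan <- variety_genotype("Bouteillan", "G2", "R2R4")
#' late_cross_possible(tanche, bouteillan)  # late fruit once R2 degrades
#' @export
late_cross_possible <- function(host, donor, config = dsd_config()) {
  code <- verdict_code(host, donor)
  day <- earliest_pass_day(host, donor, config)
  list(possible = !is.na(day), earliest_day = day, code = code)
}
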