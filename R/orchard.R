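## Orchard pollination simulator ----------------------------------------------

#' Describe an orchard for season simulation
#'
#' @param varieties Data frame with one row per planted variety: columns
#'   `name`, `dsi_group`, `pasi_pair`, `proportion` (planting proportions,
#'   normalized internally), `bloom_start`, `bloom_end` (whole days within the
#'   season).
#' @param flowers_per_variety Number of flowers simulated per variety.
#' @param pollen_per_flower_per_day Mean of the Poisson number of pollen
#'   grains landing on a receptive flower per day.
#' @param season_length Length of the season in days (default: last bloom
#'   day plus the ovule-access window).
#' @param receptive_days Days a flower keeps receiving pollen after opening
#'   (default 6; olive flowers stay receptive about 5-6 days).
#' @return An object of class `orchard_config`.
#' @examples
#' orch <- orchard_config(data.frame(
#'   name = c("Tanche", "Cayon"), dsi_group = c("G2", "G1"),
#'   pasi_pair = c("R2R3", "R1R4"), proportion = c(0.5, 0.5),
#'   bloom_start = c(1, 1), bloom_end = c(10, 10)))
#' @export
orchard_config <- function(varieties, flowers_per_variety = 100,
                           pollen_per_flower_per_day = 5,
                           season_length = NULL, receptive_days = 6) {
  need <- c("name", "dsi_group", "pasi_pair", "proportion",
            "bloom_start", "bloom_end")
  if (!is.data.frame(varieties) || !all(need %in% names(varieties))) {
    stop("varieties must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(varieties$name)) {
    stop("duplicate variety names in orchard", call. = FALSE)
  }
  if (any(varieties$proportion < 0) || sum(varieties$proportion) <= 0) {
    stop("planting proportions must be non-negative with a positive sum",
         call. = FALSE)
  }
  varieties$proportion <- varieties$proportion / sum(varieties$proportion)
  if (any(varieties$bloom_end < varieties$bloom_start)) {
    stop("bloom_end before bloom_start", call. = FALSE)
  }
  if (is.null(season_length)) season_length <- max(varieties$bloom_end) + 10
  if (any(varieties$bloom_start < 1) || any(varieties$bloom_end > season_length)) {
    stop("bloom windows must lie within 1..season_length", call. = FALSE)
  }
  genotypes <- lapply(seq_len(nrow(varieties)), function(i) {
    variety_genotype(varieties$name[i], varieties$dsi_group[i],
                     varieties$pasi_pair[i])
  })
  structure(list(varieties = varieties, genotypes = genotypes,
                 flowers_per_variety = flowers_per_variety,
                 pollen_per_flower_per_day = pollen_per_flower_per_day,
                 season_length = season_length,
                 receptive_days = receptive_days),
            class = "orchard_config")
}

#' @export
print.orchard_config <- function(x, ...) {
  cat(sprintf("<orchard> %d varieties, season %d days, %d flowers/variety\n",
              nrow(x$varieties), x$season_length, x$flowers_per_variety))
  print(x$varieties, row.names = FALSE)
  invisible(x)
}

cloud_weights <- function(orchard, day) {
  v <- orchard$varieties
  w <- v$proportion * (v$bloom_start <= day & day <= v$bloom_end)
  if (sum(w) > 0) w / sum(w) else w
}

#' Composition of the pollen cloud on a given day
#'
#' Weights are proportional to planting proportion for every variety in bloom
#' on `day`, normalized, then aggregated by pollen class (stigma determinant
#' plus expressed ovary-locus determinants).  An empty named vector is
#' returned when nothing blooms.
#'
#' @param orchard An [orchard_config()].
#' @param day Day within the season.
#' @return Named numeric vector of pollen-class weights, names like
#'   `"S2_R1R3"`.
#' @export
pollen_cloud <- function(orchard, day) {
  stopifnot(inherits(orchard, "orchard_config"))
  if (day < 1 || day > orchard$season_length) {
    stop("day outside the season", call. = FALSE)
  }
  w <- cloud_weights(orchard, day)
  keep <- w > 0
  if (!any(keep)) return(stats::setNames(numeric(0), character(0)))
  labs <- vapply(orchard$genotypes[keep], function(g) {
    p <- pollen_phenotype(g)
    paste0(p$dsi, "_", set_label(p$pasi))
  }, character(1))
  out <- tapply(w[keep], labs, sum)
  stats::setNames(as.numeric(out), names(out))
}

## Removal day of one determinant copy under a config: deterministic mode uses
## the step schedule; stochastic mode draws a geometric day-of-loss from the
## per-day hazard, starting at onset_day.
removal_day <- function(rate, config, stochastic) {
  if (!stochastic) return(if (rate > 0) config$full_day else Inf)
  if (rate <= 0) return(Inf)
  config$onset_day + stats::rgeom(1L, rate)
}

## Earliest day (since deposition) a single grain passes both screens, with
## per-encounter stochastic degradation draws.  NA when impossible within the
## ovule-access window.
sample_pass_day <- function(host, donor, config) {
  if (config$mode != "stochastic") return(earliest_pass_day(host, donor, config))
  pollen <- dominance_filter(donor$pasi)
  ovary <- host$pasi
  dsi_day <- if (dsi_screen(host, donor)) 0 else if (config$dsi_degradable) {
    removal_day(config$dsi_rate, config, TRUE)
  } else Inf
  shared <- intersect(pollen, ovary)
  pasi_day <- 0
  for (a in shared) {
    rate <- config$rates[[a]]
    resolved <- min(removal_day(rate, config, TRUE),
                    removal_day(rate, config, TRUE))
    pasi_day <- max(pasi_day, resolved)
  }
  d <- max(dsi_day, pasi_day)
  if (d <= config$ovule_access_day_max) d else NA_real_
}

#' Simulate one pollination season in an orchard
#'
#' Every flower opens on a uniformly drawn day of its variety's bloom window
#' and receives a Poisson number of grains per receptive day, drawn from the
#' pollen cloud of that day.  Each grain fertilizes at deposition day plus the
#' earliest day its effective determinants pass both screens (immediately for
#' a fully compatible grain, after determinant degradation otherwise, never if
#' a stable shared determinant persists); one ovule per flower, and the first
#' grain to fertilize wins.  Fathers are recorded as simulator ground truth.
#'
#' @param orchard An [orchard_config()].
#' @param dsd A [dsd_config()]; mode `"off"` makes the screens strict,
#'   `"stochastic"` draws per-grain degradation.
#' @param seed Integer seed; identical seeds give identical reports.
#' @return An object of class `fruit_set_report`: list with `per_variety`
#'   (data frame: `name`, `flowers`, `fruits`, `fruit_set`, `selfed`,
#'   `selfing_rate`, `dsd_events`, `mean_set_day`) and `fathers` (data frame:
#'   `host`, `father`, `count`).
#' @examples
#' orch <- orchard_config(data.frame(
#'   name = c("Tanche", "Cayon"), dsi_group = c("G2", "G1"),
#'   pasi_pair = c("R2R3", "R1R4"), proportion = c(0.5, 0.5),
#'   bloom_start = c(1, 1), bloom_end = c(10, 10)),
#'   flowers_per_variety = 20)
#' simulate_season(orch, dsd_config(mode = "off"), seed = 1)
#' @export
simulate_season <- function(orchard, dsd = dsd_config(), seed = NULL) {
  stopifnot(inherits(orchard, "orchard_config"), inherits(dsd, "dsd_config"))
  if (orchard$pollen_per_flower_per_day <= 0) {
    stop("pollen_per_flower_per_day must be positive", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(orchard$varieties)
  gts <- orchard$genotypes
  ## memoized pair outcomes (deterministic schedule)
  ages <- matrix(NA_real_, n, n)
  codes <- matrix("", n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    codes[i, j] <- verdict_code(gts[[i]], gts[[j]])
    ages[i, j] <- earliest_pass_day(gts[[i]], gts[[j]], dsd)
  }
  per <- data.frame(name = orchard$varieties$name,
                    flowers = orchard$flowers_per_variety, fruits = 0L,
                    fruit_set = 0, selfed = 0L, selfing_rate = NA_real_,
                    dsd_events = 0L, mean_set_day = NA_real_)
  fathers <- matrix(0L, n, n, dimnames = list(orchard$varieties$name,
                                              orchard$varieties$name))
  set_days <- vector("list", n)
  for (i in seq_len(n)) {
    vr <- orchard$varieties[i, ]
    opens <- sample(seq(vr$bloom_start, vr$bloom_end),
                    orchard$flowers_per_variety, replace = TRUE)
    for (f in seq_len(orchard$flowers_per_variety)) {
      t0 <- opens[f]
      last <- min(orchard$season_length, t0 + orchard$receptive_days)
      best_time <- Inf; best_donor <- NA_integer_
      for (t in t0:last) {
        w <- cloud_weights(orchard, t)
        if (sum(w) == 0) next
        k <- stats::rpois(1L, orchard$pollen_per_flower_per_day)
        if (k == 0L) next
        donors <- sample.int(n, k, replace = TRUE, prob = w)
        for (j in donors) {
          age <- if (dsd$mode == "stochastic") {
            sample_pass_day(gts[[i]], gts[[j]], dsd)
          } else ages[i, j]
          if (is.na(age)) next
          ft <- t + age
          if (ft < best_time) { best_time <- ft; best_donor <- j }
        }
      }
      if (is.finite(best_time)) {
        per$fruits[i] <- per$fruits[i] + 1L
        fathers[i, best_donor] <- fathers[i, best_donor] + 1L
        if (best_donor == i) per$selfed[i] <- per$selfed[i] + 1L
        if (codes[i, best_donor] != "1-1") per$dsd_events[i] <- per$dsd_events[i] + 1L
        set_days[[i]] <- c(set_days[[i]], best_time)
      }
    }
    per$fruit_set[i] <- per$fruits[i] / per$flowers[i]
    per$selfing_rate[i] <- if (per$fruits[i] > 0) per$selfed[i] / per$fruits[i] else NA_real_
    per$mean_set_day[i] <- if (per$fruits[i] > 0) mean(set_days[[i]]) else NA_real_
  }
  idx <- which(fathers > 0, arr.ind = TRUE)
  fa <- data.frame(host = rownames(fathers)[idx[, 1]],
                   father = colnames(fathers)[idx[, 2]],
                   count = fathers[idx])
  fa <- fa[order(fa$host, -fa$count, fa$father), , drop = FALSE]
  rownames(fa) <- NULL
  structure(list(per_variety = per, fathers = fa), class = "fruit_set_report")
}

#' @export
print.fruit_set_report <- function(x, ...) {
  cat("<fruit set report>\n")
  print(x$per_variety, row.names = FALSE, digits = 3)
  invisible(x)
}

## Paternity diagnostics ------------------------------------------------------

#' Diagnose a paradoxical paternity-test result
#'
#' Paternity tests on embryos sometimes identify a father that is
#' incompatible with the host variety.  Under the two-screen model with
#' determinant degradation this is informative rather than erroneous: when
#' exactly one of the two screens accepts the pair, the embryo can only have
#' arisen through degradation of the blocking determinant (a late
#' fertilization), which in turn means compatible pollen was lacking in the
#' orchard.
#'
#' @param host Host (seed parent) [variety_genotype()].
#' @param father Assigned father [variety_genotype()] (the assignment itself,
#'   e.g. from molecular markers, is taken as given).
#' @return An object of class `paternity_diagnosis`: list with `dsi_verdict`
#'   and `pasi_verdict` (`"Accept"`/`"Reject"`), `dsd_flag` (`TRUE` when
#'   exactly one screen accepts), and `recommendation`.
#' @examples
#' diagnose_paternity(ref_variety("Aglandau"), ref_variety("Frantoio"))
#' @export
diagnose_paternity <- function(host, father) {
  d <- dsi_screen(host, father)
  p <- pasi_screen(host, father)
  flag <- xor(d, p)
  structure(list(
    host = host$name, father = father$name,
    dsi_verdict = if (d) "Accept" else "Reject",
    pasi_verdict = if (p) "Accept" else "Reject",
    dsd_flag = flag,
    recommendation = if (flag) {
      "compatible pollen insufficient - plant suitable pollinizers"
    } else if (d && p) {
      "fully compatible father - pollination functioning"
    } else {
      "father rejected by both screens - verify the paternity assignment"
    }), class = "paternity_diagnosis")
}

#' @export
print.paternity_diagnosis <- function(x, ...) {
  cat(sprintf("<paternity> host %s, father %s\n", x$host, x$father))
  cat(sprintf("  stigma screen: %s | ovary screen: %s | degradation involved: %s\n",
              x$dsi_verdict, x$pasi_verdict, if (x$dsd_flag) "Yes" else "No"))
  cat(" ", x$recommendation, "\n")
  invisible(x)
}

#' Published paradoxical paternity diagnoses (reference set)
#'
#' Host/father pairs from olive paternity studies with the published
#' stigma-screen verdict, ovary-screen verdict, and whether determinant
#' degradation must have operated.  Rows flagged `anomaly` are internally
#' inconsistent in the published record (a printed verdict that contradicts
#' the stated genotypes or group memberships); the model's computed verdicts
#' are the coherent reading.
#'
#' @return Data frame with columns `host`, `father`, `dsi_printed`,
#'   `pasi_printed`, `dsd_printed`, `anomaly`, `note`.
#' @examples
#' pr <- paternity_reference()
#' table(pr$dsd_printed, pr$anomaly)
#' @export
paternity_reference <- function() {
  f <- system.file("extdata", "paternity_reference.csv", package = "oliveSI")
  utils::read.csv(f, stringsAsFactors = FALSE)
}
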