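## Synthetic panel / cross-table generator ------------------------------------

#' Generate a synthetic variety panel and diallel cross-record table
#'
#' Draws a panel of varieties with genotypes from a chosen distribution and
#' derives a diallel cross table (every ordered host x donor pair including
#' selfing rows) from the predicted verdicts: `"1-1"` crosses give `fruit`,
#' everything else `no_fruit`.  With `dsd_noise`, crosses that determinant
#' degradation can rescue report `fruit` with probability `noise_rate`,
#' mimicking the paradoxical fruit reports of field studies (bagged selfing,
#' late crosses between nominally incompatible pairs).
#'
#' @param n_varieties Number of varieties to draw (ignored for
#'   `source = "explicit"`).
#' @param source Genotype distribution: `"frequencies"` samples pairs and
#'   groups from [reference_panel_frequencies()]; `"uniform"` samples
#'   uniformly over the 40 admissible (group, pair) genotypes; `"explicit"`
#'   uses `varieties` as given.
#' @param varieties For `"explicit"`: a panel data frame (`name`,
#'   `dsi_group`, `pasi_pair`) or a character vector of
#'   [reference_varieties()] names.
#' @param record_completeness Fraction of the diallel rows to keep (sampled
#'   without replacement; 1 = complete table, 0 = empty).
#' @param dsd_noise Inject degradation-driven false `fruit` rows.
#' @param noise_rate Probability that a rescuable incompatible cross reports
#'   fruit when `dsd_noise` is on.
#' @param dsd [dsd_config()] used to decide which crosses are rescuable.
#' @param seed Integer seed for reproducibility.
#' @param dir If given, write `panel.csv` and `records.csv` there.
#' @return List with elements `panel` and `records` (data frames); when `dir`
#'   is given, also `panel_file` and `records_file`.
#' @examples
#' fx <- generate_fixture(4, source = "uniform", seed = 1)
#' head(fx$records)
#' @export
generate_fixture <- function(n_varieties = 4,
                             source = c("frequencies", "uniform", "explicit"),
                             varieties = NULL,
                             record_completeness = 1,
                             dsd_noise = FALSE, noise_rate = 0.5,
                             dsd = dsd_config(), seed = NULL, dir = NULL) {
  source <- match.arg(source)
  stopifnot(record_completeness >= 0, record_completeness <= 1)
  if (!is.null(seed)) set.seed(seed)

  panel <- switch(source,
    explicit = {
      if (is.character(varieties)) {
        ref <- reference_varieties()
        i <- match(varieties, ref$name)
        if (anyNA(i)) stop("unknown reference variety name(s): ",
                           paste(varieties[is.na(i)], collapse = ", "),
                           call. = FALSE)
        ref[i, c("name", "dsi_group", "pasi_pair")]
      } else if (is.data.frame(varieties)) {
        varieties[, c("name", "dsi_group", "pasi_pair")]
      } else {
        stop("for source = \"explicit\", supply `varieties`", call. = FALSE)
      }
    },
    frequencies = {
      freq <- reference_panel_frequencies()
      i <- sample.int(nrow(freq), n_varieties, replace = TRUE,
                      prob = freq$weight)
      data.frame(name = sprintf("V%02d", seq_len(n_varieties)),
                 dsi_group = freq$dsi_group[i], pasi_pair = freq$pasi_pair[i],
                 stringsAsFactors = FALSE)
    },
    uniform = {
      females <- enumerate_female_genotypes()
      gi <- sample(c("G1", "G2"), n_varieties, replace = TRUE)
      pi <- sample(names(females), n_varieties, replace = TRUE)
      data.frame(name = sprintf("V%02d", seq_len(n_varieties)),
                 dsi_group = gi, pasi_pair = pi, stringsAsFactors = FALSE)
    })
  rownames(panel) <- NULL

  gts <- lapply(seq_len(nrow(panel)), function(i) {
    variety_genotype(panel$name[i], panel$dsi_group[i], panel$pasi_pair[i])
  })
  ## subsample the diallel before evaluating verdicts, so large panels with
  ## low completeness never materialize the full n^2 grid
  n <- length(gts)
  total <- n * n
  keep <- if (record_completeness >= 1) seq_len(total) else
    sort(sample.int(total, round(record_completeness * total)))
  h <- ((keep - 1L) %% n) + 1L
  d <- ((keep - 1L) %/% n) + 1L
  records <- data.frame(host = panel$name[h], donor = panel$name[d],
                        outcome = rep(NA_character_, length(keep)),
                        method = rep("fruit_test", length(keep)),
                        stringsAsFactors = FALSE)
  for (k in seq_along(keep)) {
    host <- gts[[h[k]]]; donor <- gts[[d[k]]]
    fruit <- verdict_code(host, donor) == "1-1"
    if (!fruit && dsd_noise &&
        late_cross_possible(host, donor, dsd)$possible &&
        stats::runif(1) < noise_rate) {
      fruit <- TRUE
    }
    records$outcome[k] <- if (fruit) "fruit" else "no_fruit"
  }

  out <- list(panel = panel, records = records)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$panel_file <- write_panel(panel, file.path(dir, "panel.csv"))
    out$records_file <- write_records(records, file.path(dir, "records.csv"))
  }
  out
}
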