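## Delimited-text readers and writers -----------------------------------------

## All tables are plain comma-separated text with a one-line header; there is
## no standard exchange format for self-incompatibility cross tables.

io_error <- function(file, line, msg) {
  stop(sprintf("%s, line %d: %s", file, line, msg), call. = FALSE)
}

#' Read and write variety panel files
#'
#' A panel file is comma-separated text with header columns `name`,
#' `dsi_group` (`G1`|`G2`), `pasi_pair` (e.g. `R2R3`); further columns (e.g.
#' `source`, `notation`) are preserved.  Genotypes are validated on read and
#' malformed rows are reported with their line number.
#'
#' @param file Path to a panel file.
#' @param panel Data frame as returned by `read_panel()`.
#' @return `read_panel()` returns the panel data frame (with `pasi_pair`
#'   canonicalized); `write_panel()` returns `file` invisibly.
#' @examples
#' f <- system.file("extdata", "variety_panel.csv", package = "oliveSI")
#' head(read_panel(f))
#' @export
read_panel <- function(file) {
  panel <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("name", "dsi_group", "pasi_pair")
  if (!all(need %in% names(panel))) {
    stop(file, ": panel needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(panel))) {
    line <- i + 1L  # header is line 1
    v <- tryCatch(
      variety_genotype(panel$name[i], panel$dsi_group[i], panel$pasi_pair[i]),
      error = function(e) io_error(file, line, conditionMessage(e)))
    panel$pasi_pair[i] <- pair_label(v$pasi)
    if ("notation" %in% names(panel) && nzchar(panel$notation[i])) {
      parsed <- tryCatch(
        parse_genotype_notation(panel$notation[i], name = panel$name[i]),
        error = function(e) io_error(file, line, conditionMessage(e)))
      if (!same_genotype(parsed, v)) {
        io_error(file, line, sprintf(
          "notation '%s' disagrees with columns (%s %s)",
          panel$notation[i], panel$dsi_group[i], panel$pasi_pair[i]))
      }
    }
    dup <- which(panel$name[seq_len(i - 1L)] == panel$name[i])
    if (length(dup)) {
      io_error(file, line, sprintf("duplicate variety name '%s' (first on line %d)",
                                   panel$name[i], dup[1] + 1L))
    }
  }
  panel
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, file) {
  utils::write.csv(panel, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read and write cross-record files
#'
#' A cross-record file has one observation per line: columns `host`, `donor`,
#' `outcome` (`fruit`, `no_fruit`, `pollen_germinated`, `no_germination`,
#' `unknown`), optional `method` (`fruit_test`|`pollen_test`), `n_fruit`,
#' `n_flowers`.  Rows with `host == donor` are selfing observations.
#'
#' @param file Path to a records file.
#' @param records Data frame of records.
#' @param panel Optional panel data frame; when given, every variety name in
#'   the records must appear in it.
#' @return `read_records()` returns the records data frame; `write_records()`
#'   returns `file` invisibly.
#' @export
read_records <- function(file, panel = NULL) {
  records <- utils::read.csv(file, stringsAsFactors = FALSE)
  records <- tryCatch(validate_records(records),
                      error = function(e) stop(file, ": ",
                                               conditionMessage(e), call. = FALSE))
  if (!is.null(panel)) {
    for (i in seq_len(nrow(records))) {
      unknown <- setdiff(c(records$host[i], records$donor[i]), panel$name)
      if (length(unknown)) {
        io_error(file, i + 1L,
                 paste0("unknown variety name(s): ",
                        paste(unknown, collapse = ", ")))
      }
    }
  }
  records
}

#' @rdname read_records
#' @export
write_records <- function(records, file) {
  utils::write.csv(records, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read an orchard configuration file
#'
#' Orchard configurations are YAML: scalar keys `flowers_per_variety`,
#' `pollen_per_flower_per_day`, `season_length`, `receptive_days` (all
#' optional) and a `varieties` list whose entries carry `name`, `dsi_group`,
#' `pasi_pair`, `proportion`, `bloom_start`, `bloom_end`.
#'
#' @param file Path to a YAML orchard file.
#' @return An [orchard_config()].
#' @examples
#' f <- system.file("extdata", "orchard_example.yaml", package = "oliveSI")
#' read_orchard(f)
#' @export
read_orchard <- function(file) {
  y <- yaml::read_yaml(file)
  if (is.null(y$varieties) || !length(y$varieties)) {
    stop(file, ": orchard file must list at least one variety", call. = FALSE)
  }
  need <- c("name", "dsi_group", "pasi_pair", "proportion",
            "bloom_start", "bloom_end")
  rows <- lapply(seq_along(y$varieties), function(i) {
    v <- y$varieties[[i]]
    miss <- setdiff(need, names(v))
    if (length(miss)) {
      stop(file, ": variety entry ", i, " is missing field(s) ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    data.frame(name = v$name, dsi_group = v$dsi_group,
               pasi_pair = v$pasi_pair, proportion = v$proportion,
               bloom_start = v$bloom_start, bloom_end = v$bloom_end,
               stringsAsFactors = FALSE)
  })
  args <- list(varieties = do.call(rbind, rows))
  for (k in c("flowers_per_variety", "pollen_per_flower_per_day",
              "season_length", "receptive_days")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  do.call(orchard_config, args)
}
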