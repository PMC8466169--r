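## Genotype inference from cross-outcome tables -------------------------------

OUTCOMES <- c("fruit", "no_fruit", "pollen_germinated", "no_germination",
              "unknown")

validate_records <- function(records) {
  need <- c("host", "donor", "outcome")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    stop("records must be a data frame with columns host, donor, outcome",
         call. = FALSE)
  }
  bad <- setdiff(records$outcome, OUTCOMES)
  if (length(bad)) {
    stop("unknown outcome(s): ", paste(unique(bad), collapse = ", "),
         "; expected ", paste(OUTCOMES, collapse = ", "), call. = FALSE)
  }
  if (!"method" %in% names(records)) {
    records$method <- ifelse(
      records$outcome %in% c("pollen_germinated", "no_germination"),
      "pollen_test", "fruit_test")
  }
  records
}

## Effective outcome after applying the fruit-count threshold: crossing two
## incompatible varieties may yield a few fruits (selfing, contamination), so
## a "fruit" row with fewer than `fruit_threshold` fruits is read as no_fruit.
effective_outcome <- function(records, fruit_threshold) {
  out <- records$outcome
  if (fruit_threshold > 1 && "n_fruit" %in% names(records)) {
    demote <- out == "fruit" & !is.na(records$n_fruit) &
      records$n_fruit < fruit_threshold
    out[demote] <- "no_fruit"
  }
  out
}

as_assignment_list <- function(assignment) {
  if (is.data.frame(assignment)) {
    gl <- lapply(seq_len(nrow(assignment)), function(i) {
      variety_genotype(assignment$name[i], assignment$dsi_group[i],
                       assignment$pasi_pair[i])
    })
    names(gl) <- assignment$name
    gl
  } else if (is.list(assignment) &&
             all(vapply(assignment, inherits, logical(1), "variety_genotype"))) {
    stats::setNames(assignment,
                    vapply(assignment, function(v) v$name, character(1)))
  } else {
    stop("assignment must be a data frame (name, dsi_group, pasi_pair) or a ",
         "named list of variety_genotype objects", call. = FALSE)
  }
}

#' Check a genotype assignment against cross records
#'
#' A record constrains the assignment through the verdict its genotypes
#' imply: `fruit` requires a `"1-1"` verdict (or, with `allow_dsd`, a cross
#' that degradation can rescue); `no_fruit` forbids `"1-1"`;
#' `pollen_germinated` requires the stigma screen to pass and
#' `no_germination` requires it to fail (pollen tests probe only the first
#' screen).  Selfing observations are rows with `host == donor`.
#'
#' @param records Data frame with columns `host`, `donor`, `outcome` (one of
#'   `fruit`, `no_fruit`, `pollen_germinated`, `no_germination`, `unknown`),
#'   optional `method`, `n_fruit`, `n_flowers`.
#' @param assignment Data frame with columns `name`, `dsi_group`, `pasi_pair`
#'   covering every variety in the records (or a named list of
#'   [variety_genotype()] objects).
#' @param allow_dsd Accept `fruit` from statically incompatible pairs when
#'   determinant degradation can explain it.
#' @param dsd [dsd_config()] used when `allow_dsd = TRUE`.
#' @param fruit_threshold Minimum `n_fruit` for a `fruit` row to count as
#'   fruit (rows below it are read as `no_fruit`; default 1 = any fruit
#'   counts).
#' @return Data frame of violated records (zero rows when consistent) with a
#'   `reason` column.
#' @examples
#' recs <- data.frame(host = "Tanche", donor = "Cayon", outcome = "fruit")
#' asg <- data.frame(name = c("Tanche", "Cayon"), dsi_group = c("G2", "G1"),
#'                   pasi_pair = c("R2R3", "R1R4"))
#' check_consistency(recs, asg)  # no violations
#' @export
check_consistency <- function(records, assignment, allow_dsd = FALSE,
                              dsd = dsd_config(), fruit_threshold = 1) {
  records <- validate_records(records)
  gl <- as_assignment_list(assignment)
  missing <- setdiff(unique(c(records$host, records$donor)), names(gl))
  if (length(missing)) {
    stop("unassigned variety name(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- effective_outcome(records, fruit_threshold)
  reasons <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    host <- gl[[records$host[i]]]
    donor <- gl[[records$donor[i]]]
    code <- verdict_code(host, donor)
    reasons[i] <- switch(
      out[i],
      fruit = {
        ok <- code == "1-1" ||
          (allow_dsd && late_cross_possible(host, donor, dsd)$possible)
        if (ok) "" else sprintf(
          "fruit reported but predicted verdict is %s%s", code,
          if (allow_dsd) " and degradation cannot rescue it" else "")
      },
      no_fruit = if (code != "1-1") "" else
        "no fruit reported but the cross is predicted fully compatible (1-1)",
      pollen_germinated = if (dsi_screen(host, donor)) "" else
        "germination reported but the stigma screen is predicted to reject",
      no_germination = if (!dsi_screen(host, donor)) "" else
        "no germination reported but the stigma screen is predicted to pass",
      unknown = "")
  }
  bad <- which(reasons != "")
  data.frame(record = bad,
             host = records$host[bad], donor = records$donor[bad],
             outcome = records$outcome[bad], reason = reasons[bad],
             stringsAsFactors = FALSE)
}

## Candidate genotype tables --------------------------------------------------

dssm_candidates <- function(max_alleles) {
  stopifnot(max_alleles >= 1, max_alleles <= 6)
  alleles <- PASI_ALLELES[seq_len(max_alleles)]
  pairs <- list()
  for (i in seq_along(alleles)) for (j in i:length(alleles)) {
    p <- c(alleles[i], alleles[j])
    if (!identical(p, c("R6", "R6"))) pairs[[length(pairs) + 1L]] <- p
  }
  cand <- expand.grid(pair = seq_along(pairs), group = c("G1", "G2"),
                      stringsAsFactors = FALSE)
  list(pairs = pairs,
       group = cand$group,
       pair_idx = cand$pair,
       labels = paste0(ifelse(cand$group == "G1", "1-", "2-"),
                       vapply(pairs[cand$pair], pair_label, character(1))))
}

.cand_cache <- new.env(parent = emptyenv())

## Pairwise verdict codes (1 = 0-0, 2 = 1-0, 3 = 1-1) and degradation-rescue
## indicators between all candidate genotypes, as lookup matrices.  Cached:
## the tables depend only on max_alleles and the degradation schedule.
candidate_tables <- function(cand, dsd) {
  key <- paste(length(cand$group), dsd$mode, dsd$onset_day, dsd$full_day,
               dsd$ovule_access_day_max, paste(dsd$short_lived, collapse = ""),
               dsd$dsi_degradable, sep = "|")
  hit <- .cand_cache[[key]]
  if (!is.null(hit)) return(hit)
  res <- candidate_tables_impl(cand, dsd)
  assign(key, res, envir = .cand_cache)
  res
}

candidate_tables_impl <- function(cand, dsd) {
  nc <- length(cand$group)
  gts <- lapply(seq_len(nc), function(k) {
    variety_genotype("cand", cand$group[k], cand$pairs[[cand$pair_idx[k]]])
  })
  code <- matrix(1L, nc, nc)
  dsd_ok <- matrix(FALSE, nc, nc)
  for (a in seq_len(nc)) for (b in seq_len(nc)) {
    cc <- verdict_code(gts[[a]], gts[[b]])
    code[a, b] <- match(cc, c("0-0", "1-0", "1-1"))
    dsd_ok[a, b] <- !is.na(earliest_pass_day(gts[[a]], gts[[b]], dsd))
  }
  list(genotypes = gts, code = code, dsd_ok = dsd_ok)
}

record_ok <- function(outcome, code, dsd_ok, allow_dsd) {
  switch(outcome,
         fruit = code == 3L || (allow_dsd && dsd_ok),
         no_fruit = code != 3L,
         pollen_germinated = code >= 2L,
         no_germination = code == 1L,
         unknown = TRUE)
}

#' Enumerate genotype assignments consistent with cross records
#'
#' Exhaustive depth-first search with pruning over candidate genotypes for
#' each variety.  Under the default two-screen model a candidate is a
#' (group, allele-pair) combination over the first `max_alleles` ovary-locus
#' alleles; under `model = "one_locus"` a candidate is simply one of
#' `max_alleles` incompatibility classes with compatibility iff the classes
#' differ (the classical single-locus reading, useful for showing that no
#' number of such classes can explain intransitive compatibility patterns).
#' Results are deduplicated up to relabeling of the codominant rank class
#' (`R1`/`R3`/`R5`), whose members the records cannot distinguish.
#'
#' @inheritParams check_consistency
#' @param max_alleles Number of ovary-locus alleles (or classes) available to
#'   the search, 1-6.
#' @param model `"dssm"` (two successive screens, the default) or
#'   `"one_locus"` (plain incompatibility classes).
#' @param max_varieties Guard on the exhaustive search; more distinct
#'   varieties than this raises an error suggesting [check_consistency()]
#'   with a candidate assignment instead.
#' @param limit Stop after this many consistent assignments (before
#'   deduplication; `Inf` = all).
#' @param canonical Deduplicate up to allele relabeling (default `TRUE`).
#' @param max_states Guard on the number of partial assignments held during
#'   full enumeration; weakly constrained record sets (mostly `no_fruit`
#'   rows) can have astronomically many consistent assignments, and the
#'   search stops with an error rather than exhausting memory.
#' @return List of assignments, each a data frame with columns `name`,
#'   `dsi_group`, `pasi_pair` (or `name`, `class` for `"one_locus"`);
#'   empty list when unsatisfiable.
#' @examples
#' recs <- data.frame(
#'   host = c("A", "B"), donor = c("B", "A"),
#'   outcome = c("no_fruit", "no_fruit"))
#' length(consistent_assignments(recs, max_alleles = 2))
#' @export
consistent_assignments <- function(records, max_alleles = 6,
                                   max_varieties = 8,
                                   model = c("dssm", "one_locus"),
                                   allow_dsd = FALSE, dsd = dsd_config(),
                                   fruit_threshold = 1,
                                   limit = Inf, canonical = TRUE,
                                   max_states = 5e6) {
  model <- match.arg(model)
  records <- validate_records(records)
  vars <- unique(c(records$host, records$donor))
  if (length(vars) > max_varieties) {
    stop("too many varieties (", length(vars), " > ", max_varieties,
         ") for exhaustive search; use check_consistency() with a candidate ",
         "assignment instead", call. = FALSE)
  }
  out <- effective_outcome(records, fruit_threshold)

  if (model == "one_locus") {
    nc <- max_alleles
    code <- matrix(3L, nc, nc); diag(code) <- 1L
    dsd_ok <- matrix(FALSE, nc, nc)
  } else {
    cand <- dssm_candidates(max_alleles)
    tabs <- candidate_tables(cand, dsd)
    nc <- length(cand$group)
    code <- tabs$code
    dsd_ok <- tabs$dsd_ok
  }

  ## constraints indexed by the later-assigned variety of each record
  hi <- match(records$host, vars)
  di <- match(records$donor, vars)
  later <- pmax(hi, di)
  by_pos <- split(seq_len(nrow(records)), factor(later, levels = seq_along(vars)))

  found <- if (is.finite(limit)) {
    hits <- search_dfs(length(vars), nc, by_pos, hi, di, out, code, dsd_ok,
                       allow_dsd, limit)
    if (length(hits)) matrix(unlist(hits), nrow = length(hits), byrow = TRUE)
    else matrix(integer(0), nrow = 0L, ncol = length(vars))
  } else {
    search_join(length(vars), nc, by_pos, hi, di, out, code, dsd_ok,
                allow_dsd, max_states = max_states)
  }

  if (model == "one_locus") {
    return(lapply(seq_len(nrow(found)), function(i) {
      list2DF(list(name = vars, class = found[i, ]))
    }))
  }
  if (canonical && nrow(found) > 0L) {
    perms <- codominant_permutations(max_alleles)
    maps <- lapply(perms, candidate_permutation_map, cand = cand)
    key_of <- function(m) {
      pm <- matrix(m[found], nrow = nrow(found))
      do.call(paste, c(unname(as.data.frame(pm)), sep = ","))
    }
    keys <- Reduce(pmin, lapply(maps, key_of))
    found <- found[!duplicated(keys), , drop = FALSE]
  }
  labels <- vapply(cand$pairs, pair_label, character(1))
  lapply(seq_len(nrow(found)), function(i) {
    v <- found[i, ]
    list2DF(list(name = vars,
                 dsi_group = cand$group[v],
                 pasi_pair = labels[cand$pair_idx[v]]))
  })
}

## Depth-first backtracking, stopping after `limit` consistent assignments.
search_dfs <- function(n, nc, by_pos, hi, di, out, code, dsd_ok,
                       allow_dsd, limit) {
  found <- list()
  asg <- integer(n)
  recurse <- function(pos) {
    if (length(found) >= limit) return()
    if (pos > n) {
      found[[length(found) + 1L]] <<- asg
      return()
    }
    for (candk in seq_len(nc)) {
      asg[pos] <<- candk
      ok <- TRUE
      for (r in by_pos[[pos]]) {
        a <- asg[hi[r]]; b <- asg[di[r]]
        if (!record_ok(out[r], code[a, b], dsd_ok[a, b], allow_dsd)) {
          ok <- FALSE
          break
        }
      }
      if (ok) recurse(pos + 1L)
      if (length(found) >= limit) return()
    }
  }
  recurse(1L)
  found
}

## Vectorized join enumeration of all consistent assignments (a matrix with
## one row per assignment): extend the set of consistent prefixes one variety
## at a time, filtering with matrix lookups.  Guarded against combinatorial
## blow-up on weakly constrained record sets.
search_join <- function(n, nc, by_pos, hi, di, out, code, dsd_ok,
                        allow_dsd, max_states = 5e6) {
  if (n == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  partial <- matrix(integer(0), nrow = 1L, ncol = 0L)
  for (pos in seq_len(n)) {
    if (nrow(partial) * nc > max_states) {
      stop("search space too large (over ", format(max_states, scientific = FALSE),
           " partial assignments); add records, lower max_alleles, or use a ",
           "finite `limit`", call. = FALSE)
    }
    ext <- cbind(partial[rep(seq_len(nrow(partial)), each = nc), , drop = FALSE],
                 rep(seq_len(nc), times = nrow(partial)))
    keep <- rep(TRUE, nrow(ext))
    for (r in by_pos[[pos]]) {
      a <- ext[, hi[r]]
      b <- ext[, di[r]]
      keep <- keep & switch(
        out[r],
        fruit = code[cbind(a, b)] == 3L |
          (allow_dsd & dsd_ok[cbind(a, b)]),
        no_fruit = code[cbind(a, b)] != 3L,
        pollen_germinated = code[cbind(a, b)] >= 2L,
        no_germination = code[cbind(a, b)] == 1L,
        unknown = TRUE)
    }
    partial <- ext[keep, , drop = FALSE]
    if (nrow(partial) == 0L) break
  }
  partial
}

## Permutations of the codominant rank class {R1, R3, R5} restricted to the
## first max_alleles alleles; other ranks are singletons and cannot be
## relabeled.
codominant_permutations <- function(max_alleles) {
  cls <- intersect(c("R1", "R3", "R5"), PASI_ALLELES[seq_len(max_alleles)])
  if (length(cls) < 2) return(list(stats::setNames(PASI_ALLELES, PASI_ALLELES)))
  perm_idx <- perms_of(seq_along(cls))
  lapply(perm_idx, function(p) {
    m <- stats::setNames(PASI_ALLELES, PASI_ALLELES)
    m[cls] <- cls[p]
    m
  })
}

perms_of <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in perms_of(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

## candidate id -> candidate id under an allele relabeling
candidate_permutation_map <- function(m, cand) {
  labs <- vapply(seq_along(cand$group), function(k) {
    p <- sort_pasi(unname(m[cand$pairs[[cand$pair_idx[k]]]]))
    paste0(cand$group[k], pair_label(p))
  }, character(1))
  orig <- paste0(cand$group,
                 vapply(cand$pairs[cand$pair_idx], pair_label, character(1)))
  match(labs, orig)
}

#' Minimum number of ovary-locus alleles needed to explain cross records
#'
#' Smallest `max_alleles` for which [consistent_assignments()] finds at least
#' one consistent assignment; `NA` when even six alleles cannot explain the
#' records.
#'
#' @inheritParams consistent_assignments
#' @return Integer (1-6) or `NA`.
#' @examples
#' min_alleles(data.frame(host = character(), donor = character(),
#'                        outcome = character()))  # 1
#' @export
min_alleles <- function(records, max_varieties = 8,
                        model = c("dssm", "one_locus"),
                        allow_dsd = FALSE, dsd = dsd_config(),
                        fruit_threshold = 1) {
  model <- match.arg(model)
  records <- validate_records(records)
  if (nrow(records) == 0L) return(1L)
  for (m in 1:6) {
    hit <- consistent_assignments(records, max_alleles = m,
                                  max_varieties = max_varieties, model = model,
                                  allow_dsd = allow_dsd, dsd = dsd,
                                  fruit_threshold = fruit_threshold,
                                  limit = 1, canonical = FALSE)
    if (length(hit)) return(m)
  }
  NA_integer_
}
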