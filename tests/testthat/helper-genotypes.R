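# Worked-example varieties, built fresh so tests don't depend on the
# packaged panel file.
gt <- function(name, group, pair) variety_genotype(name, group, pair)

picholine <- gt("Picholine", "G1", "R1R3")
cayon <- gt("Cayon", "G1", "R1R4")
tanche <- gt("Tanche", "G2", "R2R3")
manzanilla <- gt("Manzanilla", "G2", "R1R2")
arbequina <- gt("Arbequina", "G1", "R1R3")

# Independent oracle: recompute a cross verdict from the raw dominance ranks,
# without going through the phenotype/screen functions under test.
oracle_verdict <- function(host_group, host_pair, donor_group, donor_pair) {
  if (host_group == donor_group) return("0-0")
  rank <- c(R1 = 2, R2 = 3, R3 = 2, R4 = 1, R5 = 2, R6 = 4)
  r <- rank[donor_pair]
  pollen <- unique(donor_pair[r == max(r)])
  if (any(pollen %in% host_pair)) "1-0" else "1-1"
}

# All 40 admissible variety genotypes (2 groups x 20 pairs).
all_genotypes <- function() {
  females <- enumerate_female_genotypes()
  out <- list()
  for (g in c("G1", "G2")) for (lab in names(females)) {
    out[[paste0(g, lab)]] <- gt(paste0(g, lab), g, females[[lab]])
  }
  out
}

random_panel <- function(n, seed) {
  set.seed(seed)
  females <- enumerate_female_genotypes()
  data.frame(name = sprintf("V%02d", seq_len(n)),
             dsi_group = sample(c("G1", "G2"), n, replace = TRUE),
             pasi_pair = sample(names(females), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Complete diallel fruit/no_fruit records implied by a panel (degradation off).
diallel_records <- function(panel) {
  gts <- lapply(seq_len(nrow(panel)), function(i) {
    gt(panel$name[i], panel$dsi_group[i], panel$pasi_pair[i])
  })
  grid <- expand.grid(h = seq_along(gts), d = seq_along(gts))
  data.frame(
    host = panel$name[grid$h], donor = panel$name[grid$d],
    outcome = ifelse(
      mapply(function(h, d) verdict_code(gts[[h]], gts[[d]]),
             grid$h, grid$d) == "1-1", "fruit", "no_fruit"),
    stringsAsFactors = FALSE)
}

# Generate-and-recover check for one panel.  Where the full consistent set is
# enumerable the generating assignment must be a member (up to relabeling);
# for weakly constrained diallels whose consistent set is too large to hold,
# fall back to requiring that the generator has zero violations and that the
# search still produces a sound witness.
recover_generating <- function(panel, max_states = 5e5) {
  recs <- diallel_records(panel)
  if (nrow(check_consistency(recs, panel)) != 0) return(FALSE)
  full <- tryCatch(
    consistent_assignments(recs, max_alleles = 6, max_states = max_states),
    error = function(e) NULL)
  if (!is.null(full)) {
    length(full) > 0 &&
      any(vapply(full, matches_up_to_relabeling, logical(1), panel = panel))
  } else {
    one <- consistent_assignments(recs, max_alleles = 6, limit = 1,
                                  canonical = FALSE)
    length(one) > 0 && nrow(check_consistency(recs, one[[1]])) == 0
  }
}

# TRUE when `asg` (name, dsi_group, pasi_pair) matches `panel` up to
# relabeling within the codominant rank class {R1, R3, R5}.
matches_up_to_relabeling <- function(asg, panel) {
  asg <- asg[match(panel$name, asg$name), ]
  cls <- c("R1", "R3", "R5")
  for (p in list(cls, cls[c(1, 3, 2)], cls[c(2, 1, 3)], cls[c(2, 3, 1)],
                 cls[c(3, 1, 2)], cls[c(3, 2, 1)])) {
    m <- setNames(pasi_alleles(), pasi_alleles())
    m[cls] <- p
    relab <- vapply(strsplit(asg$pasi_pair, "(?<=[0-9])(?=R)", perl = TRUE),
                    function(a) paste(sort(m[a]), collapse = ""), character(1))
    if (all(asg$dsi_group == panel$dsi_group) && all(relab == panel$pasi_pair))
      return(TRUE)
  }
  FALSE
}
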