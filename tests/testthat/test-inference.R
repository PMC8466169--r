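triple_records <- function() {
  # Picholine/Cayon incompatible both ways; Picholine cannot pollinate
  # Tanche; Cayon is an efficient pollinizer for Tanche.
  data.frame(
    host = c("Picholine", "Cayon", "Tanche", "Tanche"),
    donor = c("Cayon", "Picholine", "Picholine", "Cayon"),
    outcome = c("no_fruit", "no_fruit", "no_fruit", "fruit"),
    stringsAsFactors = FALSE)
}

triple_assignment <- function() {
  data.frame(name = c("Picholine", "Cayon", "Tanche"),
             dsi_group = c("G1", "G1", "G2"),
             pasi_pair = c("R1R3", "R1R4", "R2R3"),
             stringsAsFactors = FALSE)
}

test_that("the published genotypes explain the worked-example records", {
  expect_equal(nrow(check_consistency(triple_records(), triple_assignment())), 0)
  # and an empty record set is vacuously consistent
  empty <- data.frame(host = character(), donor = character(),
                      outcome = character())
  expect_equal(nrow(check_consistency(empty, triple_assignment())), 0)
})

test_that("violations are reported with record index and reason", {
  recs <- triple_records()
  bad <- triple_assignment()
  bad$dsi_group <- c("G1", "G2", "G2")  # Tanche x Cayon now same-group
  v <- check_consistency(recs, bad)
  expect_gt(nrow(v), 0)
  expect_true(4 %in% v$record)
  expect_match(v$reason[v$record == 4], "fruit reported")
  # pollen-test rows constrain only the stigma screen
  germ <- data.frame(host = "Tanche", donor = "Picholine",
                     outcome = "pollen_germinated")
  expect_equal(nrow(check_consistency(germ, triple_assignment())), 0)
  nogerm <- data.frame(host = "Tanche", donor = "Cayon",
                       outcome = "no_germination")
  v2 <- check_consistency(nogerm, triple_assignment())
  expect_match(v2$reason, "stigma screen is predicted to pass")
  expect_error(check_consistency(germ, triple_assignment()[1:2, ]),
               "unassigned")
})

test_that("allow_dsd accepts degradation-rescuable fruit, threshold demotes", {
  # Tanche selfing fruit: impossible strictly, explained by degradation
  selfing <- data.frame(host = "Tanche", donor = "Tanche", outcome = "fruit",
                        n_fruit = 2)
  expect_equal(nrow(check_consistency(selfing, triple_assignment())), 1)
  expect_equal(nrow(check_consistency(selfing, triple_assignment(),
                                      allow_dsd = TRUE)), 0)
  # Picholine selfing stays impossible even with degradation
  p_self <- data.frame(host = "Picholine", donor = "Picholine",
                       outcome = "fruit")
  expect_equal(nrow(check_consistency(p_self, triple_assignment(),
                                      allow_dsd = TRUE)), 1)
  # a trickle of fruit below the threshold reads as no_fruit
  expect_equal(nrow(check_consistency(selfing, triple_assignment(),
                                      fruit_threshold = 5)), 0)
})

test_that("a one-locus class model cannot explain the intransitive triple", {
  for (k in c(2, 3, 6)) {
    expect_length(consistent_assignments(triple_records(), max_alleles = k,
                                         model = "one_locus"), 0)
  }
  expect_true(is.na(min_alleles(triple_records(), model = "one_locus")))
  # the two-screen model explains it
  asg <- consistent_assignments(triple_records(), max_alleles = 6, limit = 1,
                                canonical = FALSE)
  expect_gt(length(asg), 0)
  expect_equal(nrow(check_consistency(triple_records(), asg[[1]])), 0)
})

test_that("symmetric-no-fruit pairs admit same-group assignments", {
  recs <- data.frame(host = c("A", "B"), donor = c("B", "A"),
                     outcome = "no_fruit")
  asg <- consistent_assignments(recs, max_alleles = 2)
  expect_gt(length(asg), 0)
  groups <- vapply(asg, function(a) paste(a$dsi_group, collapse = ""),
                   character(1))
  expect_true(any(groups %in% c("G1G1", "G2G2")))
})

test_that("every returned assignment is sound", {
  fx <- generate_fixture(4, source = "uniform", seed = 33)
  asg <- consistent_assignments(fx$records, max_alleles = 6)
  expect_gt(length(asg), 0)
  for (a in asg[seq_len(min(20, length(asg)))]) {
    expect_equal(nrow(check_consistency(fx$records, a)), 0)
  }
})

test_that("relabeling the codominant class preserves consistency", {
  fx <- generate_fixture(4, source = "uniform", seed = 51)
  asg <- consistent_assignments(fx$records, max_alleles = 6, limit = 5,
                                canonical = FALSE)
  expect_gt(length(asg), 0)
  swap <- c(R1 = "R3", R2 = "R2", R3 = "R1", R4 = "R4", R5 = "R5", R6 = "R6")
  for (a in asg) {
    b <- a
    b$pasi_pair <- vapply(strsplit(a$pasi_pair, "(?<=[0-9])(?=R)", perl = TRUE),
                          function(x) paste(sort(swap[x]), collapse = ""),
                          character(1))
    expect_equal(nrow(check_consistency(fx$records, b)), 0)
  }
})

test_that("generate-and-recover finds the generating assignment", {
  # explicit set membership on fully enumerable instances
  for (seed in c(1, 2, 3, 6, 19)) {
    panel <- random_panel(4, seed)
    asg <- consistent_assignments(diallel_records(panel), max_alleles = 6)
    expect_gt(length(asg), 0)
    expect_true(any(vapply(asg, matches_up_to_relabeling, logical(1),
                           panel = panel)), info = paste("seed", seed))
  }
  # larger panels through the tiered recovery check
  for (seed in 20:27) {
    expect_true(recover_generating(random_panel(4 + seed %% 3, seed)),
                info = paste("seed", seed))
  }
})

test_that("min_alleles is bounded by the generating allele count", {
  empty <- data.frame(host = character(), donor = character(),
                      outcome = character())
  expect_equal(min_alleles(empty), 1L)
  panel <- random_panel(5, 4)
  used <- length(unique(unlist(strsplit(panel$pasi_pair, "(?<=[0-9])(?=R)",
                                        perl = TRUE))))
  m <- min_alleles(diallel_records(panel))
  expect_false(is.na(m))
  expect_lte(m, max(used, max(match(unlist(
    strsplit(panel$pasi_pair, "(?<=[0-9])(?=R)", perl = TRUE)),
    pasi_alleles()))))
  # a fully compatible triple is impossible under two stigma groups alone
  # (three varieties cannot be pairwise in different groups) ...
  tri <- data.frame(host = c("A", "A", "B", "B", "C", "C"),
                    donor = c("B", "C", "A", "C", "A", "B"),
                    outcome = "fruit")
  expect_true(is.na(min_alleles(tri)))
  # ... but degradation-rescued late fruit explains it with few alleles
  expect_lte(min_alleles(tri, allow_dsd = TRUE), 3L)
})

test_that("the search bound raises a helpful error", {
  panel <- random_panel(9, 1)
  recs <- diallel_records(panel)
  expect_error(consistent_assignments(recs), "check_consistency")
  expect_error(min_alleles(recs), "check_consistency")
})
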