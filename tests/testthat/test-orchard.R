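two_variety_orchard <- function(p1 = 0.5, flowers = 30,
                                bloom1 = c(1, 10), bloom2 = c(1, 10)) {
  orchard_config(data.frame(
    name = c("Tanche", "Cayon"), dsi_group = c("G2", "G1"),
    pasi_pair = c("R2R3", "R1R4"), proportion = c(p1, 1 - p1),
    bloom_start = c(bloom1[1], bloom2[1]), bloom_end = c(bloom1[2], bloom2[2])),
    flowers_per_variety = flowers, pollen_per_flower_per_day = 5,
    season_length = 25)
}

test_that("orchard configuration validates and normalizes", {
  orch <- two_variety_orchard()
  expect_s3_class(orch, "orchard_config")
  expect_equal(sum(orch$varieties$proportion), 1)
  raw <- orch$varieties
  raw$proportion <- c(2, 6)  # normalized internally
  expect_equal(orchard_config(raw)$varieties$proportion, c(0.25, 0.75))
  bad <- raw
  bad$bloom_end <- c(40, 40)
  expect_error(orchard_config(bad, season_length = 25), "within")
  dup <- raw
  dup$name <- c("A", "A")
  expect_error(orchard_config(dup), "duplicate")
})

test_that("pollen cloud reflects proportions and bloom windows", {
  single <- orchard_config(data.frame(
    name = "Tanche", dsi_group = "G2", pasi_pair = "R2R3", proportion = 1,
    bloom_start = 2, bloom_end = 6))
  expect_equal(pollen_cloud(single, 3), c(S1_R2 = 1))
  expect_length(pollen_cloud(single, 10), 0)

  both <- two_variety_orchard()
  cl <- pollen_cloud(both, 5)
  expect_setequal(names(cl), c("S1_R2", "S2_R1"))
  expect_equal(unname(cl["S1_R2"]), 0.5)
  expect_equal(sum(cl), 1)

  # same pollen class from two varieties aggregates to one entry
  twins <- orchard_config(data.frame(
    name = c("A", "B"), dsi_group = c("G2", "G2"),
    pasi_pair = c("R2R3", "R2R4"), proportion = c(0.5, 0.5),
    bloom_start = c(1, 1), bloom_end = c(5, 5)))
  expect_equal(pollen_cloud(twins, 2), c(S1_R2 = 1))

  # disjoint bloom windows: one class at a time
  disjoint <- two_variety_orchard(bloom1 = c(1, 5), bloom2 = c(10, 15))
  expect_equal(names(pollen_cloud(disjoint, 3)), "S1_R2")
  expect_equal(names(pollen_cloud(disjoint, 12)), "S2_R1")
})

test_that("strict screens: monoculture sets no fruit, compatible pair outcrosses", {
  off <- dsd_config(mode = "off")
  mono <- orchard_config(data.frame(
    name = "Picholine", dsi_group = "G1", pasi_pair = "R1R3", proportion = 1,
    bloom_start = 1, bloom_end = 10), flowers_per_variety = 40)
  rep0 <- simulate_season(mono, off, seed = 11)
  expect_equal(rep0$per_variety$fruits, 0L)
  expect_equal(nrow(rep0$fathers), 0L)

  duo <- two_variety_orchard(flowers = 40)
  rep1 <- simulate_season(duo, off, seed = 12)
  expect_true(all(rep1$per_variety$selfed == 0L))
  expect_true(all(rep1$per_variety$dsd_events == 0L))
  # every attributed father is fully compatible with its host
  gts <- setNames(duo$genotypes, duo$varieties$name)
  for (i in seq_len(nrow(rep1$fathers))) {
    expect_equal(verdict_code(gts[[rep1$fathers$host[i]]],
                              gts[[rep1$fathers$father[i]]]), "1-1")
  }
  # father counts sum to fruit counts
  agg <- tapply(rep1$fathers$count, rep1$fathers$host, sum)
  for (nm in names(agg)) {
    expect_equal(unname(agg[nm]),
                 rep1$per_variety$fruits[rep1$per_variety$name == nm])
  }
})

test_that("self-fertile monoculture selfs at or after the degradation day", {
  mono <- orchard_config(data.frame(
    name = "Tanche", dsi_group = "G2", pasi_pair = "R2R3", proportion = 1,
    bloom_start = 1, bloom_end = 8), flowers_per_variety = 40)
  cfg <- dsd_config()
  rep <- simulate_season(mono, cfg, seed = 21)
  pv <- rep$per_variety
  expect_gt(pv$fruits, 0)
  expect_equal(pv$selfing_rate, 1)
  expect_equal(pv$dsd_events, pv$fruits)
  # fruit cannot set before opening day + full_day
  expect_gte(pv$mean_set_day, 1 + cfg$full_day)
})

test_that("selfing declines as compatible pollinizer proportion grows", {
  rates <- vapply(c(0.98, 0.7, 0.3), function(p_self) {
    rep <- simulate_season(two_variety_orchard(p1 = p_self, flowers = 60),
                           dsd_config(), seed = 5)
    rep$per_variety$selfing_rate[1]
  }, numeric(1))
  expect_true(all(diff(rates) <= 0))
  expect_gt(rates[1], rates[3])
})

test_that("identical seeds give identical reports", {
  orch <- two_variety_orchard()
  a <- simulate_season(orch, dsd_config(), seed = 7)
  b <- simulate_season(orch, dsd_config(), seed = 7)
  expect_identical(a, b)
  s1 <- simulate_season(orch, dsd_config(mode = "stochastic"), seed = 8)
  s2 <- simulate_season(orch, dsd_config(mode = "stochastic"), seed = 8)
  expect_identical(s1, s2)
})

test_that("paternity diagnosis flags single-screen acceptance", {
  aglandau <- gt("Aglandau", "G2", "R2R5")
  frantoio <- gt("Frantoio", "G1", "R4R5")
  cayetroux <- gt("CayetRoux", "G2", "R4R5")
  d1 <- diagnose_paternity(aglandau, frantoio)
  expect_equal(d1$dsi_verdict, "Accept")
  expect_equal(d1$pasi_verdict, "Reject")
  expect_true(d1$dsd_flag)
  expect_match(d1$recommendation, "pollinizer")
  d2 <- diagnose_paternity(aglandau, cayetroux)
  expect_equal(c(d2$dsi_verdict, d2$pasi_verdict), c("Reject", "Reject"))
  expect_false(d2$dsd_flag)
  d3 <- diagnose_paternity(cayetroux, aglandau)
  expect_equal(c(d3$dsi_verdict, d3$pasi_verdict), c("Reject", "Accept"))
  expect_true(d3$dsd_flag)
  # the flag is exactly the exclusive-or of the two verdicts
  for (h in list(aglandau, frantoio, tanche, picholine)) {
    for (f in list(aglandau, frantoio, tanche, picholine)) {
      d <- diagnose_paternity(h, f)
      expect_equal(d$dsd_flag,
                   xor(d$dsi_verdict == "Accept", d$pasi_verdict == "Accept"))
    }
  }
})
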