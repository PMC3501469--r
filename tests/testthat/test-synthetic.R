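test_that("simulate_cohort matches group structure and is deterministic", {
  cfg <- sim_config(seed = 17)
  fish <- simulate_cohort(cfg)
  expect_equal(nrow(fish), sum(default_cohort_table()$n)) # 302 released

  # published group moments: 2009 Skokomish hatchery mean length 211 (SE 3)
  skh09 <- fish[fish$population == "SkokomishH" & fish$year == 2009, ]
  expect_equal(nrow(skh09), 29)
  expect_lt(abs(mean(skh09$fork_length_mm) - 211), 3 * 3) # within 3 SE

  # condition factor recomputable from weight and length
  expect_equal(fish$condition_factor,
               1e5 * fish$weight_g / fish$fork_length_mm^3)

  # release dates inside each group's window
  bb08 <- fish[fish$population == "BigBeefW" & fish$year == 2008, ]
  expect_true(all(bb08$release_date >= 107 & bb08$release_date <= 128))

  # wild and Duckabush smolts never score SI 1
  expect_true(all(fish$smolt_index[fish$population != "SkokomishH"] > 1))

  fish2 <- simulate_cohort(cfg)
  expect_identical(fish, fish2)

  empty_cfg <- sim_config(cohorts = transform(default_cohort_table(), n = 0L))
  expect_equal(nrow(simulate_cohort(empty_cfg)), 0)
})

test_that("migration fates obey the closed-system and monotonicity laws", {
  det1 <- default_detection()
  det1$rm[] <- 1; det1$HCB <- 1; det1$ADM <- 1; det1$JDF_fixed <- 1
  cfg <- single_group_config("SkokomishW", 2008, 150, rep(1, 4),
                             seed = 31, detection = det1)
  d <- simulate_dataset(cfg)
  eh <- build_encounter_histories(d$events, d$fish, d$receivers)
  expect_true(all(eh$history == 1)) # phi = 1, p = 1: nothing missed
  expect_gte(nrow(d$events), 150 * 4)

  # general config: detection at occasion k implies truth-table survival
  # through all segments up to k, and no detections after death
  cfg2 <- sim_config(seed = 32, residual_prob_by_si = c(0.8, 0.05, 0))
  d2 <- simulate_dataset(cfg2)
  eh2 <- build_encounter_histories(d2$events, d2$fish, d2$receivers)
  alive <- as.matrix(d2$truth[, paste0("alive_", OCCASION_LINES)])
  expect_true(all(eh2$history[, -1] <= alive))
  resid <- d2$truth$fate == "residual"
  expect_true(all(rowSums(eh2$history[resid, -1, drop = FALSE]) == 0))

  # with p = 1 everywhere the histories equal the truth table exactly
  cfg3 <- single_group_config("BigBeefW", 2009, 400,
                              c(0.9, 0.8, 0.5, 0.4), seed = 33,
                              detection = det1)
  d3 <- simulate_dataset(cfg3)
  eh3 <- build_encounter_histories(d3$events, d3$fish, d3$receivers)
  alive3 <- as.matrix(d3$truth[, paste0("alive_", OCCASION_LINES)])
  expect_equal(unname(eh3$history[, -1]), unname(alive3))
})

test_that("detected fractions match the binomial oracle at n = 10,000", {
  half <- default_detection()
  half$rm[] <- 0.5; half$HCB <- 0.5; half$ADM <- 0.5; half$JDF_fixed <- 0.5
  cfg <- single_group_config("BigBeefW", 2008, 10000, rep(1, 4),
                             seed = 41, detection = half)
  sh <- simulate_histories(cfg)
  # binomial SE at p = 0.5, n = 10,000 is 0.005; allow 3 SE
  frac <- colMeans(sh$eh$history[, -1])
  expect_true(all(abs(frac - 0.5) < 0.015))

  cfg2 <- single_group_config("BigBeefW", 2008, 10000,
                              c(0.5, 1, 1, 1), seed = 42, detection = within(
                                default_detection(), {
                                  rm[] <- 1; HCB <- 1; ADM <- 1
                                  JDF_fixed <- 1
                                }))
  sh2 <- simulate_histories(cfg2)
  expect_lt(abs(mean(sh2$eh$history[, "RM"]) - 0.5), 0.015)
})

test_that("identical config and seed reproduce the event log exactly", {
  cohorts <- default_cohort_table()
  cohorts$n <- pmin(cohorts$n, 15L)
  cfg <- sim_config(cohorts = cohorts, seed = 55,
                    residual_prob_by_si = c(0.8, 0.05, 0))
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$events, d2$events)
  expect_identical(d1$truth, d2$truth)
})
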