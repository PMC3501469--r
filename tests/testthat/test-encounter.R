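test_that("event collapse maps lines to occasions and is idempotent", {
  tabs <- make_tiny_tables()
  # A1: RM only -> 11000; A2: RM + HCB -> 11100; A3: nothing -> 10000
  eh <- build_encounter_histories(tabs$events, tabs$fish, tabs$receivers)
  hs <- apply(eh$history, 1, paste, collapse = "")
  expect_equal(unname(hs), c("11000", "11100", "10000"))

  # a fish detected at RM and ADM only gives 10101-style gaps
  ev <- detection_events(data.frame(
    fish_id = c("A1", "A1"), receiver_id = c("RMBB-01", "ADM-05"),
    timestamp = c(112, 140)), tabs$receivers)
  eh2 <- build_encounter_histories(ev, tabs$fish, tabs$receivers)
  expect_equal(paste(eh2$history["A1", ], collapse = ""), "11010")

  # duplication and shuffling change nothing; behavioral receivers ignored
  ev3 <- rbind(tabs$events, tabs$events,
               data.frame(fish_id = "A3", receiver_id = "HCBEH-02",
                          timestamp = 130))
  ev3 <- ev3[sample(nrow(ev3)), ]
  eh3 <- build_encounter_histories(detection_events(ev3, tabs$receivers),
                                   tabs$fish, tabs$receivers)
  expect_equal(eh3$history, eh$history)

  bad <- detection_events(data.frame(fish_id = "A1",
                                     receiver_id = "RMBB-01",
                                     timestamp = 1), tabs$receivers)
  expect_error(build_encounter_histories(bad, tabs$fish, tabs$receivers),
               "before release")
})

test_that("travel_rate is first-detection arithmetic with NA propagation", {
  tabs <- make_tiny_tables()
  # A2 released day 125 at PR-Skokomish, first RM hit day 126 + HCB day 131.2
  r_fw <- travel_rate(tabs$events, tabs$fish, tabs$receivers,
                      "release", "RM-Skokomish", 13.5)
  expect_equal(unname(r_fw["A2"]), 13.5 / 1.0)
  r_marine <- travel_rate(tabs$events, tabs$fish, tabs$receivers,
                          "RM-Skokomish", "HCB", 75)
  expect_equal(unname(r_marine["A2"]), 75 / 5.2)
  expect_true(is.na(r_marine["A1"])) # no HCB detection: undefined, not 0
  expect_true(is.na(r_fw["A3"]))
})

test_that("simulated travel rates recover the configured speed", {
  det1 <- default_detection(); det1$rm[] <- 1; det1$HCB <- 1
  cfg <- single_group_config("SkokomishW", 2008, 1000, rep(1, 4), seed = 61,
                             detection = det1,
                             speed_fw_kmday = c(12, 3))
  d <- simulate_dataset(cfg)
  r <- travel_rate(d$events, d$fish, d$receivers, "release",
                   "RM-Skokomish", 13.5)
  # lognormal speeds are parameterized by their mean: 12 km/day
  expect_lt(abs(mean(r, na.rm = TRUE) - 12), 3 * 3 / sqrt(sum(!is.na(r))))
})

test_that("migration_range takes the northernmost detection", {
  tabs <- make_tiny_tables()
  ev <- detection_events(data.frame(
    fish_id = c("A2", "A2", "A3"),
    receiver_id = c("HCBEH-01", "HCBEH-06", "RMSK-02"),
    timestamp = c(127, 129, 123)), tabs$receivers)
  rng <- migration_range(ev, tabs$fish, tabs$receivers)
  expect_equal(unname(rng["A2"]), 60) # receivers at 10 and 60 km
  expect_equal(unname(rng["A3"]), 0)  # estuary only
  expect_true(is.na(rng["A1"]))       # never detected

  # monotone: adding events never shrinks the range
  ev2 <- rbind(ev, data.frame(fish_id = "A2", receiver_id = "HCB-01",
                              timestamp = 131))
  rng2 <- migration_range(detection_events(ev2, tabs$receivers),
                          tabs$fish, tabs$receivers)
  expect_gte(unname(rng2["A2"]), unname(rng["A2"]))

  # under p = 1 the range equals the truth-table furthest line position
  det1 <- default_detection()
  det1$rm[] <- 1; det1$HCB <- 1; det1$ADM <- 1; det1$JDF_fixed <- 1
  cfg <- single_group_config("SkokomishW", 2008, 200,
                             c(0.9, 0.7, 0.6, 0.5), seed = 62,
                             detection = det1, behavior_detect_prob = 0.5)
  d <- simulate_dataset(cfg)
  rng3 <- migration_range(d$events, d$fish, d$receivers)
  alive <- as.matrix(d$truth[, paste0("alive_", OCCASION_LINES)])
  pos <- c(0, 75, 100, 210) # RM, HCB, ADM, JDF corridor positions
  truth_far <- apply(alive, 1, function(a) {
    w <- which(a == 1); if (length(w)) pos[max(w)] else NA_real_
  })
  idx <- match(d$truth$fish_id, names(rng3))
  expect_equal(unname(rng3[idx]), unname(truth_far))
})

test_that("density tables split fish counts per receiver", {
  tabs <- make_tiny_tables()
  ev <- detection_events(data.frame(
    fish_id = sprintf("A%d", c(1, 2, 3, 1, 2)),
    receiver_id = c("HCB-01", "HCB-01", "HCB-01", "HCBEH-02", "HCBEH-02"),
    timestamp = 130), tabs$receivers)
  dt <- density_table(ev, tabs$fish$fish_id, tabs$receivers)
  expect_equal(dt$proportion_of_detected[dt$receiver_id == "HCB-01"], 1.0)
  expect_equal(dt$proportion_of_detected[dt$receiver_id == "HCBEH-02"],
               2 / 3)
  expect_equal(nrow(density_table(ev, character(0), tabs$receivers)), 0)

  # residual-heavy hatchery group reaches the northern receivers less often
  cohorts <- default_cohort_table()[2:3, ] # 2008 Skokomish wild + hatchery
  cohorts$n <- c(150L, 150L)
  cfg <- sim_config(cohorts = cohorts, seed = 63,
                    residual_prob_by_si = c(0.9, 0.3, 0.1))
  d <- simulate_dataset(cfg)
  north <- function(pop) {
    ids <- d$fish$fish_id[d$fish$population == pop]
    dt <- density_table(d$events, ids, d$receivers)
    sum(dt$n_detected_fish[dt$corridor_position_km >= 60]) /
      max(sum(dt$n_detected_fish), 1)
  }
  expect_lt(north("SkokomishH"), north("SkokomishW"))
})
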