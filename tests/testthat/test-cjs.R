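test_that("model grammar parses and rejects unknown terms", {
  spec <- parse_model_spec(
    "phi ~ segment * SkokH + rd; p ~ segment + RM:line; fix p[JDF]=0.685")
  expect_length(spec$fixed, 1)
  expect_equal(spec$fixed[[1]]$value, 0.685)
  expect_error(parse_model_spec("phi ~ segment + moonphase; p ~ segment"),
               "moonphase")
  expect_error(parse_model_spec("phi ~ segment"), "clause")
})

test_that("design matrices code factors, interactions and fixed cells", {
  cohorts <- default_cohort_table()
  cohorts$n <- pmin(cohorts$n, 12L)
  sh <- simulate_histories(sim_config(cohorts = cohorts, seed = 71))

  d1 <- build_design("phi ~ segment; p ~ segment; fix p[JDF]=0.685", sh$eh)
  expect_length(d1$est_phi, 4) # one estimable phi column per segment

  d2 <- build_design("phi ~ segment * SkokH; p ~ segment; fix p[JDF]=0.685",
                     sh$eh)
  expect_length(d2$est_phi, 8) # 4 segments x 2 groups

  # the standard top model counts 15 design parameters
  d3 <- build_design(
    "phi ~ segment * SkokH + rd; p ~ segment + RM:line; fix p[JDF]=0.685",
    sh$eh)
  expect_equal(d3$K, 15)
  # the fixed terminal cell removes one estimated beta but not the count
  expect_equal(d3$n_beta, 14)

  # aliased columns are dropped (one river-mouth column is redundant)
  expect_true(length(d3$dropped) >= 1)
})

test_that("likelihood matches closed forms and the enumeration oracle", {
  # single fish, one occasion: "11" forced path and "10" chi closed form
  expect_equal(cjs_negloglik_real(matrix(0.5), matrix(1), matrix(1L)),
               -log(0.5))
  expect_equal(cjs_negloglik_real(matrix(0.5), matrix(0.5), matrix(0L)),
               -log(0.75))

  # every 4-occasion history against exhaustive fate enumeration
  set.seed(81)
  hists <- as.matrix(expand.grid(0:1, 0:1, 0:1, 0:1))
  dimnames(hists) <- NULL
  for (rep in 1:50) {
    phi <- runif(4, 0.05, 0.99)
    p <- runif(4, 0.05, 0.99)
    for (i in seq_len(nrow(hists))) {
      y <- hists[i, ]
      nll <- cjs_negloglik_real(matrix(phi, 1), matrix(p, 1),
                                matrix(y, 1))
      expect_equal(nll, -log(brute_force_history_prob(y, phi, p)),
                   tolerance = 1e-10)
    }
  }
})

test_that("saturated fit reproduces closed-form survivor ratios at p = 1", {
  det1 <- default_detection()
  det1$rm[] <- 1; det1$HCB <- 1; det1$ADM <- 1; det1$JDF_fixed <- 1
  cfg <- single_group_config("BigBeefW", 2008, 2000, c(0.9, 0.7, 0.5, 0.4),
                             seed = 91, detection = det1)
  sh <- simulate_histories(cfg)
  f <- cjs_fit(paste0("phi ~ segment; p ~ segment; fix p[RM]=1; ",
                      "fix p[HCB]=1; fix p[ADM]=1; fix p[JDF]=1"), sh$eh)
  n_alive <- colSums(sh$alive)
  emp <- n_alive / c(nrow(sh$alive), n_alive[-4])
  expect_equal(f$real_phi$estimate, unname(emp), tolerance = 1e-6)
})

test_that("estimates are invariant to fish order; duplication shrinks SEs", {
  cfg <- single_group_config("BigBeefW", 2008, 600,
                             c(0.95, 0.85, 0.5, 0.45), p_rm = 0.9, seed = 92)
  sh <- simulate_histories(cfg)
  f1 <- cjs_fit("phi ~ segment; p ~ segment; fix p[JDF]=0.685", sh$eh)

  perm <- sample(nrow(sh$eh$history))
  eh_p <- encounter_histories(sh$eh$history[perm, ],
                              sh$eh$records[perm, ], sh$eh$occasions)
  f2 <- cjs_fit("phi ~ segment; p ~ segment; fix p[JDF]=0.685", eh_p)
  expect_equal(f1$real_phi$estimate, f2$real_phi$estimate, tolerance = 1e-5)

  rec2 <- rbind(sh$eh$records, transform(sh$eh$records,
                                         fish_id = paste0(fish_id, "b")))
  eh_d <- encounter_histories(rbind(sh$eh$history, sh$eh$history),
                              fish_records(rec2), sh$eh$occasions)
  f3 <- cjs_fit("phi ~ segment; p ~ segment; fix p[JDF]=0.685", eh_d)
  expect_equal(f3$real_phi$estimate, f1$real_phi$estimate, tolerance = 1e-5)
  expect_equal(f3$real_phi$se[1:3], f1$real_phi$se[1:3] / sqrt(2),
               tolerance = 0.02)
})

test_that("parameter recovery stays inside 3 Monte-Carlo SEs", {
  # scaled down from the 100 x 10,000 property: 25 replicates of 4,000
  # fish keep the whole suite inside its runtime budget
  phi_true <- c(0.969, 0.892, 0.389, 0.457)
  hits <- 0L; total <- 0L
  for (r in 1:25) {
    cfg <- single_group_config("BigBeefW", 2008, 4000, phi_true,
                               p_rm = 0.928, seed = 1000 + r)
    sh <- simulate_histories(cfg)
    f <- cjs_fit("phi ~ segment; p ~ segment; fix p[JDF]=0.685", sh$eh)
    ok <- abs(f$real_phi$estimate - phi_true) < 3 * f$real_phi$se
    hits <- hits + sum(ok); total <- total + length(ok)
  }
  expect_gte(hits / total, 0.95)
})

test_that("terminal phi and p are confounded until p is fixed", {
  cfg <- single_group_config("BigBeefW", 2008, 1500,
                             c(0.95, 0.85, 0.5, 0.45), p_rm = 0.9, seed = 93)
  sh <- simulate_histories(cfg)

  f_free <- cjs_fit("phi ~ segment; p ~ segment", sh$eh)
  expect_true(f_free$terminal_confounded)
  expect_true("confounded" %in% names(f_free$real_phi))
  pr <- profile_confounding(f_free)
  expect_true(pr$confounded)
  expect_lt(pr$ridge_range, 1e-6)

  f_fix <- cjs_fit("phi ~ segment; p ~ segment; fix p[JDF]=0.685", sh$eh)
  expect_false(f_fix$terminal_confounded)
  pr2 <- profile_confounding(f_fix)
  expect_false(pr2$confounded)
  expect_gt(pr2$ridge_range, 1e-3)

  # the identifiable product matches between the two parameterizations
  prod_free <- f_free$real_phi$estimate[4] * f_free$real_p$estimate[4]
  prod_fix <- f_fix$real_phi$estimate[4] * 0.685
  expect_equal(prod_free, prod_fix, tolerance = 0.01)
})
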