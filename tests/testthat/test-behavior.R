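test_that("adjusted G-test matches the Poisson-deviance oracle", {
  # perfect independence
  r0 <- g_test_adj(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r0$G_adj, 0, ignore_attr = TRUE)
  expect_equal(r0$p, 1, ignore_attr = TRUE)

  # the uncorrected G equals the deviance of the independence log-linear
  # model (an independent route through glm)
  tabs <- list(matrix(c(1, 13, 60, 27), 2, byrow = TRUE),
               matrix(c(5, 20, 30, 12), 2, byrow = TRUE),
               matrix(c(40, 3, 7, 22), 2, byrow = TRUE))
  for (tab in tabs) {
    df <- data.frame(count = as.vector(tab),
                     r = factor(rep(1:2, 2)), c = factor(rep(1:2, each = 2)))
    dev <- stats::glm(count ~ r + c, poisson, df)$deviance
    res <- g_test_adj(tab)
    expect_equal(res$G, dev, tolerance = 1e-8, ignore_attr = TRUE)
    expect_lte(res$G_adj, res$G) # Williams divisor >= 1
    expect_gte(res$q, 1)
  }

  # zero cell is finite via 0 ln 0 = 0; zero margin is flagged
  fin <- g_test_adj(matrix(c(0, 10, 5, 7), 2))
  expect_true(is.finite(fin$G))
  expect_warning(und <- g_test_adj(matrix(c(0, 0, 5, 7), 2, byrow = TRUE)),
                 "margin")
  expect_true(is.na(und$G))
})

test_that("G_adj <= G on random tables and type-I error is calibrated", {
  set.seed(121)
  for (i in 1:200) {
    tab <- matrix(rpois(4, lambda = sample(3:40, 1)) + 1, 2)
    res <- g_test_adj(tab)
    expect_lte(res$G_adj, res$G + 1e-12)
  }
  # null simulation at the smolt-index margins (14% small row, 60%
  # detected): rejection rate at alpha = 0.05 must sit in [0.04, 0.06]
  reps <- 10000; n <- 100
  pvals <- vapply(seq_len(reps), function(i) {
    r <- stats::rbinom(n, 1, 0.14)
    c <- stats::rbinom(n, 1, 0.60)
    tab <- matrix(c(sum(r & c), sum(r & !c), sum(!r & c), sum(!r & !c)),
                  2, 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(NA_real_)
    suppressWarnings(g_test_adj(tab)$p)
  }, numeric(1))
  rate <- mean(pvals < 0.05, na.rm = TRUE)
  expect_gte(rate, 0.04)
  expect_lte(rate, 0.06)
})

test_that("smolt-index detection table counts detected-at-or-beyond RM", {
  eh <- make_eh(c("11000", "10000", "10100", "10000"),
                population = "SkokomishH")
  eh$records$smolt_index <- c(1L, 1L, 3L, 2L)
  tab <- si_detection_table(eh$records, eh)
  expect_equal(unname(tab), matrix(c(1, 1, 1, 1), 2, byrow = TRUE))
})

test_that("two-way ANOVA matches the balanced closed-form oracle", {
  # balanced 2 x 3 design: textbook sums of squares are exact
  set.seed(131)
  cells <- expand.grid(origin = c("wild", "hatchery"),
                       year = factor(2008:2010))
  n_cell <- 8
  mu <- c(10, 7, 12, 9, 11, 8)
  df <- cells[rep(seq_len(6), each = n_cell), ]
  df$y <- rep(mu, each = n_cell) + rnorm(6 * n_cell, 0, 1.2)

  res <- two_way_anova(df, "y")

  # textbook two-way decomposition computed directly
  gm <- mean(df$y)
  mA <- tapply(df$y, df$origin, mean)
  mB <- tapply(df$y, df$year, mean)
  mAB <- tapply(df$y, interaction(df$origin, df$year), mean)
  ssA <- 3 * n_cell * sum((mA - gm)^2)
  ssB <- 2 * n_cell * sum((mB - gm)^2)
  ssCells <- n_cell * sum((mAB - gm)^2)
  ssAB <- ssCells - ssA - ssB
  ssE <- sum((df$y - mAB[interaction(df$origin, df$year)])^2)
  dfe <- 6 * (n_cell - 1)
  expect_equal(res$table$F,
               c(ssA / 1, ssB / 2, ssAB / 2) / (ssE / dfe),
               tolerance = 1e-8)
  expect_equal(res$df_res, dfe)

  # constant response: all F are zero
  flat <- df; flat$y <- 5
  expect_true(all(two_way_anova(flat, "y")$table$F == 0))

  # scaling the response leaves F unchanged
  sc <- df; sc$y <- df$y * 7
  expect_equal(two_way_anova(sc, "y")$table$F, res$table$F,
               tolerance = 1e-8)
})

test_that("interaction contrasts are detected and Tukey respects the gate", {
  set.seed(141)
  make_data <- function(gap_years) {
    cells <- expand.grid(origin = c("wild", "hatchery"),
                         year = factor(2008:2010))
    df <- cells[rep(seq_len(6), each = 12), ]
    base <- ifelse(df$origin == "wild" & df$year %in% gap_years, 40, 10)
    df$y <- base + rnorm(nrow(df), 0, 3)
    df
  }
  # wild >> hatchery in two of three years: interaction significant, and
  # Tukey flags exactly those years
  hits <- 0L
  for (r in 1:20) {
    df <- make_data(c("2008", "2010"))
    res <- two_way_anova(df, "y")
    if (res$table$p[3] <= 0.05) {
      tk <- tukey_hsd(res)
      sig <- tk$within[tk$p < 0.05]
      if (setequal(sig, c("2008", "2010"))) hits <- hits + 1L
    }
  }
  expect_gte(hits / 20, 0.95)

  # identical groups: Tukey p-values are 1 (gate forced via big interaction
  # in other cells)
  df <- make_data("2008")
  df$y[df$year == "2009"] <- 5 # identical constant in 2009 cells
  res <- two_way_anova(df, "y")
  tk <- tukey_hsd(res)
  expect_equal(tk$p[tk$within == "2009"], 1, tolerance = 1e-6)

  # no significant interaction: refuse with a message
  null_df <- make_data(character(0))
  res0 <- two_way_anova(null_df, "y")
  expect_gt(res0$table$p[3], 0.05)
  expect_error(tukey_hsd(res0), "not significant")
})

test_that("Tukey-Kramer agrees with the stats reference on balanced data", {
  set.seed(151)
  cells <- expand.grid(origin = c("wild", "hatchery"),
                       year = factor(2008:2010))
  df <- cells[rep(seq_len(6), each = 10), ]
  df$y <- rnorm(nrow(df), ifelse(df$origin == "wild", 20, 12) +
                  3 * as.integer(df$year), 4)
  res <- two_way_anova(df, "y")
  tk <- tukey_hsd(res, alpha = 1) # bypass the gate to compare machinery
  ref <- stats::TukeyHSD(stats::aov(y ~ origin * year, df))$`origin:year`
  for (i in seq_len(nrow(tk))) {
    nms <- c(paste0(tk$group1[i], ":", tk$within[i], "-",
                    tk$group2[i], ":", tk$within[i]),
             paste0(tk$group2[i], ":", tk$within[i], "-",
                    tk$group1[i], ":", tk$within[i]))
    nm <- intersect(nms, rownames(ref))
    expect_length(nm, 1)
    expect_equal(unname(tk$p[i]), unname(ref[nm, "p adj"]),
                 tolerance = 1e-6)
  }
})
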