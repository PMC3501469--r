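# Cohort and migration simulator. The generating process is exactly the CJS
# structure the estimator assumes: independent Bernoulli survival per
# corridor segment and independent Bernoulli detection per receiver line,
# with two optional departures used only to exercise diagnostics -- a
# per-fish logit-normal frailty on survival (overdispersion, for c-hat
# calibration) and a smolt-index-linked residualization state (fish that
# never leave freshwater; apparent survival folds these in).

month_day_to_doy <- function(year, md) {
  as.integer(strftime(as.Date(paste0(year, "-", md)), "%j"))
}

si_probs_for <- function(population, smolt_index_mean) {
  if (population == "SkokomishH") {
    # age-2 Skokomish hatchery groups contained unsmolted (SI = 1) fish
    p1 <- max(0.10, 2.05 - smolt_index_mean)
  } else {
    p1 <- 0 # wild and Duckabush hatchery smolts all scored 2 or 3
  }
  p3 <- smolt_index_mean - 2 + p1
  p3 <- min(max(p3, 0), 1 - p1)
  c(p1, 1 - p1 - p3, p3)
}

#' Build a simulation configuration
#'
#' The default configuration reproduces the study design the package
#' emulates: ten (population, year) tag groups with published cohort
#' moments, generating segment survival taken from the published group-year
#' survival table, and line detection probabilities from the published
#' estimates. Survival entering the simulator is *apparent* survival, so
#' residualization is off by default (non-migrants are already folded into
#' 1 - phi); switch it on for behavior-focused runs.
#'
#' @param cohorts cohort table as [default_cohort_table()]; rows may be
#'   edited (e.g. `n` scaled) before passing
#' @param survival generating survival table as [default_survival_table()]
#' @param detection detection list as [default_detection()]
#' @param residual_prob_by_si length-3 probability a fish with smolt index
#'   1, 2, 3 never leaves freshwater
#' @param speed_fw_kmday,speed_marine_kmday mean (and SD, second element)
#'   migration speed for the freshwater segment and marine segments
#' @param frailty_sd SD of a shared per-fish normal deviate (a latent fish
#'   quality) added to logit(phi) in every segment and to logit(p) at every
#'   line; 0 = exact CJS generation. Survival-only frailty in a single
#'   release cohort is absorbed by the time-dependent phi's; the detection
#'   component is what contingency-table GOF can actually see, making this
#'   the overdispersion knob for c-hat work.
#' @param behavior_detect_prob probability a live fish passing a behavioral
#'   receiver logs an event there
#' @param seed integer RNG seed
#' @return a `sim_config` list
#' @export
sim_config <- function(cohorts = default_cohort_table(),
                       survival = default_survival_table(),
                       detection = default_detection(),
                       residual_prob_by_si = c(0, 0, 0),
                       speed_fw_kmday = c(10, 4),
                       speed_marine_kmday = c(15, 5),
                       frailty_sd = 0,
                       behavior_detect_prob = 0.5,
                       seed = 1L) {
  stopifnot(length(residual_prob_by_si) == 3,
            all(residual_prob_by_si >= 0 & residual_prob_by_si <= 1),
            speed_fw_kmday[1] > 0, speed_marine_kmday[1] > 0,
            frailty_sd >= 0)
  if (any(unlist(survival[, SEGMENT_NAMES]) <= 0) ||
      any(unlist(survival[, SEGMENT_NAMES]) > 1)) {
    stop("generating survival must be in (0, 1]", call. = FALSE)
  }
  structure(list(cohorts = cohorts, survival = survival,
                 detection = detection,
                 residual_prob_by_si = residual_prob_by_si,
                 speed_fw_kmday = speed_fw_kmday,
                 speed_marine_kmday = speed_marine_kmday,
                 frailty_sd = frailty_sd,
                 behavior_detect_prob = behavior_detect_prob,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# generating phi row for a (population, year): Skokomish hatchery fish get
# the SkokomishH row, everything else the pooled wild row of that year
generating_phi <- function(config, population, year) {
  grp <- if (population == "SkokomishH") "SkokomishH" else "pooled_wild"
  row <- config$survival[config$survival$year == year &
                           config$survival$group == grp, ]
  if (nrow(row) != 1) {
    # fall back to the year-averaged group row (e.g. single-year configs)
    row <- config$survival[config$survival$group == grp, ][1, ]
  }
  unlist(row[, SEGMENT_NAMES])
}

generating_p <- function(config, population) {
  det <- config$detection
  c(RM = unname(det$rm[[population]]), HCB = det$HCB, ADM = det$ADM,
    JDF = det$JDF_fixed)
}

#' Simulate a tagged cohort
#'
#' Draws one `fish_records` row per fish: fork length normal around the
#' group mean (SD recovered from the printed SE), weight through a normal
#' condition factor (so condition is recoverable from length and weight),
#' smolt index from a per-group simplex matching the printed mean, and
#' release day uniform in the group's release window.
#'
#' @param config a [sim_config()]
#' @return a [fish_records()] table with a `release_time` column (timestamp
#'   in days, equal to the release day-of-year)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  rows <- lapply(seq_len(nrow(config$cohorts)), function(i) {
    g <- config$cohorts[i, ]
    n <- g$n
    if (n == 0) return(NULL)
    len <- stats::rnorm(n, g$length_mean, g$length_sd)
    len <- pmax(len, g$length_mean * 0.5)
    k <- pmax(stats::rnorm(n, g$condition_mean, 0.05), 0.5)
    weight <- k * len^3 / 1e5
    si <- sample(1:3, n, replace = TRUE,
                 prob = si_probs_for(g$population, g$smolt_index_mean))
    doy0 <- month_day_to_doy(g$year, g$release_start)
    doy1 <- month_day_to_doy(g$year, g$release_end)
    rd <- sample(seq(doy0, doy1), n, replace = TRUE)
    data.frame(
      fish_id = sprintf("%s-%d-%03d", g$population, g$year, seq_len(n)),
      population = g$population, year = g$year,
      fork_length_mm = round(len, 1), weight_g = round(weight, 1),
      smolt_index = si, release_date = rd,
      release_site = paste0("PR-", g$population),
      release_time = as.numeric(rd),
      stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    empty <- data.frame(fish_id = character(), population = character(),
                        year = integer(), fork_length_mm = numeric(),
                        weight_g = numeric(), smolt_index = integer(),
                        release_date = integer(), release_site = character(),
                        release_time = numeric())
    return(fish_records(empty))
  }
  fish_records(do.call(rbind, rows))
}

lognormal_speed <- function(n, mean_sd) {
  m <- mean_sd[1]; s <- if (length(mean_sd) > 1) mean_sd[2] else m * 0.3
  sdlog <- sqrt(log(1 + (s / m)^2))
  stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate migration fates and detection events
#'
#' Each fish either residualizes (with a smolt-index-dependent probability)
#' or migrates seaward, surviving segment s with probability phi_s and, if
#' alive at line k, being detected there with probability p_k. Detected
#' fish log an event at one receiver of the line at its passage time
#' (cumulative distance over lognormal segment speeds). Live fish passing
#' behavioral receivers between their river mouth and their furthest
#' survived line log events with probability `behavior_detect_prob`.
#'
#' @param fish a [fish_records()] table (needs `release_time`)
#' @param config a [sim_config()]
#' @param receivers a [receiver_lines()] table
#' @return list with `truth` (per-fish fate table) and `events`
#'   ([detection_events()])
#' @export
simulate_migration <- function(fish, config, receivers = default_receivers()) {
  stopifnot(inherits(config, "sim_config"))
  seed2 <- (config$seed %% 2000000000L) + 7L
  set.seed(seed2)
  n <- nrow(fish)
  T_occ <- 4L
  alive <- matrix(0L, n, T_occ)   # alive at line k (survived segments 1..k)
  det <- matrix(0L, n, T_occ)     # detected at line k
  tpass <- matrix(NA_real_, n, T_occ)
  fate <- character(n)
  death_segment <- rep(NA_integer_, n)
  ev <- vector("list", n)

  occ_recv <- lapply(seq_len(T_occ), function(k) {
    receivers[!is.na(receivers$occasion) & receivers$occasion == k, ]
  })
  beh <- receivers[is.na(receivers$occasion), ]
  frail <- if (config$frailty_sd > 0) stats::rnorm(n, 0, config$frailty_sd)
           else numeric(n)

  # per-group parameter lookup (avoids per-fish table scans)
  keys <- paste(fish$population, fish$year)
  lookup <- lapply(unique(keys), function(k) {
    i <- match(k, keys)
    pop <- fish$population[i]
    list(phi = generating_phi(config, pop, fish$year[i]),
         p = generating_p(config, pop),
         pos = line_positions(pop),
         geom = default_geometry(pop)$segments)
  })
  names(lookup) <- unique(keys)

  for (i in seq_len(n)) {
    pop <- fish$population[i]
    grp <- lookup[[keys[i]]]
    phi <- grp$phi
    p <- grp$p
    if (config$frailty_sd > 0) {
      phi <- stats::plogis(stats::qlogis(phi) + frail[i])
      p <- stats::plogis(stats::qlogis(p) + frail[i])
    }
    pos <- grp$pos
    geom <- grp$geom
    res_p <- config$residual_prob_by_si[fish$smolt_index[i]]
    if (stats::runif(1) < res_p) {
      fate[i] <- "residual"
      next
    }
    speeds <- c(lognormal_speed(1, config$speed_fw_kmday),
                lognormal_speed(3, config$speed_marine_kmday))
    t_at <- fish$release_time[i] + cumsum(geom$distance_km / speeds)
    evs <- list()
    died <- FALSE
    for (k in seq_len(T_occ)) {
      if (stats::runif(1) > phi[k]) { # died in segment k
        death_segment[i] <- k
        fate[i] <- "died"
        died <- TRUE
        break
      }
      alive[i, k] <- 1L
      tpass[i, k] <- t_at[k]
      if (stats::runif(1) < p[k]) {
        det[i, k] <- 1L
        rl <- occ_recv[[k]]
        if (k == 1) rl <- rl[rl$line_id == rm_line_for(pop), ]
        rid <- rl$receiver_id[sample.int(nrow(rl), 1)]
        evs[[length(evs) + 1]] <- data.frame(
          fish_id = fish$fish_id[i], receiver_id = rid,
          timestamp = t_at[k], stringsAsFactors = FALSE)
      }
    }
    if (!died) fate[i] <- "survived"
    # behavioral receivers between this fish's river mouth and its furthest
    # survived line (migration-range structure)
    extent_line <- max(c(0L, which(alive[i, ] == 1L)))
    if (nrow(beh) && extent_line >= 1L) {
      far_pos <- pos[[OCCASION_LINES[extent_line]]]
      lo <- min(pos[["RM"]], far_pos); hi <- max(pos[["RM"]], far_pos)
      cand <- beh[beh$corridor_position_km > lo &
                    beh$corridor_position_km < hi, ]
      if (nrow(cand)) {
        hit <- stats::runif(nrow(cand)) < config$behavior_detect_prob
        if (any(hit)) {
          frac <- abs(cand$corridor_position_km[hit] - pos[["RM"]]) /
            max(hi - lo, 1e-9)
          evs[[length(evs) + 1]] <- data.frame(
            fish_id = fish$fish_id[i], receiver_id = cand$receiver_id[hit],
            timestamp = tpass[i, 1] +
              frac * (t_at[min(extent_line + 1L, T_occ)] - tpass[i, 1]),
            stringsAsFactors = FALSE)
        }
      }
    }
    ev[[i]] <- if (length(evs)) do.call(rbind, evs) else NULL
  }
  events <- do.call(rbind, ev[!vapply(ev, is.null, logical(1))])
  if (is.null(events)) {
    events <- data.frame(fish_id = character(), receiver_id = character(),
                         timestamp = numeric())
  }
  truth <- data.frame(fish_id = fish$fish_id, fate = fate,
                      death_segment = death_segment,
                      stringsAsFactors = FALSE)
  colnames(alive) <- paste0("alive_", OCCASION_LINES)
  colnames(det) <- paste0("det_", OCCASION_LINES)
  colnames(tpass) <- paste0("t_", OCCASION_LINES)
  truth <- cbind(truth, alive, det, tpass)
  list(truth = truth,
       events = detection_events(events[order(events$fish_id,
                                              events$timestamp), ,
                                        drop = FALSE], receivers))
}

#' Simulate encounter histories directly (vectorized)
#'
#' Generates the same survival/detection fates as [simulate_migration()]
#' without the event-level layer (no receivers, timestamps or behavioral
#' detections), which makes large parameter-recovery and calibration runs
#' cheap. Survival through segment s and detection at line k are the same
#' independent Bernoulli draws; residualization and per-fish frailty apply
#' identically.
#'
#' @param config a [sim_config()]
#' @return list with `eh` ([encounter_histories()]), `fish`, and `alive`
#'   (true per-occasion survival indicators)
#' @export
simulate_histories <- function(config) {
  fish <- simulate_cohort(config)
  set.seed((config$seed %% 2000000000L) + 7L)
  n <- nrow(fish); T_occ <- 4L
  keys <- paste(fish$population, fish$year)
  phi <- matrix(NA_real_, n, T_occ)
  p <- matrix(NA_real_, n, T_occ)
  for (k in unique(keys)) {
    i <- keys == k
    first <- match(k, keys)
    phi[i, ] <- matrix(generating_phi(config, fish$population[first],
                                      fish$year[first]),
                       sum(i), T_occ, byrow = TRUE)
    p[i, ] <- matrix(generating_p(config, fish$population[first]),
                     sum(i), T_occ, byrow = TRUE)
  }
  if (config$frailty_sd > 0) {
    frail <- stats::rnorm(n, 0, config$frailty_sd)
    phi <- stats::plogis(stats::qlogis(phi) + frail)
    p <- stats::plogis(stats::qlogis(p) + frail)
  }
  migrant <- stats::runif(n) >=
    config$residual_prob_by_si[fish$smolt_index]
  alive <- matrix(0L, n, T_occ)
  prev <- as.integer(migrant)
  for (k in seq_len(T_occ)) {
    alive[, k] <- prev * (stats::runif(n) < phi[, k])
    prev <- alive[, k]
  }
  det <- alive * (matrix(stats::runif(n * T_occ), n, T_occ) < p)
  list(eh = encounter_histories(cbind(1L, det), fish), fish = fish,
       alive = alive)
}

#' Single-group simulation configuration
#'
#' Convenience for parameter-recovery work: one (population, year) group of
#' `n` fish with explicit generating segment survival and river-mouth
#' detection probability (other lines keep their defaults).
#'
#' @param population,year group identity
#' @param n number of fish
#' @param phi length-4 generating segment survival (PR-RM, RM-HCB,
#'   HCB-ADM, ADM-JDF)
#' @param p_rm river-mouth detection probability for this population
#' @param seed RNG seed
#' @param detection detection list as [default_detection()]
#' @param ... further arguments to [sim_config()]
#' @return a `sim_config`
#' @export
single_group_config <- function(population, year, n, phi, p_rm = NULL,
                                seed = 1L, detection = default_detection(),
                                ...) {
  stopifnot(length(phi) == 4)
  cohorts <- default_cohort_table()
  row <- cohorts[cohorts$population == population, ][1, ]
  if (is.na(row$n)) stop("unknown population: ", population, call. = FALSE)
  row$year <- as.integer(year)
  row$n <- as.integer(n)
  grp <- if (population == "SkokomishH") "SkokomishH" else "pooled_wild"
  survival <- data.frame(year = as.integer(year), group = grp,
                         check.names = FALSE, stringsAsFactors = FALSE)
  survival[, SEGMENT_NAMES] <- as.list(phi)
  survival$marine_printed <- prod(phi[2:4])
  survival$marine_lo <- NA_real_; survival$marine_hi <- NA_real_
  if (!is.null(p_rm)) detection$rm[population] <- p_rm
  sim_config(cohorts = row, survival = survival, detection = detection,
             seed = seed, ...)
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: cohort, migration, and receiver deployment in one
#' call, in the same shapes [read_tables()] returns plus the ground truth.
#'
#' @param config a [sim_config()]
#' @return list with `fish`, `receivers`, `events`, `truth`, `config`
#' @export
simulate_dataset <- function(config = sim_config()) {
  fish <- simulate_cohort(config)
  receivers <- default_receivers()
  mig <- simulate_migration(fish, config, receivers)
  list(fish = fish, receivers = receivers, events = mig$events,
       truth = mig$truth, config = config)
}
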