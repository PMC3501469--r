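# Default parameter tables for the Hood Canal steelhead emulation: three
# release years (2008-2010), two wild populations (Big Beef Creek weir,
# Skokomish River screwtrap) and two conservation-hatchery populations
# (Skokomish reared at McKernan, Duckabush reared at Lilliwaup). These
# tables are the simulator's stated world; they are also the generating
# truth for parameter-recovery tests.

#' Default cohort structure
#'
#' Published cohort moments for the ten (population, year) tag groups:
#' sample size, mean fork length and weight with standard errors, release
#' date window (day of year), mean smolt index and mean Fulton condition
#' factor. Sample SDs are recovered as SE * sqrt(n).
#'
#' @return data.frame, one row per tag group (total n = 302)
#' @export
default_cohort_table <- function() {
  df <- data.frame(
    year = c(2008L, 2008L, 2008L, 2009L, 2009L, 2009L, 2009L,
             2010L, 2010L, 2010L),
    population = c("BigBeefW", "SkokomishW", "SkokomishH",
                   "BigBeefW", "SkokomishW", "SkokomishH", "DuckabushH",
                   "BigBeefW", "SkokomishW", "SkokomishH"),
    n = c(27L, 41L, 42L, 32L, 23L, 29L, 30L, 36L, 12L, 30L),
    length_mean = c(183, 180, 171, 175, 175, 211, 211, 178, 167, 201),
    length_se = c(3, 3, 1, 2, 4, 3, 2, 2, 4, 3),
    weight_mean = c(57.6, 53.7, 49.0, 48.2, 50.9, 93.5, 91.6,
                    50.2, 42.6, 76.3),
    weight_se = c(2.6, 2.5, 1.1, 2.4, 3.3, 3.5, 3.2, 2.1, 3.1, 3.6),
    release_start = c("04-16", "05-02", "04-29", "04-24", "04-29", "04-29",
                      "05-30", "04-14", "04-22", "04-22"),
    release_end = c("05-07", "05-23", "05-27", "05-10", "05-27", "06-06",
                    "06-06", "05-05", "05-29", "04-30"),
    smolt_index_mean = c(2.63, 2.46, 2.19, 2.34, 2.22, 2.24, 3.00,
                         2.80, 2.45, 1.77),
    condition_mean = c(0.93, 0.97, 0.90, 0.89, 0.93, 0.98, 0.97,
                       0.89, 0.91, 0.93),
    stringsAsFactors = FALSE
  )
  df$length_sd <- df$length_se * sqrt(df$n)
  df$weight_sd <- df$weight_se * sqrt(df$n)
  df
}

#' Default generating survival table
#'
#' Published segment-specific apparent survival (proportions) for the six
#' estimated group-year rows, the published cumulative marine (RM-JDF)
#' survival, and the sensitivity range obtained by fixing the terminal
#' detection probability at its 95% confidence bounds. `group` pools the
#' populations exactly as the best year-structured model did: wild
#' populations (plus the Duckabush hatchery group in 2009) versus the
#' Skokomish hatchery group.
#'
#' @return data.frame with columns `year`, `group`, the four segment
#'   survivals, `marine_printed`, `marine_lo`, `marine_hi`
#' @export
default_survival_table <- function() {
  data.frame(
    year = c(2008L, 2008L, 2009L, 2009L, 2010L, 2010L),
    group = rep(c("pooled_wild", "SkokomishH"), 3),
    `PR-RM` = c(0.969, 0.587, 0.961, 0.522, 0.958, 0.502),
    `RM-HCB` = c(0.892, 0.341, 0.864, 0.285, 0.855, 0.269),
    `HCB-ADM` = c(0.389, 0.470, 0.329, 0.406, 0.312, 0.387),
    `ADM-JDF` = c(0.457, 0.320, 0.393, 0.266, 0.374, 0.251),
    marine_printed = c(0.159, 0.051, 0.112, 0.031, 0.100, 0.026),
    marine_lo = c(0.122, 0.038, 0.084, 0.023, 0.073, 0.018),
    marine_hi = c(0.259, 0.089, 0.187, 0.052, 0.183, 0.050),
    check.names = FALSE, stringsAsFactors = FALSE
  )
}

#' Default line detection probabilities
#'
#' River-mouth detection probability differs by river (the Big Beef weir
#' line was far more efficient than the Skokomish and Duckabush mouth
#' receivers); the Hood Canal Bridge and Admiralty Inlet lines share rates
#' across populations, and the terminal Strait of Juan de Fuca line is fixed
#' from an external estimate rather than estimated.
#'
#' @return named list: `rm` (per population), `HCB`, `ADM`, `JDF_fixed`,
#'   and the 95% bounds used for the fixed-p sensitivity analysis
#' @export
default_detection <- function() {
  list(
    rm = c(BigBeefW = 0.928, SkokomishW = 0.415, SkokomishH = 0.415,
           DuckabushH = 0.489),
    HCB = 0.767,
    ADM = 0.757,
    JDF_fixed = 0.685,
    JDF_bounds = c(lower = 0.428, upper = 0.863)
  )
}

#' Default corridor geometry
#'
#' Corridor positions are km seaward of the Skokomish River estuary.
#' Freshwater (PR-RM) segment lengths: Big Beef 0.05 km, Duckabush 1.9 km,
#' Skokomish 13.5 km. RM-HCB: 24 km (Big Beef, which enters Hood Canal
#' about 1.6 km north of the Duckabush mouth), 25.6 km (Duckabush), 75 km
#' (Skokomish). HCB-ADM is 25 km and ADM-JDF 110 km for all populations.
#'
#' @param population one of the four populations
#' @return a [segment_geometry()] for that population
#' @export
default_geometry <- function(population = POPULATIONS) {
  population <- match.arg(population)
  rm_hcb <- c(BigBeefW = 24, SkokomishW = 75, SkokomishH = 75,
              DuckabushH = 25.6)
  pr_rm <- c(BigBeefW = 0.05, SkokomishW = 13.5, SkokomishH = 13.5,
             DuckabushH = 1.9)
  segment_geometry(population, data.frame(
    from_line = c("PR", "RM", "HCB", "ADM"),
    to_line = c("RM", "HCB", "ADM", "JDF"),
    distance_km = c(pr_rm[[population]], rm_hcb[[population]], 25, 110),
    stringsAsFactors = FALSE
  ))
}

# corridor position (km north of the Skokomish estuary) of each line for a
# population; releases sit up-river (negative of the freshwater distance
# relative to their own river mouth)
line_positions <- function(population) {
  rm_pos <- c(BigBeefW = 51, SkokomishW = 0, SkokomishH = 0,
              DuckabushH = 49.4)
  geom <- default_geometry(population)$segments
  pos <- c(RM = rm_pos[[population]], HCB = 75, ADM = 100, JDF = 210)
  c(PR = pos[["RM"]] - geom$distance_km[1], pos)
}

#' Default receiver deployment table
#'
#' One or two receivers per river mouth, 7 on the Hood Canal Bridge line,
#' 13 across Admiralty Inlet, 31 across the Strait of Juan de Fuca, plus
#' behavioral receivers spread through Hood Canal that carry no encounter
#' occasion.
#'
#' @param behavioral_positions_km corridor positions of behavioral receivers
#' @return a [receiver_lines()] table
#' @export
default_receivers <- function(behavioral_positions_km = seq(10, 70, by = 10)) {
  mk <- function(prefix, line, n, pos, occ) {
    data.frame(receiver_id = sprintf("%s-%02d", prefix, seq_len(n)),
               line_id = line, corridor_position_km = pos, occasion = occ,
               stringsAsFactors = FALSE)
  }
  rbind(
    mk("RMBB", "RM-BigBeef", 2, 51, 1L),
    mk("RMSK", "RM-Skokomish", 2, 0, 1L),
    mk("RMDU", "RM-Duckabush", 1, 49.4, 1L),
    mk("HCB", "HCB", 7, 75, 2L),
    mk("ADM", "ADM", 13, 100, 3L),
    mk("JDF", "JDF", 31, 210, 4L),
    mk("HCBEH", "HC-behavior", length(behavioral_positions_km),
       behavioral_positions_km, NA_integer_)
  ) |> receiver_lines()
}

# the river-mouth line a population's fish pass on occasion 1
rm_line_for <- function(population) {
  c(BigBeefW = "RM-BigBeef", SkokomishW = "RM-Skokomish",
    SkokomishH = "RM-Skokomish", DuckabushH = "RM-Duckabush")[population]
}
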