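#' @keywords internal
"_PACKAGE"

POPULATIONS <- c("BigBeefW", "SkokomishW", "SkokomishH", "DuckabushH")
OCCASION_LINES <- c("RM", "HCB", "ADM", "JDF")
SEGMENT_NAMES <- c("PR-RM", "RM-HCB", "HCB-ADM", "ADM-JDF")

#' Fulton condition factor
#'
#' Body-condition index K = 1e5 * weight / length^3 for weight in grams and
#' fork length in millimetres. The 1e5 scaling puts typical smolt values near
#' 0.9-1.0.
#'
#' @param weight_g body weight in grams (> 0)
#' @param fork_length_mm fork length in millimetres (> 0)
#' @return numeric condition factor(s)
#' @examples
#' compute_condition_factor(57.6, 183)
#' @export
compute_condition_factor <- function(weight_g, fork_length_mm) {
  if (any(weight_g <= 0) || any(fork_length_mm <= 0)) {
    stop("weight_g and fork_length_mm must be positive", call. = FALSE)
  }
  1e5 * weight_g / fork_length_mm^3
}

population_origin <- function(population) {
  ifelse(population %in% c("BigBeefW", "SkokomishW"), "wild", "hatchery")
}

#' Construct a table of tagged-fish records
#'
#' Validates and types a cohort of tagged smolts. Each row is one fish with
#' its biological covariates and release metadata.
#'
#' @param df data.frame with columns `fish_id`, `population`, `year`,
#'   `fork_length_mm`, `weight_g`, `smolt_index`, `release_date`
#'   (day-of-year), `release_site`. `origin` and `condition_factor` are
#'   derived if absent.
#' @return a validated `fish_records` data.frame
#' @export
fish_records <- function(df) {
  req <- c("fish_id", "population", "year", "fork_length_mm", "weight_g",
           "smolt_index", "release_date", "release_site")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("fish table is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df$fish_id <- as.character(df$fish_id)
  if (anyDuplicated(df$fish_id)) {
    stop("duplicate fish_id: ",
         paste(unique(df$fish_id[duplicated(df$fish_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad_pop <- setdiff(unique(df$population), POPULATIONS)
  if (length(bad_pop)) {
    stop("unknown population(s): ", paste(bad_pop, collapse = ", "), call. = FALSE)
  }
  if (!all(df$smolt_index %in% 1:3)) {
    stop("smolt_index must be in {1, 2, 3}", call. = FALSE)
  }
  if (any(df$fork_length_mm <= 0) || any(df$weight_g <= 0)) {
    stop("fork_length_mm and weight_g must be positive", call. = FALSE)
  }
  df$origin <- population_origin(df$population)
  df$condition_factor <- compute_condition_factor(df$weight_g, df$fork_length_mm)
  df$year <- as.integer(df$year)
  df$smolt_index <- as.integer(df$smolt_index)
  class(df) <- c("fish_records", "data.frame")
  df
}

#' Construct a receiver-line table
#'
#' @param df data.frame with columns `receiver_id`, `line_id`,
#'   `corridor_position_km` and `occasion` (integer encounter-occasion index
#'   for the main survival lines, NA for behavioral receivers).
#' @return a validated `receiver_lines` data.frame
#' @export
receiver_lines <- function(df) {
  req <- c("receiver_id", "line_id", "corridor_position_km", "occasion")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("receiver table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$receiver_id <- as.character(df$receiver_id)
  if (anyDuplicated(df$receiver_id)) {
    stop("receiver_id assigned to more than one line", call. = FALSE)
  }
  occ <- df[!is.na(df$occasion), ]
  if (nrow(occ)) {
    # occasion order must follow corridor position (seaward = increasing)
    med <- tapply(occ$corridor_position_km, occ$occasion, stats::median)
    if (is.unsorted(med[order(as.integer(names(med)))], strictly = FALSE)) {
      stop("occasion-bearing lines must be ordered by corridor position",
           call. = FALSE)
    }
  }
  class(df) <- c("receiver_lines", "data.frame")
  df
}

#' Construct a detection-event table
#'
#' @param df data.frame with columns `fish_id`, `receiver_id`, `timestamp`
#'   (days since the run epoch).
#' @param receivers optional `receiver_lines` table; if given, every
#'   `receiver_id` must exist in it.
#' @return a validated `detection_events` data.frame
#' @export
detection_events <- function(df, receivers = NULL) {
  req <- c("fish_id", "receiver_id", "timestamp")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("event table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$fish_id <- as.character(df$fish_id)
  df$receiver_id <- as.character(df$receiver_id)
  if (!is.null(receivers)) {
    unknown <- setdiff(unique(df$receiver_id), receivers$receiver_id)
    if (length(unknown)) {
      stop("events reference unknown receiver(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  class(df) <- c("detection_events", "data.frame")
  df
}

#' Per-population migration segment geometry
#'
#' Ordered, contiguous corridor segments with between-line distances d_s in
#' kilometres. Segment s runs from `from_line` to `to_line`; the first
#' segment starts at the point of release (PR).
#'
#' @param population population the geometry applies to
#' @param segments data.frame with columns `from_line`, `to_line`,
#'   `distance_km`
#' @return a `segment_geometry` object
#' @export
segment_geometry <- function(population, segments) {
  stopifnot(all(c("from_line", "to_line", "distance_km") %in% names(segments)))
  if (any(segments$distance_km <= 0)) {
    stop("segment distances must be positive", call. = FALSE)
  }
  n <- nrow(segments)
  if (n > 1 && !all(segments$to_line[-n] == segments$from_line[-1])) {
    stop("segments must be contiguous", call. = FALSE)
  }
  structure(list(population = population, segments = segments),
            class = "segment_geometry")
}

#' @export
print.segment_geometry <- function(x, ...) {
  cat("Segment geometry for", x$population, "\n")
  print(x$segments)
  invisible(x)
}

#' Encounter-history set
#'
#' A binary detection matrix over occasions. Column 1 is the release
#' occasion and is always 1; remaining columns follow the ordered receiver
#' lines. Row names are fish ids; `records` carries the matching covariates.
#'
#' @param history integer matrix (n x T+1) of 0/1 with first column all 1
#' @param records `fish_records` aligned with the rows of `history`
#' @param occasion_names names of the detection occasions (length T)
#' @return an `encounter_histories` object
#' @export
encounter_histories <- function(history, records,
                                occasion_names = OCCASION_LINES) {
  history <- as.matrix(history)
  storage.mode(history) <- "integer"
  if (!all(history %in% c(0L, 1L))) stop("histories must be 0/1", call. = FALSE)
  if (!all(history[, 1] == 1L)) {
    stop("release occasion (column 1) must be 1 for every fish", call. = FALSE)
  }
  if (nrow(history) != nrow(records)) {
    stop("history rows and records rows differ", call. = FALSE)
  }
  colnames(history) <- c("release", occasion_names)
  rownames(history) <- records$fish_id
  structure(list(history = history, records = records,
                 occasions = occasion_names),
            class = "encounter_histories")
}

#' @export
print.encounter_histories <- function(x, ...) {
  cat(nrow(x$history), "encounter histories over occasions:",
      paste(colnames(x$history), collapse = " "), "\n")
  tab <- table(apply(x$history, 1, paste, collapse = ""))
  print(utils::head(sort(tab, decreasing = TRUE), 10))
  invisible(x)
}

history_strings <- function(eh) apply(eh$history, 1, paste, collapse = "")
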