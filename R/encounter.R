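# Collapse raw detection events into CJS encounter histories and compute
# per-fish migration behavior metrics. Occasion collapse uses presence
# only: multiplicity and residence time at a line are ignored, and
# behavioral (non-occasion) receivers never enter a history.

#' Build encounter histories from detection events
#'
#' `history[, k+1] = 1` iff the fish logged at least one event on any
#' receiver of occasion line k. Every released fish yields a history
#' (all-zero beyond release if never detected). Events timestamped before a
#' fish's release are an integrity error, not clipped.
#'
#' @param events [detection_events()]
#' @param fish [fish_records()]
#' @param receivers [receiver_lines()] with occasion indices
#' @return an [encounter_histories()] object
#' @export
build_encounter_histories <- function(events, fish, receivers) {
  occ <- receivers$occasion[match(events$receiver_id, receivers$receiver_id)]
  if (anyNA(occ) && any(is.na(occ) & !events$receiver_id %in%
                          receivers$receiver_id)) {
    stop("events reference unknown receivers", call. = FALSE)
  }
  if ("release_time" %in% names(fish)) {
    rel <- fish$release_time[match(events$fish_id, fish$fish_id)]
    if (any(events$timestamp < rel - 1e-9, na.rm = TRUE)) {
      stop("detection before release", call. = FALSE)
    }
  }
  T_occ <- max(receivers$occasion, na.rm = TRUE)
  h <- matrix(0L, nrow(fish), T_occ + 1L)
  h[, 1] <- 1L
  keep <- !is.na(occ)
  fi <- match(events$fish_id[keep], fish$fish_id)
  if (anyNA(fi)) stop("events reference unknown fish", call. = FALSE)
  h[cbind(fi, occ[keep] + 1L)] <- 1L
  encounter_histories(h, fish,
                      occasion_names = OCCASION_LINES[seq_len(T_occ)])
}

first_time_at <- function(events, receiver_ids) {
  e <- events[events$receiver_id %in% receiver_ids, ]
  if (!nrow(e)) return(stats::setNames(numeric(0), character(0)))
  tapply(e$timestamp, e$fish_id, min)
}

#' Per-fish travel rate between two corridor points
#'
#' distance / (first detection at the destination line minus the reference
#' time at the origin). The origin may be `"release"` (reference time =
#' release timestamp) or a line id (reference time = first detection
#' there). Fish missing either bounding time get NA, never zero.
#'
#' @param events [detection_events()]
#' @param fish [fish_records()]
#' @param receivers [receiver_lines()]
#' @param from `"release"` or a `line_id`
#' @param to a `line_id`
#' @param distance_km corridor distance between the bounding points
#' @return named numeric vector of km/day, one entry per fish
#' @export
travel_rate <- function(events, fish, receivers, from, to, distance_km) {
  stopifnot(distance_km > 0)
  t_to <- first_time_at(events,
                        receivers$receiver_id[receivers$line_id == to])
  if (identical(from, "release")) {
    t_from <- stats::setNames(fish$release_time, fish$fish_id)
  } else {
    t_from <- first_time_at(events,
                            receivers$receiver_id[receivers$line_id == from])
  }
  out <- stats::setNames(rep(NA_real_, nrow(fish)), fish$fish_id)
  common <- intersect(names(t_to), names(t_from))
  common <- common[t_to[common] > t_from[common]]
  out[common] <- distance_km / (t_to[common] - t_from[common])
  out
}

#' Per-fish migration range
#'
#' Corridor distance from the estuary reference position to the
#' northernmost receiver at which the fish was ever detected (behavioral
#' receivers count). Fish never detected get NA; fish detected only at the
#' estuary get 0.
#'
#' @param events [detection_events()]
#' @param fish [fish_records()]
#' @param receivers [receiver_lines()]
#' @param estuary_position_km corridor position of the estuary reference
#'   (default 0, the Skokomish river mouth)
#' @return named numeric vector of km, one entry per fish
#' @export
migration_range <- function(events, fish, receivers, estuary_position_km = 0) {
  pos <- receivers$corridor_position_km[match(events$receiver_id,
                                              receivers$receiver_id)]
  if (anyNA(pos)) stop("corridor position unknown for some receiver",
                       call. = FALSE)
  far <- tapply(pos, events$fish_id, max)
  out <- stats::setNames(rep(NA_real_, nrow(fish)), fish$fish_id)
  out[names(far)] <- pmax(far - estuary_position_km, 0)
  out
}

#' Per-receiver detection density table
#'
#' For a subset of fish, counts distinct fish detected at each receiver of
#' the named lines and the proportion of all fish (in the subset) with at
#' least one detection in the region.
#'
#' @param events [detection_events()]
#' @param fish_ids fish subset
#' @param receivers [receiver_lines()]
#' @param region_lines line ids defining the region (default: everything
#'   south of Admiralty Inlet, i.e. Hood Canal lines)
#' @return data.frame `receiver_id`, `corridor_position_km`,
#'   `n_detected_fish`, `proportion_of_detected`
#' @export
density_table <- function(events, fish_ids, receivers,
                          region_lines = c("RM-Skokomish", "RM-BigBeef",
                                           "RM-Duckabush", "HC-behavior",
                                           "HCB")) {
  reg <- receivers[receivers$line_id %in% region_lines, ]
  e <- events[events$fish_id %in% fish_ids &
                events$receiver_id %in% reg$receiver_id, ]
  if (!nrow(e)) {
    return(data.frame(receiver_id = character(),
                      corridor_position_km = numeric(),
                      n_detected_fish = integer(),
                      proportion_of_detected = numeric()))
  }
  n_detected <- length(unique(e$fish_id))
  counts <- tapply(e$fish_id, e$receiver_id, function(x) length(unique(x)))
  data.frame(
    receiver_id = names(counts),
    corridor_position_km = reg$corridor_position_km[
      match(names(counts), reg$receiver_id)],
    n_detected_fish = as.integer(counts),
    proportion_of_detected = as.numeric(counts) / n_detected,
    row.names = NULL, stringsAsFactors = FALSE)
}
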