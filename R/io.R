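# Delimited-text IO. One canonical schema: comma-separated, header row,
# UTF-8. Readers enforce the type invariants; writers emit exactly the
# columns the readers require, so write -> read is the identity.

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(basename(path), " is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read the three input tables
#'
#' Reads the fish, receiver and detection-event CSV files and returns typed,
#' validated tables. Events are checked referentially against the receiver
#' table and against per-fish release times when available.
#'
#' @param fish_path,receivers_path,events_path CSV file paths
#' @return list with elements `fish`, `receivers`, `events`
#' @export
read_tables <- function(fish_path, receivers_path, events_path) {
  fish <- fish_records(read_checked_csv(
    fish_path, c("fish_id", "population", "year", "fork_length_mm",
                 "weight_g", "smolt_index", "release_date", "release_site")))
  receivers <- receiver_lines(read_checked_csv(
    receivers_path, c("receiver_id", "line_id", "corridor_position_km",
                      "occasion")))
  events <- detection_events(read_checked_csv(
    events_path, c("fish_id", "receiver_id", "timestamp")), receivers)
  unknown_fish <- setdiff(unique(events$fish_id), fish$fish_id)
  if (length(unknown_fish)) {
    stop("events reference unknown fish: ",
         paste(unknown_fish, collapse = ", "), call. = FALSE)
  }
  if ("release_time" %in% names(fish)) {
    rel <- fish$release_time[match(events$fish_id, fish$fish_id)]
    bad <- which(events$timestamp < rel)
    if (length(bad)) {
      stop("detections before release for fish ",
           paste(unique(events$fish_id[bad]), collapse = ", "),
           " (event rows ", paste(utils::head(bad, 5), collapse = ", "), ")",
           call. = FALSE)
    }
  }
  list(fish = fish, receivers = receivers, events = events)
}

#' Write the three input tables
#'
#' @param tables list with `fish`, `receivers`, `events` as returned by
#'   [read_tables()] or [simulate_dataset()]
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fish = file.path(dir, "fish.csv"),
             receivers = file.path(dir, "receivers.csv"),
             events = file.path(dir, "events.csv"))
  utils::write.csv(as.data.frame(tables$fish), paths["fish"], row.names = FALSE)
  utils::write.csv(as.data.frame(tables$receivers), paths["receivers"],
                   row.names = FALSE)
  utils::write.csv(as.data.frame(tables$events), paths["events"],
                   row.names = FALSE)
  invisible(paths)
}

#' Export encounter histories in MARK .inp dialect
#'
#' One line per unique (history, group) combination: the history string,
#' one frequency column per group level, and a terminating semicolon.
#'
#' @param eh `encounter_histories`
#' @param grouping name of a column of `eh$records` to group frequencies by,
#'   or NULL for a single frequency column
#' @param path optional file to write; if NULL the lines are returned
#' @return character vector of .inp lines, invisibly when `path` is given
#' @export
write_inp <- function(eh, grouping = NULL, path = NULL) {
  hs <- history_strings(eh)
  if (is.null(grouping)) {
    grp <- factor(rep("all", length(hs)))
  } else {
    if (!grouping %in% names(eh$records)) {
      stop("grouping column not found: ", grouping, call. = FALSE)
    }
    grp <- factor(eh$records[[grouping]])
  }
  tab <- table(history = hs, group = grp)
  lines <- vapply(seq_len(nrow(tab)), function(i) {
    paste(rownames(tab)[i], paste(tab[i, ], collapse = " "), ";")
  }, character(1))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
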