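#' Construct a burst table
#'
#' A burst table is the in-memory form of an electrode burst list: one row
#' per detected burst, with the electrode token, burst start time (s), burst
#' size (spikes) and burst duration (s), plus plate metadata carried as
#' attributes. Rows are stable-sorted by (electrode, start time) and all
#' electrodes must belong to wells present in the layout.
#'
#' @param records A data frame with columns `electrode`, `time_s`,
#'   `size_spikes`, `duration_s`.
#' @param recording_id Free-text identifier for the recording.
#' @param layout A [plate_layout()].
#' @param recording_length_s Total recording length in seconds, or `NA` if
#'   unknown.
#' @return A tibble of class `burst_table` with columns `electrode`, `well`,
#'   `elec_col`, `elec_row`, `time_s`, `size_spikes`, `duration_s`.
#' @export
burst_table <- function(records, recording_id = "", layout = plate_layout(),
                        recording_length_s = NA_real_) {
  records <- tibble::as_tibble(records)
  needed <- c("electrode", "time_s", "size_spikes", "duration_s")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    stop("burst_table(): missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(records) > 0) {
    ids <- parse_electrode_id(records$electrode, layout$electrodes_per_side)
    records$electrode <- ids$electrode
    records$well <- ids$well
    records$elec_col <- ids$elec_col
    records$elec_row <- ids$elec_row
  } else {
    records$well <- character(0)
    records$elec_col <- integer(0)
    records$elec_row <- integer(0)
  }
  records$time_s <- as.double(records$time_s)
  records$size_spikes <- as.integer(records$size_spikes)
  records$duration_s <- as.double(records$duration_s)
  records <- records[, c("electrode", "well", "elec_col", "elec_row",
                         "time_s", "size_spikes", "duration_s")]
  if (any(records$time_s < 0)) {
    stop("burst_table(): negative burst start times")
  }
  if (any(records$size_spikes < 1)) {
    stop("burst_table(): burst sizes must be >= 1 spike")
  }
  if (any(records$duration_s < 0)) {
    stop("burst_table(): negative burst durations")
  }
  if (any(records$duration_s == 0 & records$size_spikes > 1)) {
    stop("burst_table(): zero duration is only valid for single-spike records")
  }
  bad_wells <- setdiff(unique(records$well), plate_wells(layout))
  if (length(bad_wells) > 0) {
    stop("burst_table(): electrodes from wells absent in layout: ",
         paste(bad_wells, collapse = ", "))
  }
  records <- records[order(records$electrode, records$time_s,
                           method = "radix"), ]
  structure(
    records,
    recording_id = recording_id,
    layout = layout,
    recording_length_s = recording_length_s,
    class = c("burst_table", class(tibble::tibble()))
  )
}

#' @export
print.burst_table <- function(x, ...) {
  cat(sprintf("<burst_table> %d bursts, %d electrodes, recording '%s'\n",
              nrow(x), dplyr::n_distinct(x$electrode),
              attr(x, "recording_id")))
  NextMethod()
}

#' Plate layout of a burst table
#' @param table A [burst_table()].
#' @return The [plate_layout()] attached to the table.
#' @export
table_layout <- function(table) {
  stopifnot(inherits(table, "burst_table"))
  attr(table, "layout")
}
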