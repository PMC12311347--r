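#' Detect single-electrode bursts with an ISI-threshold rule
#'
#' A burst is a maximal run of consecutive spikes in which every inter-spike
#' interval (ISI) is at most `max_isi_s`, retained only if the run contains
#' at least `min_spikes` spikes. The defaults (5 spikes, 100 ms) are the
#' standard AxIS single-electrode burst definition. An ISI exactly equal to
#' `max_isi_s` joins the burst. The burst start time is the first spike
#' time; the duration is last minus first spike time.
#'
#' @param times_s Strictly increasing spike timestamps in seconds.
#' @param min_spikes Minimum spikes per burst (default 5).
#' @param max_isi_s Maximum within-burst ISI in seconds (default 0.1).
#' @return A tibble with columns `time_s` (burst start), `size_spikes`,
#'   `duration_s`, one row per burst in temporal order. Empty input gives
#'   zero rows.
#' @examples
#' detect_bursts(c(0, 0.01, 0.02, 0.03, 0.04))
#' @export
detect_bursts <- function(times_s, min_spikes = 5L, max_isi_s = 0.1) {
  stopifnot(min_spikes >= 2, max_isi_s > 0)
  empty <- tibble::tibble(time_s = double(0), size_spikes = integer(0),
                          duration_s = double(0))
  n <- length(times_s)
  if (n == 0) return(empty)
  if (any(is.na(times_s)) || any(times_s < 0)) {
    stop("detect_bursts(): spike times must be non-negative and non-missing")
  }
  if (n > 1 && any(diff(times_s) <= 0)) {
    stop("detect_bursts(): spike times must be strictly increasing")
  }
  if (n < min_spikes) return(empty)

  # runs of spikes linked by ISI <= threshold; run of m linked gaps = m+1
  # spikes. The boundary is inclusive; the epsilon keeps grid-aligned
  # timestamps (e.g. multiples of 1/12500 s summing to exactly 0.1) from
  # falling out of a burst through floating-point representation error.
  linked <- diff(times_s) <= max_isi_s + 1e-12
  r <- rle(linked)
  gap_end <- cumsum(r$lengths)
  gap_start <- gap_end - r$lengths + 1L
  keep <- r$values & (r$lengths + 1L >= min_spikes)
  if (!any(keep)) return(empty)
  first <- gap_start[keep]          # spike index of run start
  last <- gap_end[keep] + 1L        # spike index of run end
  tibble::tibble(
    time_s = times_s[first],
    size_spikes = last - first + 1L,
    duration_s = times_s[last] - times_s[first]
  )
}

#' Detect bursts on every electrode of a spike-train set
#'
#' Applies [detect_bursts()] per electrode and assembles the results into a
#' [burst_table()] with the same shape as an AxIS electrode burst list.
#'
#' @param spikes A tibble with columns `electrode` and `time_s` (one row per
#'   spike), as returned by [read_spike_times()] or
#'   [simulate_spike_trains()].
#' @param min_spikes,max_isi_s Burst definition, see [detect_bursts()].
#' @param recording_id,layout,recording_length_s Metadata for the resulting
#'   table.
#' @return A [burst_table()].
#' @export
detect_bursts_table <- function(spikes, min_spikes = 5L, max_isi_s = 0.1,
                                recording_id = "", layout = plate_layout(),
                                recording_length_s = NA_real_) {
  stopifnot(all(c("electrode", "time_s") %in% names(spikes)))
  per <- lapply(split(spikes$time_s, spikes$electrode), function(t) {
    detect_bursts(sort(t), min_spikes = min_spikes, max_isi_s = max_isi_s)
  })
  recs <- dplyr::bind_rows(per, .id = "electrode")
  if (nrow(recs) == 0) {
    recs <- tibble::tibble(electrode = character(0), time_s = double(0),
                           size_spikes = integer(0), duration_s = double(0))
  }
  burst_table(recs, recording_id = recording_id, layout = layout,
              recording_length_s = recording_length_s)
}

#' Read spike timestamps from CSV
#'
#' Expects a two-column CSV with header `Electrode,Time (s)` (same header
#' conventions as the burst list reader). Rows are sorted per electrode;
#' duplicate timestamps on one electrode and negative times are rejected.
#'
#' @param source Path to a CSV file or a character vector of CSV lines.
#' @param dialect An [axis_dialect()] supplying electrode/time aliases.
#' @return A tibble with columns `electrode`, `time_s`, sorted by
#'   (electrode, time).
#' @export
read_spike_times <- function(source, dialect = axis_dialect()) {
  if (length(source) == 1 && file.exists(source)) {
    lines <- readr::read_lines(source)
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE))
  }
  if (length(lines) == 0 || all(trimws(lines) == "")) {
    stop("read_spike_times(): empty input")
  }
  raw <- readr::read_csv(I(paste(lines, collapse = "\n")),
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  norm <- normalize_header(names(raw))
  e_idx <- which(norm %in% normalize_header(dialect$electrode))[1]
  t_idx <- which(norm %in% normalize_header(dialect$time))[1]
  if (is.na(e_idx) || is.na(t_idx)) {
    stop("read_spike_times(): need electrode and time columns; found: ",
         paste(names(raw), collapse = ", "))
  }
  electrode <- parse_electrode_id(raw[[e_idx]])$electrode
  time_s <- suppressWarnings(as.double(raw[[t_idx]]))
  if (any(is.na(time_s))) {
    stop("read_spike_times(): unparseable time values in data row(s): ",
         paste(which(is.na(time_s)), collapse = ", "))
  }
  if (any(time_s < 0)) {
    stop("read_spike_times(): negative spike times")
  }
  out <- tibble::tibble(electrode = electrode, time_s = time_s)
  out <- out[order(out$electrode, out$time_s, method = "radix"), ]
  dup <- duplicated(out)
  if (any(dup)) {
    stop("read_spike_times(): duplicate (electrode, time) pairs, e.g. ",
         out$electrode[which(dup)[1]], " @ ", out$time_s[which(dup)[1]], " s")
  }
  out
}
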