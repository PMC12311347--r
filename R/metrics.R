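#' Labelled analysis time windows
#'
#' A time window is the half-open interval `[t0_s, t1_s)`; a burst belongs
#' to the window containing its start time, so consecutive windows partition
#' a recording without double counting.
#'
#' @param label Window label(s) used in outputs and plots.
#' @param t0_s,t1_s Window bounds in seconds, `t1_s > t0_s`.
#' @return A tibble with columns `label`, `t0_s`, `t1_s`.
#' @examples
#' time_windows(c("baseline", "KCl"), c(0, 120), c(120, 240))
#' @export
time_windows <- function(label, t0_s, t1_s) {
  stopifnot(length(label) == length(t0_s), length(t0_s) == length(t1_s))
  t0_s <- as.double(t0_s)
  t1_s <- as.double(t1_s)
  if (any(is.na(t0_s)) || any(is.na(t1_s)) || any(t1_s <= t0_s)) {
    stop("time_windows(): need t1_s > t0_s for every window")
  }
  label <- as.character(label)
  if (anyDuplicated(label)) {
    stop("time_windows(): duplicate window labels")
  }
  tibble::tibble(label = label, t0_s = t0_s, t1_s = t1_s)
}

#' Read a windows configuration file
#'
#' Accepts YAML or JSON holding a list of `{label, t0_s, t1_s}` entries.
#'
#' @param path Path to the config file (`.yaml`, `.yml` or `.json`).
#' @return A [time_windows()] tibble.
#' @export
read_windows <- function(path) {
  if (!file.exists(path)) stop("read_windows(): no such file: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.list(cfg) && !is.null(cfg$windows)) cfg <- cfg$windows
  if (length(cfg) == 0) stop("read_windows(): no windows in ", path)
  time_windows(
    label = vapply(cfg, function(w) as.character(w$label), ""),
    t0_s = vapply(cfg, function(w) as.double(w$t0_s), 0),
    t1_s = vapply(cfg, function(w) as.double(w$t1_s), 0)
  )
}

#' Filter a burst table to one time window
#'
#' Retains exactly the bursts whose start time lies in `[t0_s, t1_s)`;
#' table metadata is preserved.
#'
#' @param table A [burst_table()].
#' @param window A single-row [time_windows()] tibble (or a list with
#'   `t0_s` and `t1_s`).
#' @return A [burst_table()] with the retained records.
#' @export
filter_window <- function(table, window) {
  stopifnot(inherits(table, "burst_table"))
  if (is.data.frame(window) && nrow(window) != 1) {
    stop("filter_window(): exactly one window expected")
  }
  keep <- table$time_s >= window$t0_s & table$time_s < window$t1_s
  out <- table[keep, ]
  attributes(out)[c("recording_id", "layout", "recording_length_s")] <-
    attributes(table)[c("recording_id", "layout", "recording_length_s")]
  class(out) <- class(table)
  out
}

#' Mean within-burst inter-spike interval
#'
#' For a burst of `size_spikes` spikes spanning `duration_s` seconds the
#' mean ISI is `duration_s / (size_spikes - 1)`: the duration divided by the
#' number of intervals. The electrode-level "mean burst ISI" parameter is
#' the arithmetic mean of this quantity over bursts, not the ratio of mean
#' duration to mean size.
#'
#' @param duration_s Burst duration(s) in seconds.
#' @param size_spikes Burst size(s) in spikes, at least 2.
#' @return Mean ISI in seconds.
#' @examples
#' mean_burst_isi(0.09216, 17) # 0.00576
#' @export
mean_burst_isi <- function(duration_s, size_spikes) {
  if (any(size_spikes < 2)) {
    stop("mean_burst_isi(): size_spikes must be >= 2 (a burst of one spike ",
         "has no ISI)")
  }
  duration_s / (size_spikes - 1)
}

#' Single-electrode burst parameters for labelled time windows
#'
#' Computes, per electrode and window, the four burst parameters: number of
#' bursts, mean burst duration, mean spikes per burst and mean within-burst
#' ISI (see [mean_burst_isi()]). Electrodes with no in-window bursts get
#' `n_bursts = 0` and `NA` means -- never zeros.
#'
#' @param table A [burst_table()].
#' @param windows A [time_windows()] tibble (one or more rows).
#' @param electrodes Electrode tokens to report. Defaults to the electrodes
#'   present in `table`; pass an explicit vector (e.g. from
#'   [plate_electrodes()]) to include silent electrodes.
#' @return A tibble with one row per (electrode, window): `electrode`,
#'   `well`, `elec_col`, `elec_row`, `window`, `n_bursts`,
#'   `mean_duration_s`, `mean_spikes_per_burst`, `mean_burst_isi_s`.
#' @export
summarize_electrode <- function(table, windows, electrodes = NULL) {
  stopifnot(inherits(table, "burst_table"))
  if (is.null(electrodes)) electrodes <- sort(unique(table$electrode))
  if (length(electrodes) == 0) {
    stop("summarize_electrode(): no electrodes to summarize")
  }
  ids <- parse_electrode_id(electrodes,
                            table_layout(table)$electrodes_per_side)
  per_window <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    sub <- filter_window(table, w)
    sub <- sub[sub$electrode %in% ids$electrode, ]
    agg <- dplyr::summarise(
      dplyr::group_by(tibble::as_tibble(sub), electrode),
      n_bursts = dplyr::n(),
      mean_duration_s = mean(duration_s),
      mean_spikes_per_burst = mean(size_spikes),
      mean_burst_isi_s = mean(mean_burst_isi(duration_s, size_spikes)),
      .groups = "drop"
    )
    out <- dplyr::left_join(ids, agg, by = "electrode")
    out$n_bursts[is.na(out$n_bursts)] <- 0L
    out$window <- w$label
    out
  })
  out <- dplyr::bind_rows(per_window)
  out[, c("electrode", "well", "elec_col", "elec_row", "window", "n_bursts",
          "mean_duration_s", "mean_spikes_per_burst", "mean_burst_isi_s")]
}

sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

#' Whole-well burst parameters with SEM across electrodes
#'
#' Aggregates single-electrode parameters to the well level. Burst counts
#' average over all electrodes of the well (inactive electrodes contribute
#' 0 bursts when `count_inactive = TRUE`, the default); the duration,
#' spikes-per-burst and mean-ISI parameters average over active electrodes
#' only, since they are undefined where no burst was detected. SEM is the
#' sample (n-1) standard deviation over the contributing electrode values
#' divided by sqrt(n).
#'
#' @param table A [burst_table()].
#' @param wells Well labels to summarize; default all wells of the layout
#'   that appear in `table`.
#' @param windows A [time_windows()] tibble.
#' @param count_inactive If `TRUE`, electrodes with no bursts enter the
#'   burst-count mean as zeros; if `FALSE`, counts too are averaged over
#'   active electrodes only.
#' @return A tibble with one row per (well, window, parameter): columns
#'   `well`, `window`, `parameter`, `mean`, `sem`, `n_electrodes`,
#'   `n_electrodes_active`.
#' @export
summarize_well <- function(table, windows, wells = NULL,
                           count_inactive = TRUE) {
  stopifnot(inherits(table, "burst_table"))
  layout <- table_layout(table)
  if (is.null(wells)) wells <- sort(unique(table$well))
  bad <- setdiff(wells, plate_wells(layout))
  if (length(bad) > 0) {
    stop("summarize_well(): wells absent from layout: ",
         paste(bad, collapse = ", "))
  }
  if (length(wells) == 0) stop("summarize_well(): no wells to summarize")
  electrodes <- plate_electrodes(layout, wells)$electrode
  es <- summarize_electrode(table, windows, electrodes = electrodes)
  params <- c("n_bursts", "mean_duration_s", "mean_spikes_per_burst",
              "mean_burst_isi_s")
  long <- tidyr::pivot_longer(es, dplyr::all_of(params),
                              names_to = "parameter", values_to = "value")
  long$value <- as.double(long$value)
  # counts: optionally keep zeros; other parameters: NA marks inactive
  drop <- (long$parameter == "n_bursts" & !count_inactive &
             long$value == 0) |
    (long$parameter != "n_bursts" & is.na(long$value))
  active <- dplyr::summarise(
    dplyr::group_by(es, well, window),
    n_electrodes = dplyr::n(),
    n_electrodes_active = sum(n_bursts > 0),
    .groups = "drop"
  )
  agg <- dplyr::summarise(
    dplyr::group_by(long[!drop, ], well, window, parameter),
    mean = mean(value),
    sem = sem(value),
    .groups = "drop"
  )
  out <- dplyr::left_join(
    tidyr::expand_grid(well = wells, window = windows$label,
                       parameter = params),
    agg, by = c("well", "window", "parameter")
  )
  out <- dplyr::left_join(out, active, by = c("well", "window"))
  out$parameter <- factor(out$parameter, levels = params)
  dplyr::arrange(out, well, window, parameter)
}

#' Compare electrode summaries against a reference metrics table
#'
#' Checks computed single-electrode parameters against a flat reference CSV
#' (or tibble) keyed by electrode token, with per-parameter absolute
#' differences judged at a tolerance. Electrodes present on only one side
#' are flagged, not fatal. Integer burst counts must match exactly to pass.
#'
#' @param summaries A tibble as produced by [summarize_electrode()] (the
#'   `window` column is optional).
#' @param reference A data frame, or path to a CSV, with columns
#'   `electrode`, `n_bursts`, `mean_duration_s`, `mean_spikes_per_burst`,
#'   `mean_burst_isi_s`.
#' @param tol Absolute tolerance for the three mean parameters (default
#'   1e-3, i.e. agreement to 3 decimal places).
#' @return A tibble with columns `electrode`, `parameter`, `value`,
#'   `reference`, `abs_diff`, `pass` (`NA` where a side is missing), with
#'   attribute `n_fail` for quick inspection.
#' @export
compare_with_reference <- function(summaries, reference, tol = 1e-3) {
  if (is.character(reference) && length(reference) == 1) {
    reference <- readr::read_csv(reference, show_col_types = FALSE,
                                 progress = FALSE)
  }
  reference <- tibble::as_tibble(reference)
  names(reference)[normalize_header(names(reference)) == "electrode"] <-
    "electrode"
  params <- c("n_bursts", "mean_duration_s", "mean_spikes_per_burst",
              "mean_burst_isi_s")
  missing_ref <- setdiff(params, names(reference))
  if (length(missing_ref) > 0) {
    stop("compare_with_reference(): reference lacks column(s): ",
         paste(missing_ref, collapse = ", "))
  }
  s_long <- tidyr::pivot_longer(
    summaries[, c("electrode", intersect(params, names(summaries)))],
    -electrode, names_to = "parameter", values_to = "value",
    values_transform = as.double
  )
  r_long <- tidyr::pivot_longer(
    reference[, c("electrode", params)],
    -electrode, names_to = "parameter", values_to = "reference",
    values_transform = as.double
  )
  out <- dplyr::full_join(s_long, r_long, by = c("electrode", "parameter"))
  out$abs_diff <- abs(out$value - out$reference)
  out$pass <- ifelse(
    is.na(out$value) | is.na(out$reference), NA,
    ifelse(out$parameter == "n_bursts",
           out$value == out$reference, out$abs_diff <= tol)
  )
  structure(dplyr::arrange(out, electrode, parameter),
            n_fail = sum(!out$pass, na.rm = TRUE))
}
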