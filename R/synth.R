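#' Parameters for the synthetic spike-train generator
#'
#' Describes a seeded generative model of per-electrode bursty spike trains
#' on a multi-well MEA plate. Each electrode emits a sequence of bursts:
#' burst sizes are shifted Poisson (minimum `min_spikes`, mean
#' `size_mean`), within-burst ISIs are log-normal (median `isi_median_s`,
#' log-sd `isi_sigma`) truncated to lie strictly inside `(0, max_isi_s)`,
#' and inter-burst gaps are exponential above a floor `gap_floor_s` that
#' exceeds `max_isi_s`. The two truncations guarantee that the ISI-threshold
#' detector recovers every generated burst exactly (never split, never
#' merged), even after timestamps are quantized to the acquisition sampling
#' grid (`sample_rate_hz`). Defaults emulate a 24-well plate with 16
#' electrodes per well, a 10-minute recording in 2-minute windows, and
#' burst parameters in the ranges typical of mature hippocampal cultures
#' (durations 0.08--0.2 s, sizes 7--42 spikes, mean ISIs 4--29 ms).
#'
#' @param wells Well labels to simulate (default: all wells of `layout`).
#' @param layout A [plate_layout()].
#' @param recording_length_s Recording length in seconds.
#' @param windows A [time_windows()] tibble; default partitions the
#'   recording into 120 s windows.
#' @param burst_rate_per_min Baseline burst rate per electrode
#'   (bursts/minute); 0 gives silent trains.
#' @param size_mean Mean burst size in spikes (shifted Poisson).
#' @param isi_median_s Median within-burst ISI in seconds.
#' @param isi_sigma Log-sd of the within-burst ISI distribution.
#' @param gap_floor_s Minimum inter-burst gap in seconds; must exceed
#'   `max_isi_s` by at least two sample periods.
#' @param min_spikes,max_isi_s Burst definition the fixture must satisfy.
#' @param silent_electrodes Electrode tokens that emit no spikes.
#' @param modulation Optional named numeric vector of per-window burst-rate
#'   multipliers, names matching window labels (e.g. a KCl-like transient:
#'   `c(w2 = 2)`).
#' @param sample_rate_hz Acquisition sampling rate; timestamps are
#'   quantized to this grid.
#' @param seed Integer seed; one global seed expands to per-electrode
#'   substreams by stable hashing of the electrode token, so adding
#'   electrodes never perturbs existing trains.
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(wells = NULL, layout = plate_layout(),
                         recording_length_s = 600,
                         windows = NULL,
                         burst_rate_per_min = 10,
                         size_mean = 20,
                         isi_median_s = 0.008,
                         isi_sigma = 0.6,
                         gap_floor_s = 0.2,
                         min_spikes = 5L,
                         max_isi_s = 0.1,
                         silent_electrodes = character(0),
                         modulation = NULL,
                         sample_rate_hz = 12500,
                         seed = 1L) {
  if (is.null(wells)) wells <- plate_wells(layout)
  if (is.null(windows)) {
    edges <- seq(0, recording_length_s, by = 120)
    if (edges[length(edges)] < recording_length_s) {
      edges <- c(edges, recording_length_s)
    }
    windows <- time_windows(paste0("w", seq_len(length(edges) - 1)),
                            edges[-length(edges)], edges[-1])
  }
  p <- structure(
    list(wells = wells, layout = layout,
         recording_length_s = recording_length_s, windows = windows,
         burst_rate_per_min = burst_rate_per_min, size_mean = size_mean,
         isi_median_s = isi_median_s, isi_sigma = isi_sigma,
         gap_floor_s = gap_floor_s, min_spikes = as.integer(min_spikes),
         max_isi_s = max_isi_s,
         silent_electrodes = silent_electrodes,
         modulation = modulation, sample_rate_hz = sample_rate_hz,
         seed = as.integer(seed)),
    class = "synth_params"
  )
  validate_synth_params(p)
  p
}

validate_synth_params <- function(p) {
  dt <- 1 / p$sample_rate_hz
  if (p$isi_median_s >= p$max_isi_s - 2 * dt) {
    stop("synth_params(): isi_median_s must sit below max_isi_s minus two ",
         "sample periods, or generated bursts would not survive detection")
  }
  if (p$gap_floor_s <= p$max_isi_s + 2 * dt) {
    stop("synth_params(): gap_floor_s must exceed max_isi_s by more than ",
         "two sample periods, or adjacent bursts could merge under detection")
  }
  if (p$size_mean < p$min_spikes) {
    stop("synth_params(): size_mean must be at least min_spikes")
  }
  if (p$burst_rate_per_min < 0 || p$recording_length_s <= 0) {
    stop("synth_params(): negative rate or non-positive recording length")
  }
  if (!is.null(p$modulation)) {
    unknown <- setdiff(names(p$modulation), p$windows$label)
    if (length(unknown) > 0) {
      stop("synth_params(): modulation names not matching window labels: ",
           paste(unknown, collapse = ", "))
    }
  }
  invisible(p)
}

# deterministic 31-adic string hash into [0, 2^31 - 2]
stable_hash <- function(s) {
  M <- 2147483647
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% M
  h
}

rate_multiplier_at <- function(t, windows, modulation) {
  if (is.null(modulation)) return(1)
  i <- which(t >= windows$t0_s & t < windows$t1_s)
  if (length(i) == 0) return(1)
  m <- modulation[windows$label[i[1]]]
  if (is.na(m)) 1 else as.double(m)
}

# truncated log-normal sampler via inverse CDF (deterministic in the RNG)
rlnorm_trunc <- function(n, meanlog, sdlog, lo, hi) {
  p_lo <- stats::plnorm(lo, meanlog, sdlog)
  p_hi <- stats::plnorm(hi, meanlog, sdlog)
  stats::qlnorm(p_lo + stats::runif(n) * (p_hi - p_lo), meanlog, sdlog)
}

simulate_one_electrode <- function(p, electrode) {
  dt <- 1 / p$sample_rate_hz
  isi_lo <- 2 * dt
  isi_hi <- p$max_isi_s - 2 * dt
  gap_excess_mean <- max(60 / max(p$burst_rate_per_min, 1e-9) -
                           p$gap_floor_s, 0.01)
  set.seed(stable_hash(paste0(p$seed, ":", electrode)))
  bursts <- list()
  spike_times <- list()
  t <- 0
  if (p$burst_rate_per_min > 0) {
    repeat {
      m <- rate_multiplier_at(t, p$windows, p$modulation)
      gap <- p$gap_floor_s + stats::rexp(1, rate = m / gap_excess_mean)
      start <- t + gap
      if (start >= p$recording_length_s) break
      size <- p$min_spikes + stats::rpois(1, p$size_mean - p$min_spikes)
      isis <- rlnorm_trunc(size - 1, log(p$isi_median_s), p$isi_sigma,
                           isi_lo, isi_hi)
      raw <- start + cumsum(c(0, isis))
      q <- round(raw * p$sample_rate_hz) / p$sample_rate_hz
      if (q[length(q)] >= p$recording_length_s) break
      bursts[[length(bursts) + 1L]] <- c(
        start = q[1], size = size, duration = q[length(q)] - q[1])
      spike_times[[length(spike_times) + 1L]] <- q
      t <- raw[length(raw)]
    }
  }
  list(
    spikes = if (length(spike_times)) unlist(spike_times) else double(0),
    bursts = if (length(bursts)) {
      b <- do.call(rbind, bursts)
      tibble::tibble(time_s = b[, "start"],
                     size_spikes = as.integer(b[, "size"]),
                     duration_s = b[, "duration"])
    } else {
      tibble::tibble(time_s = double(0), size_spikes = integer(0),
                     duration_s = double(0))
    }
  )
}

#' Simulate bursty spike trains with known ground truth
#'
#' Draws spike trains for every electrode of the requested wells under the
#' generative model described in [synth_params()], and tabulates the exact
#' per-electrode, per-window ground truth (burst count, mean duration, mean
#' size, mean within-burst ISI) from the generated burst boundaries. The
#' output is bit-identical across calls with the same parameters and seed.
#'
#' @param params A [synth_params()] object.
#' @return A list with elements `spikes` (tibble: `electrode`, `time_s`),
#'   `truth` (tibble: one row per electrode x window with the four true
#'   parameters in the [summarize_electrode()] layout) and `params`.
#' @export
simulate_spike_trains <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  electrodes <- plate_electrodes(params$layout, params$wells)
  silent <- params$silent_electrodes
  if (length(silent) > 0) {
    silent <- parse_electrode_id(silent,
                                 params$layout$electrodes_per_side)$electrode
  }
  spike_rows <- list()
  truth_rows <- list()
  for (i in seq_len(nrow(electrodes))) {
    e <- electrodes$electrode[[i]]
    sim <- if (e %in% silent) {
      list(spikes = double(0),
           bursts = tibble::tibble(time_s = double(0),
                                   size_spikes = integer(0),
                                   duration_s = double(0)))
    } else {
      simulate_one_electrode(params, e)
    }
    if (length(sim$spikes) > 0) {
      spike_rows[[e]] <- tibble::tibble(electrode = e, time_s = sim$spikes)
    }
    b <- sim$bursts
    for (j in seq_len(nrow(params$windows))) {
      w <- params$windows[j, ]
      inw <- b[b$time_s >= w$t0_s & b$time_s < w$t1_s, ]
      truth_rows[[paste(e, w$label)]] <- tibble::tibble(
        electrode = e, well = electrodes$well[[i]],
        elec_col = electrodes$elec_col[[i]],
        elec_row = electrodes$elec_row[[i]],
        window = w$label,
        n_bursts = nrow(inw),
        mean_duration_s = if (nrow(inw)) mean(inw$duration_s) else NA_real_,
        mean_spikes_per_burst = if (nrow(inw)) mean(inw$size_spikes) else NA_real_,
        mean_burst_isi_s = if (nrow(inw)) {
          mean(inw$duration_s / (inw$size_spikes - 1))
        } else NA_real_
      )
    }
  }
  spikes <- if (length(spike_rows)) {
    dplyr::bind_rows(spike_rows)
  } else {
    tibble::tibble(electrode = character(0), time_s = double(0))
  }
  list(spikes = spikes, truth = dplyr::bind_rows(truth_rows),
       params = params)
}

#' Write a complete synthetic fixture to disk
#'
#' Simulates spike trains, runs the burst detector over them, and writes
#' four plain-text files to `out_dir`: `spikes.csv` (electrode, spike
#' time), `bursts.csv` (the detected electrode burst list in the AxIS
#' dialect), `ground_truth.json` (per electrode x window true parameters)
#' and `manifest.json` (seed, parameter hash, file list). Re-running with
#' the same parameters reproduces the files byte for byte.
#'
#' @param params A [synth_params()] object.
#' @param out_dir Output directory; created if absent.
#' @return The manifest, invisibly.
#' @export
generate_fixture <- function(params, out_dir) {
  stopifnot(inherits(params, "synth_params"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_spike_trains(params)
  spikes_path <- file.path(out_dir, "spikes.csv")
  bursts_path <- file.path(out_dir, "bursts.csv")
  truth_path <- file.path(out_dir, "ground_truth.json")
  manifest_path <- file.path(out_dir, "manifest.json")

  readr::write_csv(
    tibble::tibble("Electrode" = sim$spikes$electrode,
                   "Time (s)" = sim$spikes$time_s),
    spikes_path, progress = FALSE
  )
  detected <- detect_bursts_table(
    sim$spikes, min_spikes = params$min_spikes,
    max_isi_s = params$max_isi_s,
    recording_id = paste0("synthetic-seed-", params$seed),
    layout = params$layout,
    recording_length_s = params$recording_length_s
  )
  write_electrode_burst_list(detected, bursts_path)
  jsonlite::write_json(sim$truth, truth_path, digits = NA, na = "null")
  manifest <- list(
    seed = params$seed,
    params_hash = rlang::hash(params),
    n_electrodes = nrow(plate_electrodes(params$layout, params$wells)),
    n_spikes = nrow(sim$spikes),
    n_bursts = nrow(detected),
    files = c("spikes.csv", "bursts.csv", "ground_truth.json")
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

#' Read a fixture's ground truth back
#'
#' @param path Path to a `ground_truth.json` written by
#'   [generate_fixture()].
#' @return The ground-truth tibble.
#' @export
read_ground_truth <- function(path) {
  tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}
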