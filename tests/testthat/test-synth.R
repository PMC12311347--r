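small_params <- function(seed = 1, ...) {
  synth_params(wells = "B6", recording_length_s = 120,
               windows = time_windows(c("w1", "w2"), c(0, 60), c(60, 120)),
               seed = seed, ...)
}

test_that("parameter combinations breaking the truncation invariants error", {
  expect_error(small_params(gap_floor_s = 0.1), "gap_floor_s")
  expect_error(small_params(isi_median_s = 0.2), "isi_median_s")
  expect_error(small_params(size_mean = 2), "size_mean")
})

test_that("zero rate gives empty trains and all-zero ground truth", {
  sim <- simulate_spike_trains(small_params(burst_rate_per_min = 0))
  expect_equal(nrow(sim$spikes), 0L)
  expect_true(all(sim$truth$n_bursts == 0))
  expect_true(all(is.na(sim$truth$mean_duration_s)))
})

test_that("the same seed reproduces bit-identical output", {
  a <- simulate_spike_trains(small_params(seed = 5))
  b <- simulate_spike_trains(small_params(seed = 5))
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$truth, b$truth)
  c <- simulate_spike_trains(small_params(seed = 6))
  expect_false(identical(a$spikes, c$spikes))
})

test_that("adding electrodes never perturbs existing trains", {
  one <- simulate_spike_trains(
    synth_params(wells = "B6", recording_length_s = 60,
                 silent_electrodes = setdiff(
                   plate_electrodes(wells = "B6")$electrode, "B6_11"),
                 seed = 3))
  two <- simulate_spike_trains(
    synth_params(wells = "B6", recording_length_s = 60, seed = 3))
  expect_identical(one$spikes$time_s,
                   two$spikes$time_s[two$spikes$electrode == "B6_11"])
})

test_that("silent electrodes emit nothing and generated bursts obey the rule", {
  p <- small_params(silent_electrodes = c("B6_11", "B6_44"), seed = 2)
  sim <- simulate_spike_trains(p)
  expect_false(any(sim$spikes$electrode %in% c("B6_11", "B6_44")))
  expect_equal(
    sim$truth$n_bursts[sim$truth$electrode %in% c("B6_11", "B6_44")],
    rep(0L, 4)
  )
  # every emitted ISI is either within-burst (<= max) or a gap (> max),
  # and timestamps sit on the sampling grid
  for (e in unique(sim$spikes$electrode)[1:3]) {
    t <- sim$spikes$time_s[sim$spikes$electrode == e]
    expect_true(all(abs(t * p$sample_rate_hz -
                          round(t * p$sample_rate_hz)) < 1e-9))
    isis <- diff(t)
    expect_true(all(isis <= p$max_isi_s | isis > p$max_isi_s))
    expect_true(all(isis > 0))
  }
})

test_that("the detector recovers generated bursts exactly on every seed", {
  for (seed in 1:5) {
    p <- small_params(seed = seed)
    sim <- simulate_spike_trains(p)
    detected <- detect_bursts_table(sim$spikes, layout = p$layout,
                                    recording_length_s = p$recording_length_s)
    got <- summarize_electrode(
      detected, p$windows,
      electrodes = plate_electrodes(p$layout, p$wells)$electrode)
    want <- sim$truth[order(sim$truth$electrode, sim$truth$window), ]
    got <- got[order(got$electrode, got$window), ]
    expect_identical(got$n_bursts, as.integer(want$n_bursts))
    expect_equal(got$mean_duration_s, want$mean_duration_s, tolerance = 0)
    expect_equal(got$mean_spikes_per_burst, want$mean_spikes_per_burst,
                 tolerance = 0)
    expect_equal(got$mean_burst_isi_s, want$mean_burst_isi_s, tolerance = 0)
  }
})

test_that("fixture generation writes idempotent files that round-trip", {
  p <- synth_params(wells = "B6", recording_length_s = 60, seed = 9)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_fixture(p, d1)
  m2 <- generate_fixture(p, d2)
  for (f in c("spikes.csv", "bursts.csv", "ground_truth.json",
              "manifest.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_equal(m1$params_hash, m2$params_hash)
  # the written burst list reloads to the detector's output
  tab <- read_electrode_burst_list(file.path(d1, "bursts.csv"))
  expect_equal(nrow(tab), m1$n_bursts)
  truth <- read_ground_truth(file.path(d1, "ground_truth.json"))
  expect_equal(sum(truth$n_bursts), m1$n_bursts)
})

test_that("rate modulation raises counts in the boosted window", {
  diffs <- vapply(1:100, function(seed) {
    p <- synth_params(
      wells = "A1", recording_length_s = 120,
      windows = time_windows(c("w1", "w2"), c(0, 60), c(60, 120)),
      silent_electrodes = setdiff(plate_electrodes(wells = "A1")$electrode,
                                  c("A1_11", "A1_12")),
      modulation = c(w2 = 2), seed = seed)
    tr <- simulate_spike_trains(p)$truth
    sum(tr$n_bursts[tr$window == "w2"]) - sum(tr$n_bursts[tr$window == "w1"])
  }, 0)
  expect_gt(mean(diffs), 0)
})

test_that("the mean-ISI estimator is unbiased against the analytic truth", {
  # one electrode, ~200 bursts per seed, median ISI 10 ms
  p0 <- synth_params(wells = "A1", recording_length_s = 600,
                     windows = time_windows("all", 0, 600),
                     burst_rate_per_min = 20, isi_median_s = 0.010,
                     silent_electrodes = setdiff(
                       plate_electrodes(wells = "A1")$electrode, "A1_11"),
                     seed = 1)
  ests <- vapply(1:100, function(seed) {
    p <- p0
    p$seed <- seed
    sim <- simulate_spike_trains(p)
    sim$truth$mean_burst_isi_s[sim$truth$electrode == "A1_11"]
  }, 0)
  # analytic mean of the truncated log-normal ISI distribution
  mu <- log(0.010); sg <- p0$isi_sigma
  dt <- 1 / p0$sample_rate_hz
  lo <- 2 * dt; hi <- p0$max_isi_s - 2 * dt
  z <- function(x) (log(x) - mu) / sg
  truth <- exp(mu + sg^2 / 2) *
    (pnorm(z(hi) - sg) - pnorm(z(lo) - sg)) /
    (pnorm(z(hi)) - pnorm(z(lo)))
  mc_sem <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - truth), 2.58 * mc_sem + 1e-4)
})
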