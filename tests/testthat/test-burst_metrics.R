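test_that("window membership is half-open on burst start times", {
  tab <- burst_table(tibble::tibble(
    electrode = rep("B6_11", 3),
    time_s = c(119.9, 120.0, 240.0),
    size_spikes = c(5L, 5L, 5L),
    duration_s = c(0.1, 0.1, 0.1)
  ))
  w <- time_windows("mid", 120, 240)
  kept <- filter_window(tab, w)
  expect_equal(kept$time_s, 120.0) # lower bound in, upper bound out
  expect_equal(attr(kept, "recording_id"), attr(tab, "recording_id"))
})

test_that("per-window counts over a partition sum to the total count", {
  set.seed(11)
  for (rep in 1:10) {
    tab <- random_burst_table(60L)
    edges <- sort(c(0, runif(sample(2:5, 1), 0, 600), 600))
    windows <- time_windows(paste0("p", seq_len(length(edges) - 1)),
                            edges[-length(edges)], edges[-1])
    per <- summarize_electrode(tab, windows)
    totals <- dplyr::count(tibble::tibble(electrode = tab$electrode),
                           electrode)
    summed <- dplyr::summarise(dplyr::group_by(per, electrode),
                               n = sum(n_bursts), .groups = "drop")
    expect_equal(summed, totals)
  }
})

test_that("mean within-burst ISI is duration over intervals", {
  expect_equal(mean_burst_isi(0.09216, 17), 0.00576)
  expect_equal(round(mean_burst_isi(0.08424, 22), 9), 0.004011429)
  expect_equal(mean_burst_isi(0.1, 2), 0.1)
  expect_error(mean_burst_isi(0.1, 1), "size_spikes")
})

test_that("electrode summaries match the direct-arithmetic oracle", {
  set.seed(12)
  tab <- random_burst_table(50L)
  w <- time_windows("w", 100, 400)
  got <- summarize_electrode(tab, w)
  for (e in unique(tab$electrode)) {
    sub <- tab[tab$electrode == e, ]
    want <- oracle_electrode_summary(sub$time_s, sub$size_spikes,
                                     sub$duration_s, 100, 400)
    row <- got[got$electrode == e, ]
    expect_equal(row$n_bursts, want$n_bursts)
    expect_equal(row$mean_duration_s, want$mean_duration_s)
    expect_equal(row$mean_spikes_per_burst, want$mean_spikes_per_burst)
    expect_equal(row$mean_burst_isi_s, want$mean_burst_isi_s)
  }
})

test_that("zero-burst electrodes report NA means, never zeros", {
  tab <- demo_burst_table()
  w <- time_windows("late", 200, 240)
  s <- summarize_electrode(tab, w,
                           electrodes = c("B6_11", "B6_12", "B6_13"))
  expect_equal(s$n_bursts, c(0L, 0L, 0L))
  expect_true(all(is.na(s$mean_duration_s)))
  expect_true(all(is.na(s$mean_burst_isi_s)))
})

test_that("the electrode mean ISI is the mean over bursts, not a ratio of means", {
  # heterogeneous two-burst fixture where the two conventions differ
  tab <- burst_table(tibble::tibble(
    electrode = c("B6_12", "B6_12"),
    time_s = c(1, 2),
    size_spikes = c(5L, 21L),
    duration_s = c(0.08, 0.16)
  ))
  s <- summarize_electrode(tab, time_windows("all", 0, 10))
  per_burst <- mean(c(0.08 / 4, 0.16 / 20))
  ratio_of_means <- mean(c(0.08, 0.16)) / (mean(c(5, 21)) - 1)
  expect_equal(s$mean_burst_isi_s, per_burst)
  expect_false(isTRUE(all.equal(s$mean_burst_isi_s, ratio_of_means)))
})

test_that("scaling durations by c scales duration and ISI means, nothing else", {
  set.seed(13)
  tab <- random_burst_table(40L)
  scaled <- burst_table(
    dplyr::mutate(tibble::as_tibble(tab), duration_s = duration_s * 3),
    recording_length_s = 600
  )
  w <- time_windows("all", 0, 600)
  a <- summarize_electrode(tab, w)
  b <- summarize_electrode(scaled, w)
  expect_equal(b$mean_duration_s, 3 * a$mean_duration_s)
  expect_equal(b$mean_burst_isi_s, 3 * a$mean_burst_isi_s)
  expect_equal(b$n_bursts, a$n_bursts)
  expect_equal(b$mean_spikes_per_burst, a$mean_spikes_per_burst)
})

test_that("well summaries pool counts over all electrodes and means over active ones", {
  # 3 active electrodes with counts 1,2,3 in a 16-electrode well
  tab <- burst_table(tibble::tibble(
    electrode = c("B6_11", "B6_12", "B6_12", "B6_13", "B6_13", "B6_13"),
    time_s = 1:6,
    size_spikes = rep(5L, 6),
    duration_s = rep(0.1, 6)
  ))
  w <- time_windows("all", 0, 10)
  ws <- summarize_well(tab, w, wells = "B6")
  counts <- ws[ws$parameter == "n_bursts", ]
  expect_equal(counts$mean, 6 / 16)
  expect_equal(counts$n_electrodes, 16L)
  expect_equal(counts$n_electrodes_active, 3L)
  # sd of 13 zeros + {1,2,3} over sqrt(16)
  expect_equal(counts$sem, sd(c(rep(0, 13), 1, 2, 3)) / 4)
  dur <- ws[ws$parameter == "mean_duration_s", ]
  expect_equal(dur$mean, 0.1)
  expect_equal(dur$sem, 0) # all active electrodes identical

  excl <- summarize_well(tab, w, wells = "B6", count_inactive = FALSE)
  expect_equal(excl[excl$parameter == "n_bursts", ]$mean, 2)
  expect_equal(excl[excl$parameter == "n_bursts", ]$sem, sd(1:3) / sqrt(3))
})

test_that("SEM of {1,2,3} uses the sample standard deviation", {
  expect_equal(round(sd(1:3) / sqrt(3), 4), 0.5774)
})

test_that("well summaries match a brute-force mean/SEM oracle on random data", {
  set.seed(14)
  tab <- random_burst_table(80L)
  w <- time_windows("all", 0, 600)
  for (well in unique(tab$well)) {
    ws <- summarize_well(tab, w, wells = well)
    es <- summarize_electrode(tab, w,
                              electrodes = plate_electrodes(wells = well)$electrode)
    vals <- es$mean_duration_s[!is.na(es$mean_duration_s)]
    dur <- ws[ws$parameter == "mean_duration_s", ]
    expect_equal(dur$mean, mean(vals))
    expect_equal(dur$sem,
                 if (length(vals) > 1) sd(vals) / sqrt(length(vals)) else NA_real_)
    cnt <- ws[ws$parameter == "n_bursts", ]
    expect_equal(cnt$mean, mean(es$n_bursts))
  }
  expect_error(summarize_well(tab, w, wells = "Z9"), "absent")
})

test_that("reference comparison judges parameters at the tolerance", {
  s <- tibble::tibble(electrode = c("E1_11", "E1_12"),
                      n_bursts = c(3L, 4L),
                      mean_duration_s = c(0.09216, 0.2),
                      mean_spikes_per_burst = c(10, 11),
                      mean_burst_isi_s = c(0.005, 0.006))
  # against itself everything passes
  self <- compare_with_reference(s, s, tol = 1e-12)
  expect_true(all(self$pass))
  # the worked near-miss pair passes at 1e-3, a 2e-3 gap fails
  ref <- s
  ref$mean_duration_s <- c(0.09224, 0.202)
  rep2 <- compare_with_reference(s, ref, tol = 1e-3)
  expect_true(rep2$pass[rep2$electrode == "E1_11" &
                          rep2$parameter == "mean_duration_s"])
  expect_false(rep2$pass[rep2$electrode == "E1_12" &
                           rep2$parameter == "mean_duration_s"])
  expect_equal(attr(rep2, "n_fail"), 1L)
  # one-sided electrodes are flagged, not fatal
  lonely <- compare_with_reference(s[1, ], ref)
  expect_true(any(is.na(lonely$pass)))
})

test_that("windows config files read from YAML and JSON", {
  wy <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("- label: baseline", "  t0_s: 0", "  t1_s: 120",
               "- label: treated", "  t0_s: 120", "  t1_s: 240"), wy)
  expect_equal(read_windows(wy),
               time_windows(c("baseline", "treated"), c(0, 120), c(120, 240)))
  wj <- withr::local_tempfile(fileext = ".json")
  writeLines('[{"label":"a","t0_s":0,"t1_s":1}]', wj)
  expect_equal(read_windows(wj), time_windows("a", 0, 1))
  expect_error(time_windows("bad", 10, 10), "t1_s > t0_s")
})
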