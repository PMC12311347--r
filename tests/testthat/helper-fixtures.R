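# Shared fixture builders (all data generated in code).

# A small, heterogeneous burst table spanning two wells.
demo_burst_table <- function() {
  burst_table(
    tibble::tibble(
      electrode = c("B6_11", "B6_11", "B6_11", "B6_12", "A1_44"),
      time_s = c(0.5, 10, 130, 5, 60),
      size_spikes = c(10L, 20L, 5L, 8L, 12L),
      duration_s = c(0.09, 0.19, 0.05, 0.08, 0.12)
    ),
    recording_id = "demo", recording_length_s = 240
  )
}

# Random valid burst table for round-trip property tests.
random_burst_table <- function(n = 30L) {
  el <- plate_electrodes()
  pick <- el[sample(nrow(el), 5), ]
  burst_table(
    tibble::tibble(
      electrode = sample(pick$electrode, n, replace = TRUE),
      time_s = runif(n, 0, 600),
      size_spikes = sample(5:40, n, replace = TRUE),
      duration_s = runif(n, 0.05, 0.3)
    ),
    recording_id = "random", recording_length_s = 600
  )
}

mea_reference_path <- function() {
  system.file("extdata", "b6_mea_metrics.csv", package = "meaburst")
}

axion_reference_path <- function() {
  system.file("extdata", "b6_axion_metrics.csv", package = "meaburst")
}
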