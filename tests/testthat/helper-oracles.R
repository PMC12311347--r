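# Independent oracles, deliberately naive: these re-derive expected results
# by enumeration or textbook formulas and never share code with the package.

# Brute-force burst finder: enumerate every contiguous index range, keep the
# ranges whose internal ISIs are all <= max_isi and whose length >= min
# spikes, then select the maximal ones (not contained in a larger valid
# range).
oracle_bursts <- function(times, min_spikes = 5L, max_isi = 0.1) {
  n <- length(times)
  valid <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j - i + 1 < min_spikes) next
      isis <- diff(times[i:j])
      if (all(isis <= max_isi)) valid[[length(valid) + 1L]] <- c(i, j)
    }
  }
  if (length(valid) == 0) {
    return(tibble::tibble(time_s = double(0), size_spikes = integer(0),
                          duration_s = double(0)))
  }
  maximal <- Filter(function(r) {
    !any(vapply(valid, function(s) {
      (s[1] < r[1] && s[2] >= r[2]) || (s[1] <= r[1] && s[2] > r[2])
    }, logical(1)))
  }, valid)
  maximal <- maximal[order(vapply(maximal, `[`, 0, 1))]
  tibble::tibble(
    time_s = vapply(maximal, function(r) times[r[1]], 0),
    size_spikes = vapply(maximal, function(r) r[2] - r[1] + 1L, 0L),
    duration_s = vapply(maximal, function(r) times[r[2]] - times[r[1]], 0)
  )
}

# Random spike train with a mix of within-burst and between-burst ISIs.
random_train <- function(n_max = 50L, max_isi = 0.1) {
  n <- sample(0:n_max, 1)
  if (n == 0) return(double(0))
  cumsum(runif(n, 1e-4, 2 * max_isi))
}

# ICC(2,k) via R's own two-way ANOVA fit: an independent route to the mean
# squares the closed-form implementation computes from explicit sums.
oracle_icc2k_aov <- function(m) {
  d <- data.frame(
    value = as.vector(m),
    subject = factor(rep(seq_len(nrow(m)), times = ncol(m))),
    rater = factor(rep(seq_len(ncol(m)), each = nrow(m)))
  )
  tab <- summary(stats::aov(value ~ subject + rater, data = d))[[1]]
  msr <- tab["subject", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (msc - mse) / nrow(m))
}

# Direct-arithmetic summary oracle for one electrode's in-window bursts.
oracle_electrode_summary <- function(time_s, size_spikes, duration_s,
                                     t0, t1) {
  keep <- time_s >= t0 & time_s < t1
  s <- size_spikes[keep]
  d <- duration_s[keep]
  list(
    n_bursts = sum(keep),
    mean_duration_s = if (any(keep)) sum(d) / length(d) else NA_real_,
    mean_spikes_per_burst = if (any(keep)) sum(s) / length(s) else NA_real_,
    mean_burst_isi_s = if (any(keep)) sum(d / (s - 1)) / length(d) else NA_real_
  )
}
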