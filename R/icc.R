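#' Average-raters intraclass correlation ICC(2,k)
#'
#' Shrout--Fleiss ICC(2,k): two-way random effects, absolute agreement,
#' average of k raters. The complete n x k ratings matrix is decomposed by
#' two-way ANOVA into subject, rater and residual sums of squares with
#' degrees of freedom (n-1), (k-1) and (n-1)(k-1); then
#'
#'   ICC(2,k) = (MSR - MSE) / (MSR + (MSC - MSE) / n)
#'
#' where MSR, MSC and MSE are the subject, rater and residual mean squares.
#' The coefficient is at most 1 and may be negative. A matrix of identical
#' cells has no variance to apportion and raises an error rather than
#' returning 0 or 1.
#'
#' @param m A complete numeric matrix, subjects in rows (n >= 2), raters in
#'   columns (k >= 2). Row/column names, if present, are carried through.
#' @return A list of class `icc_result` with elements `icc2k`, `ms_rows`
#'   (MSR), `ms_cols` (MSC), `ms_error` (MSE), `n_subjects`, `k_raters`.
#' @examples
#' icc2k(cbind(1:3, 1:3))$icc2k # identical raters -> 1
#' @export
icc2k <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m)) stop("icc2k(): ratings must be numeric")
  if (anyNA(m)) stop("icc2k(): ratings matrix must be complete (no NA)")
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2 || k < 2) {
    stop("icc2k(): need at least 2 subjects and 2 raters, got ", n, "x", k)
  }
  gm <- mean(m)
  ss_rows <- k * sum((rowMeans(m) - gm)^2)
  ss_cols <- n * sum((colMeans(m) - gm)^2)
  ss_total <- sum((m - gm)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- msr + (msc - mse) / n
  scale <- max(abs(m - gm))
  if (scale == 0 || abs(denom) < 1e-12 * max(1, gm^2)) {
    stop("icc2k(): degenerate ratings (no variance to apportion); ",
         "ICC is undefined")
  }
  structure(
    list(icc2k = (msr - mse) / denom,
         ms_rows = msr, ms_cols = msc, ms_error = mse,
         n_subjects = n, k_raters = k),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf(
    "ICC(2,k) = %.4f  (n = %d subjects, k = %d raters)\n  MSR %.6g  MSC %.6g  MSE %.6g\n",
    x$icc2k, x$n_subjects, x$k_raters, x$ms_rows, x$ms_cols, x$ms_error))
  invisible(x)
}

#' Build a ratings matrix from single-electrode summaries
#'
#' Arranges one burst parameter from [summarize_electrode()] output into the
#' complete subjects x raters matrix that [icc2k()] consumes. In the default
#' orientation the subjects are wells and the raters are the electrode
#' positions within a well (so consistency across electrodes is assessed);
#' the alternative uses time windows as subjects, for a per-well ICC across
#' windows. Electrodes (raters) with any undefined value make the matrix
#' incomplete: this errors, listing the offending cells, unless
#' `drop_incomplete_raters = TRUE`, which removes those rater columns
#' entirely. No imputation is ever performed.
#'
#' @param summaries Output of [summarize_electrode()].
#' @param parameter One of `"n_bursts"`, `"mean_duration_s"`,
#'   `"mean_spikes_per_burst"`, `"mean_burst_isi_s"`.
#' @param orientation `"wells-by-electrodes"` (default; one matrix per
#'   window, subjects = wells, raters = electrode positions) or
#'   `"windows-by-electrodes"` (subjects = windows, raters = electrodes,
#'   usually within one well).
#' @param window For `"wells-by-electrodes"`: which window label to use
#'   (defaults to the only window present; required if several).
#' @param drop_incomplete_raters Drop rater columns containing undefined
#'   values instead of erroring.
#' @return A numeric matrix with subject row names and rater column names.
#' @export
build_ratings_matrix <- function(summaries, parameter,
                                 orientation = c("wells-by-electrodes",
                                                 "windows-by-electrodes"),
                                 window = NULL,
                                 drop_incomplete_raters = FALSE) {
  orientation <- match.arg(orientation)
  params <- c("n_bursts", "mean_duration_s", "mean_spikes_per_burst",
              "mean_burst_isi_s")
  if (!parameter %in% params) {
    stop("build_ratings_matrix(): unknown parameter '", parameter,
         "'; expected one of: ", paste(params, collapse = ", "))
  }
  s <- tibble::as_tibble(summaries)
  if (orientation == "wells-by-electrodes") {
    labs <- unique(s$window)
    if (is.null(window)) {
      if (length(labs) > 1) {
        stop("build_ratings_matrix(): several windows present (",
             paste(labs, collapse = ", "), "); pick one with `window`")
      }
      window <- labs
    }
    s <- s[s$window == window, ]
    if (nrow(s) == 0) stop("build_ratings_matrix(): no rows for window '",
                           window, "'")
    subject <- s$well
    rater <- paste0(s$elec_col, s$elec_row)
  } else {
    subject <- s$window
    rater <- s$electrode
  }
  value <- as.double(s[[parameter]])
  wide <- tapply(value, list(subject, rater), function(v) v[[1L]])
  n_per_cell <- table(subject, rater)
  if (any(n_per_cell > 1)) {
    stop("build_ratings_matrix(): duplicate values for some ",
         "(subject, rater) cells; summaries are not uniquely keyed")
  }
  bad <- which(is.na(wide), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    cells <- paste0(rownames(wide)[bad[, 1]], ":", colnames(wide)[bad[, 2]])
    if (drop_incomplete_raters) {
      wide <- wide[, setdiff(colnames(wide), unique(colnames(wide)[bad[, 2]])),
                   drop = FALSE]
      if (ncol(wide) < 2) {
        stop("build_ratings_matrix(): fewer than 2 complete raters remain")
      }
    } else {
      stop("build_ratings_matrix(): undefined cells (subject:rater): ",
           paste(utils::head(cells, 10), collapse = ", "),
           if (length(cells) > 10) " ..." else "",
           "; use drop_incomplete_raters = TRUE to drop those raters")
    }
  }
  wide
}

#' Tidy ICC results for several parameters and windows
#'
#' Convenience wrapper: runs [build_ratings_matrix()] + [icc2k()] per
#' (parameter, window) and returns the tidy export layout.
#'
#' @inheritParams build_ratings_matrix
#' @param parameters Parameters to process (default all four).
#' @return A tibble with columns `parameter`, `window`, `n_subjects`,
#'   `k_raters`, `ms_rows`, `ms_cols`, `ms_error`, `icc2k`.
#' @export
icc_summary <- function(summaries,
                        parameters = c("n_bursts", "mean_duration_s",
                                       "mean_spikes_per_burst",
                                       "mean_burst_isi_s"),
                        orientation = "wells-by-electrodes",
                        drop_incomplete_raters = FALSE) {
  windows <- unique(summaries$window)
  grid <- expand.grid(parameter = parameters, window = windows,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- grid$parameter[[i]]
    w <- grid$window[[i]]
    sub <- if (orientation == "wells-by-electrodes") {
      summaries
    } else {
      summaries[summaries$window %in% windows, ]
    }
    m <- build_ratings_matrix(sub, p, orientation = orientation,
                              window = if (orientation == "wells-by-electrodes") w else NULL,
                              drop_incomplete_raters = drop_incomplete_raters)
    r <- icc2k(m)
    tibble::tibble(parameter = p, window = w,
                   n_subjects = r$n_subjects, k_raters = r$k_raters,
                   ms_rows = r$ms_rows, ms_cols = r$ms_cols,
                   ms_error = r$ms_error, icc2k = r$icc2k)
  })
  if (orientation == "windows-by-electrodes") {
    # one matrix spans all windows; collapse the per-window duplication
    rows <- rows[!duplicated(grid$parameter)]
    out <- dplyr::bind_rows(rows)
    out$window <- "all"
    return(out)
  }
  dplyr::bind_rows(rows)
}
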