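#' Save a chart with its sidecar data table
#'
#' Every chart in this package is a view of an explicit data table, never a
#' recomputation. `save_chart()` writes the figure as PNG and the plotted
#' values as a sidecar CSV next to it (same path, `.csv` extension), so
#' figures can be regression-tested without image comparison.
#'
#' @param chart A `mea_chart` object returned by one of the `plot_*`
#'   functions.
#' @param path Output PNG path.
#' @param width,height,dpi Device size in inches and resolution.
#' @return A character vector with the PNG and CSV paths, invisibly.
#' @export
save_chart <- function(chart, path, width = 7, height = 5, dpi = 150) {
  stopifnot(inherits(chart, "mea_chart"))
  ggplot2::ggsave(path, chart$plot, width = width, height = height,
                  dpi = dpi)
  sidecar <- sub("\\.[A-Za-z]+$", ".csv", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".csv")
  readr::write_csv(chart$data, sidecar, progress = FALSE)
  invisible(c(image = path, data = sidecar))
}

#' @export
print.mea_chart <- function(x, ...) {
  print(x$plot)
  invisible(x)
}

parameter_labels <- c(
  n_bursts = "Number of bursts",
  mean_duration_s = "Mean burst duration (s)",
  mean_spikes_per_burst = "Mean spikes per burst",
  mean_burst_isi_s = "Mean within-burst ISI (s)"
)

#' Whole-well bar chart of one burst parameter over time windows
#'
#' One bar per time window, in the order the windows appear in the
#' summaries (or in `windows` if given), with optional +/-SEM whiskers.
#' Windows where the well mean is undefined (no active electrodes) are
#' annotated as such, never drawn as zero-height bars.
#'
#' @param well_summaries Output of [summarize_well()] for one well.
#' @param parameter Which burst parameter to draw.
#' @param windows Optional character vector fixing the bar order.
#' @param error_bars Draw +/-SEM whiskers.
#' @return A `mea_chart` (list with `plot`, a ggplot, and `data`, the
#'   plotted table).
#' @export
plot_well_bars <- function(well_summaries,
                           parameter = "n_bursts",
                           windows = NULL, error_bars = TRUE) {
  d <- tibble::as_tibble(well_summaries)
  d <- d[d$parameter == parameter, ]
  if (nrow(d) == 0) stop("plot_well_bars(): no rows for parameter '",
                         parameter, "'")
  if (dplyr::n_distinct(d$well) != 1) {
    stop("plot_well_bars(): summaries must cover exactly one well")
  }
  if (is.null(windows)) windows <- unique(d$window)
  d <- d[match(windows, d$window), ]
  if (anyNA(d$window)) stop("plot_well_bars(): unknown window label(s)")
  d$window <- factor(d$window, levels = windows)
  drawn <- d[!is.na(d$mean), ]
  undefined <- d[is.na(d$mean), ]
  p <- ggplot2::ggplot(drawn, ggplot2::aes(x = window, y = mean)) +
    ggplot2::geom_col(fill = "grey35", width = 0.7) +
    ggplot2::scale_x_discrete(drop = FALSE) +
    ggplot2::labs(
      title = sprintf("Well %s", d$well[[1]]),
      x = "Time window",
      y = parameter_labels[[parameter]]
    ) +
    ggplot2::theme_classic()
  if (error_bars) {
    whisk <- drawn[!is.na(drawn$sem), ]
    p <- p + ggplot2::geom_errorbar(
      data = whisk,
      ggplot2::aes(ymin = mean - sem, ymax = mean + sem),
      width = 0.25
    )
  }
  if (nrow(undefined) > 0) {
    p <- p + ggplot2::geom_text(
      data = undefined,
      ggplot2::aes(x = window, y = 0, label = "no active\nelectrodes"),
      size = 2.8, vjust = -0.2
    )
  }
  structure(list(plot = p, data = d), class = "mea_chart")
}

#' Single-electrode bar charts laid out on the physical 4x4 grid
#'
#' One panel per electrode of a well, positioned at its physical (column,
#' row) location, each panel holding one bar per time window. Electrodes
#' with no bursts in any window are rendered as empty panels labelled
#' inactive. By convention electrode row 1 is drawn at the top; set
#' `flip_rows = TRUE` for the opposite orientation.
#'
#' @param electrode_summaries Output of [summarize_electrode()] for the 16
#'   electrodes of one well.
#' @param parameter Which burst parameter to draw.
#' @param windows Optional character vector fixing the bar order.
#' @param flip_rows Draw electrode row 1 at the bottom instead of the top.
#' @return A `mea_chart`.
#' @export
plot_electrode_bars <- function(electrode_summaries,
                                parameter = "n_bursts",
                                windows = NULL, flip_rows = FALSE) {
  d <- tibble::as_tibble(electrode_summaries)
  if (dplyr::n_distinct(d$well) != 1) {
    stop("plot_electrode_bars(): electrodes from several wells; ",
         "summarize one well at a time")
  }
  if (is.null(windows)) windows <- unique(d$window)
  d <- d[d$window %in% windows, ]
  d$window <- factor(d$window, levels = windows)
  d$value <- as.double(d[[parameter]])
  active <- dplyr::summarise(dplyr::group_by(d, electrode),
                             any_burst = any(n_bursts > 0),
                             .groups = "drop")
  d <- dplyr::left_join(d, active, by = "electrode")
  # facet rows render top to bottom in level order: row 1 at top by default
  d$row_f <- factor(d$elec_row,
                    levels = if (flip_rows) rev(sort(unique(d$elec_row)))
                             else sort(unique(d$elec_row)))
  inactive <- unique(d[!d$any_burst,
                       c("electrode", "elec_col", "row_f", "window")])
  inactive <- inactive[!duplicated(inactive$electrode), ]
  inactive$x0 <- 1
  inactive$y0 <- 0
  inactive$note <- "inactive"
  p <- ggplot2::ggplot(d[d$any_burst, ],
                       ggplot2::aes(x = window, y = value)) +
    ggplot2::geom_col(fill = "grey35", width = 0.7) +
    ggplot2::facet_grid(rows = ggplot2::vars(row_f),
                        cols = ggplot2::vars(elec_col), drop = FALSE) +
    ggplot2::scale_x_discrete(drop = FALSE) +
    ggplot2::labs(
      title = sprintf("Well %s, by electrode (grid column x row)",
                      d$well[[1]]),
      x = "Time window", y = parameter_labels[[parameter]]
    ) +
    ggplot2::theme_bw()
  if (nrow(inactive) > 0) {
    p <- p + ggplot2::geom_text(
      data = inactive,
      ggplot2::aes(x = x0, y = y0, label = note),
      inherit.aes = FALSE, size = 3, hjust = 0, colour = "grey50"
    )
  }
  keep <- c("electrode", "well", "elec_col", "elec_row", "window", "value")
  structure(list(plot = p, data = d[, keep]), class = "mea_chart")
}

#' To-scale schematic of the electrode grid
#'
#' Draws the electrode array of each well to scale (default 50 um diameter
#' circles at 350 um pitch) with electrode positions labelled in the
#' "column,row" convention.
#'
#' @param layout A [plate_layout()].
#' @param wells Wells to draw; defaults to a single representative well.
#' @return A `mea_chart`; its data table holds one row per electrode with
#'   physical x/y centre coordinates in micrometres.
#' @export
plot_plate_schematic <- function(layout = plate_layout(), wells = NULL) {
  stopifnot(inherits(layout, "plate_layout"))
  if (layout$electrode_pitch_um < layout$electrode_diameter_um) {
    stop("plot_plate_schematic(): electrode pitch smaller than diameter; ",
         "electrodes would overlap")
  }
  if (is.null(wells)) wells <- plate_wells(layout)[[1]]
  el <- plate_electrodes(layout, wells)
  pitch <- layout$electrode_pitch_um
  side <- layout$electrodes_per_side
  well_span <- (side + 1) * pitch
  well_idx <- match(el$well, wells)
  el$x_um <- (well_idx - 1) * well_span + el$elec_col * pitch
  el$y_um <- (side + 1 - el$elec_row) * pitch  # row 1 at top
  el$label <- paste0(el$elec_col, ",", el$elec_row)

  theta <- seq(0, 2 * pi, length.out = 48)
  r <- layout$electrode_diameter_um / 2
  circles <- do.call(rbind, lapply(seq_len(nrow(el)), function(i) {
    data.frame(electrode = el$electrode[[i]],
               x = el$x_um[[i]] + r * cos(theta),
               y = el$y_um[[i]] + r * sin(theta))
  }))
  p <- ggplot2::ggplot() +
    ggplot2::geom_polygon(data = circles,
                          ggplot2::aes(x = x, y = y, group = electrode),
                          fill = "grey60", colour = "grey20") +
    ggplot2::geom_text(data = el,
                       ggplot2::aes(x = x_um, y = y_um + 2.5 * r,
                                    label = label), size = 2.6) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = sprintf("Electrode grid (%g µm dia, %g µm pitch)",
                                  layout$electrode_diameter_um,
                                  layout$electrode_pitch_um)) +
    ggplot2::theme_minimal()
  keep <- c("electrode", "well", "elec_col", "elec_row", "x_um", "y_um")
  structure(list(plot = p, data = tibble::as_tibble(el[, keep])),
            class = "mea_chart")
}
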