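#' CSV dialect for AxIS-style electrode burst lists
#'
#' AxIS Navigator exports vary in header spelling and may carry a free-form
#' metadata preamble before the column header. The dialect lists, per field,
#' the accepted header aliases; matching is case-insensitive after stripping
#' a trailing parenthesised unit (so "Time (s)", "Time_s" and "time" all
#' match). The preamble is skipped by scanning for the first line containing
#' an electrode-column alias, up to `max_preamble_lines` lines.
#'
#' @param electrode,time,size,duration Character vectors of accepted header
#'   aliases for each field.
#' @param max_preamble_lines Maximum number of leading metadata lines to
#'   scan past before giving up.
#' @return A list of class `axis_dialect`.
#' @export
axis_dialect <- function(electrode = c("Electrode"),
                         time = c("Time (s)", "Time_s", "Time"),
                         size = c("Size (spikes)", "Size_spikes", "Size"),
                         duration = c("Duration (s)", "Duration_s", "Duration"),
                         max_preamble_lines = 200L) {
  structure(
    list(electrode = electrode, time = time, size = size,
         duration = duration,
         max_preamble_lines = as.integer(max_preamble_lines)),
    class = "axis_dialect"
  )
}

# "Size (spikes)" -> "size"; "Time_s" -> "time_s" -> matched via alias set
normalize_header <- function(x) {
  x <- tolower(trimws(x))
  x <- sub("\\s*\\([^)]*\\)\\s*$", "", x)
  gsub("[ _]+", "", x)
}

match_columns <- function(header, dialect) {
  norm <- normalize_header(header)
  find_one <- function(aliases) {
    hits <- which(norm %in% normalize_header(aliases))
    if (length(hits) == 0) NA_integer_ else hits[[1L]]
  }
  c(electrode = find_one(dialect$electrode),
    time = find_one(dialect$time),
    size = find_one(dialect$size),
    duration = find_one(dialect$duration))
}

#' Read an electrode burst list CSV
#'
#' Parses a burst list in the AxIS Navigator dialect: one row per detected
#' burst with electrode token, burst start time (s), size (spikes) and
#' duration (s). A metadata preamble of variable length before the header is
#' skipped automatically. Rows whose numeric fields fail to parse are
#' dropped with a warning naming the offending row numbers.
#'
#' @param source Path to a CSV file, or a character vector of CSV lines.
#' @param dialect An [axis_dialect()].
#' @param recording_id Identifier stored on the result; defaults to the file
#'   name.
#' @param layout A [plate_layout()].
#' @param recording_length_s Recording length in seconds if known.
#' @return A [burst_table()].
#' @export
read_electrode_burst_list <- function(source, dialect = axis_dialect(),
                                      recording_id = NULL,
                                      layout = plate_layout(),
                                      recording_length_s = NA_real_) {
  if (length(source) == 1 && file.exists(source)) {
    lines <- readr::read_lines(source)
    if (is.null(recording_id)) recording_id <- basename(source)
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE))
    if (is.null(recording_id)) recording_id <- ""
  }
  lines <- lines[!is.na(lines)]
  if (length(lines) == 0 || all(trimws(lines) == "")) {
    stop("read_electrode_burst_list(): empty input")
  }

  elec_aliases <- normalize_header(dialect$electrode)
  scan_limit <- min(length(lines), dialect$max_preamble_lines)
  header_line <- NA_integer_
  for (i in seq_len(scan_limit)) {
    fields <- normalize_header(strsplit(lines[[i]], ",", fixed = TRUE)[[1L]])
    if (any(fields %in% elec_aliases)) {
      header_line <- i
      break
    }
  }
  if (is.na(header_line)) {
    stop("read_electrode_burst_list(): no header line with an electrode ",
         "column found in the first ", scan_limit, " lines; expected one of: ",
         paste(dialect$electrode, collapse = ", "))
  }

  body <- lines[header_line:length(lines)]
  raw <- readr::read_csv(I(paste(body, collapse = "\n")),
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  idx <- match_columns(names(raw), dialect)
  if (any(is.na(idx))) {
    stop("read_electrode_burst_list(): missing required column(s) [",
         paste(names(idx)[is.na(idx)], collapse = ", "), "]; found headers: ",
         paste(names(raw), collapse = ", "))
  }

  electrode <- raw[[idx[["electrode"]]]]
  time_s <- suppressWarnings(as.double(raw[[idx[["time"]]]]))
  size_spikes <- suppressWarnings(as.double(raw[[idx[["size"]]]]))
  duration_s <- suppressWarnings(as.double(raw[[idx[["duration"]]]]))

  blank <- is.na(electrode) | trimws(electrode) == ""
  bad <- !blank & (is.na(time_s) | is.na(size_spikes) | is.na(duration_s))
  if (any(bad)) {
    warning("read_electrode_burst_list(): dropped ", sum(bad),
            " row(s) with unparseable numeric fields (data rows: ",
            paste(which(bad), collapse = ", "), ")")
  }
  keep <- !blank & !bad
  burst_table(
    tibble::tibble(
      electrode = electrode[keep],
      time_s = time_s[keep],
      size_spikes = size_spikes[keep],
      duration_s = duration_s[keep]
    ),
    recording_id = recording_id, layout = layout,
    recording_length_s = recording_length_s
  )
}

#' Write an electrode burst list CSV
#'
#' Writes a [burst_table()] in the canonical dialect with header
#' `Electrode,Time (s),Size (spikes),Duration (s)`. Numeric fields are
#' written at full round-trip precision, so
#' `read_electrode_burst_list(write_electrode_burst_list(x))` reproduces `x`
#' exactly.
#'
#' @param table A [burst_table()].
#' @param sink Output file path.
#' @return `sink`, invisibly.
#' @export
write_electrode_burst_list <- function(table, sink) {
  stopifnot(inherits(table, "burst_table"))
  bad_wells <- setdiff(unique(table$well), plate_wells(table_layout(table)))
  if (length(bad_wells) > 0) {
    stop("write_electrode_burst_list(): electrodes from wells absent in ",
         "layout: ", paste(bad_wells, collapse = ", "))
  }
  out <- tibble::tibble(
    "Electrode" = table$electrode,
    "Time (s)" = table$time_s,
    "Size (spikes)" = table$size_spikes,
    "Duration (s)" = table$duration_s
  )
  readr::write_csv(out, sink, progress = FALSE)
  invisible(sink)
}
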