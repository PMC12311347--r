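#' Plate layout description
#'
#' Describes the geometry of a multi-well MEA plate. The default corresponds
#' to a 24-well CytoView plate: 4 rows of wells (labelled A--D) by 6 columns
#' (1--6), each well carrying a 4x4 grid of 16 electrodes of 50 um diameter
#' at 350 um pitch.
#'
#' @param well_rows Number of well rows (labelled A, B, ...).
#' @param well_cols Number of well columns (labelled 1, 2, ...).
#' @param electrodes_per_side Electrodes per side of the square grid in each
#'   well (4 gives the 16-electrode layout).
#' @param electrode_diameter_um Electrode diameter in micrometres.
#' @param electrode_pitch_um Centre-to-centre electrode spacing in
#'   micrometres.
#' @return An object of class `plate_layout`.
#' @examples
#' layout <- plate_layout()
#' length(plate_wells(layout)) # 24
#' @export
plate_layout <- function(well_rows = 4L, well_cols = 6L,
                         electrodes_per_side = 4L,
                         electrode_diameter_um = 50,
                         electrode_pitch_um = 350) {
  stopifnot(well_rows >= 1, well_cols >= 1, electrodes_per_side >= 1,
            electrode_diameter_um > 0, electrode_pitch_um > 0)
  if (well_rows > 26) {
    stop("plate_layout(): at most 26 well rows (single-letter labels)")
  }
  structure(
    list(
      well_rows = as.integer(well_rows),
      well_cols = as.integer(well_cols),
      electrodes_per_side = as.integer(electrodes_per_side),
      electrode_diameter_um = electrode_diameter_um,
      electrode_pitch_um = electrode_pitch_um
    ),
    class = "plate_layout"
  )
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf(
    "<plate_layout> %d wells (%dx%d), %d electrodes/well (%dx%d grid), %g um dia / %g um pitch\n",
    x$well_rows * x$well_cols, x$well_rows, x$well_cols,
    x$electrodes_per_side^2, x$electrodes_per_side, x$electrodes_per_side,
    x$electrode_diameter_um, x$electrode_pitch_um
  ))
  invisible(x)
}

#' Well labels of a plate layout
#'
#' @param layout A [plate_layout()].
#' @return Character vector of well labels in row-major order ("A1", "A2",
#'   ...).
#' @export
plate_wells <- function(layout = plate_layout()) {
  stopifnot(inherits(layout, "plate_layout"))
  as.vector(t(outer(LETTERS[seq_len(layout$well_rows)],
                    seq_len(layout$well_cols), paste0)))
}

#' All electrode identifiers of a plate layout
#'
#' @param layout A [plate_layout()].
#' @param wells Optional subset of well labels.
#' @return A tibble with columns `electrode` (canonical token such as
#'   "B6_24"), `well`, `elec_col`, `elec_row`.
#' @export
plate_electrodes <- function(layout = plate_layout(), wells = NULL) {
  stopifnot(inherits(layout, "plate_layout"))
  all_wells <- plate_wells(layout)
  if (is.null(wells)) {
    wells <- all_wells
  } else if (!all(wells %in% all_wells)) {
    stop("plate_electrodes(): wells not in layout: ",
         paste(setdiff(wells, all_wells), collapse = ", "))
  }
  s <- layout$electrodes_per_side
  grid <- expand.grid(elec_row = seq_len(s), elec_col = seq_len(s),
                      well = wells, stringsAsFactors = FALSE)
  tibble::tibble(
    electrode = format_electrode_id(grid$well, grid$elec_col, grid$elec_row),
    well = grid$well,
    elec_col = as.integer(grid$elec_col),
    elec_row = as.integer(grid$elec_row)
  )
}

#' Parse electrode identifiers
#'
#' Electrode tokens follow the AxIS convention `<well>_<col><row>`: the first
#' digit after the underscore is the electrode column within the well, the
#' second the electrode row. For example "B6_24" is the electrode in column
#' 2, row 4 of well B6.
#'
#' @param token Character vector of electrode tokens.
#' @param electrodes_per_side Grid side length; positions outside
#'   `1..electrodes_per_side` are rejected.
#' @return A tibble with columns `electrode` (canonical form), `well`,
#'   `elec_col`, `elec_row`. Errors on any malformed token.
#' @examples
#' parse_electrode_id("B6_24") # well B6, column 2, row 4
#' @export
parse_electrode_id <- function(token, electrodes_per_side = 4L) {
  if (length(token) == 0) {
    stop("parse_electrode_id(): no token supplied")
  }
  token <- trimws(as.character(token))
  m <- regmatches(token, regexec("^([A-Za-z][0-9]+)[ ]?_([0-9])([0-9])$", token))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("parse_electrode_id(): malformed electrode token(s): ",
         paste(unique(token[bad]), collapse = ", "))
  }
  well <- toupper(vapply(m, `[[`, "", 2L))
  col <- as.integer(vapply(m, `[[`, "", 3L))
  row <- as.integer(vapply(m, `[[`, "", 4L))
  out_of_grid <- col < 1L | col > electrodes_per_side |
    row < 1L | row > electrodes_per_side
  if (any(out_of_grid)) {
    stop("parse_electrode_id(): electrode position outside the ",
         electrodes_per_side, "x", electrodes_per_side, " grid: ",
         paste(unique(token[out_of_grid]), collapse = ", "))
  }
  tibble::tibble(
    electrode = paste0(well, "_", col, row),
    well = well, elec_col = col, elec_row = row
  )
}

#' Format electrode identifiers
#'
#' Inverse of [parse_electrode_id()]: builds the canonical
#' `<well>_<col><row>` token.
#'
#' @param well Well label(s) such as "B6".
#' @param col,row Electrode column and row within the well.
#' @return Character vector of canonical tokens.
#' @export
format_electrode_id <- function(well, col, row) {
  stopifnot(length(well) == length(col), length(col) == length(row))
  if (any(col < 1 | row < 1 | col > 9 | row > 9)) {
    stop("format_electrode_id(): col and row must be single digits >= 1")
  }
  paste0(toupper(well), "_", as.integer(col), as.integer(row))
}
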