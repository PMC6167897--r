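#' Construct a cell table
#'
#' A cell table holds one segmented section worth of cells: one row per cell
#' with micrometre coordinates, binary marker-positivity flags (as emitted by
#' upstream image-analysis software), an optional cell radius, and slots for
#' the lineage and region labels assigned downstream. Coordinates follow the
#' image convention: x to the right, y increasing downward, origin at the
#' slide scan origin.
#'
#' @param cells data.frame with columns `cell_id`, `x_um`, `y_um`, optionally
#'   `radius_um`, one 0/1 column per marker, and optionally `lineage`,
#'   `region`, `field_id`.
#' @param markers character vector of marker column names (e.g. `c("PD1",
#'   "PDL1", "CD8")`).
#' @param specimen_id,section_id identifiers carried through all outputs.
#' @return An object of class `cell_table`: a list with elements
#'   `specimen_id`, `section_id`, `markers`, and `cells` (the data.frame).
#' @export
cell_table <- function(cells, markers, specimen_id = "specimen",
                       section_id = "section") {
  stopifnot(is.data.frame(cells))
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  needed <- c("cell_id", "x_um", "y_um")
  missing_cols <- setdiff(needed, names(cells))
  if (length(missing_cols) > 0)
    stop("cell table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!"radius_um" %in% names(cells)) cells$radius_um <- rep(0, nrow(cells))
  if (!"lineage" %in% names(cells))
    cells$lineage <- rep(NA_character_, nrow(cells))
  if (!"region" %in% names(cells)) cells$region <- rep("UNASSIGNED", nrow(cells))
  cells$cell_id <- as.character(cells$cell_id)
  if (anyDuplicated(cells$cell_id))
    stop("cell ids must be unique within a section")
  if (nrow(cells) > 0) {
    if (!all(is.finite(cells$x_um)) || !all(is.finite(cells$y_um)))
      stop("cell coordinates must be finite")
    if (any(cells$radius_um < 0)) stop("cell radius must be >= 0")
  }
  markers <- as.character(markers)
  for (m in markers) {
    if (!m %in% names(cells))
      stop("marker column not found in cell table: ", m)
    v <- cells[[m]]
    if (nrow(cells) > 0 && !all(v %in% c(0, 1)))
      stop("marker column '", m, "' must be strictly binary (0/1)")
    cells[[m]] <- as.integer(v)
  }
  structure(
    list(specimen_id = specimen_id, section_id = section_id,
         markers = markers, cells = cells),
    class = "cell_table"
  )
}

#' @export
print.cell_table <- function(x, ...) {
  cat("cell_table:", x$specimen_id, "/", x$section_id, "-",
      nrow(x$cells), "cells, markers:",
      paste(x$markers, collapse = ", "), "\n")
  reg <- table(x$cells$region)
  if (length(reg)) cat("  regions:",
      paste(names(reg), as.integer(reg), sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Number of cells in a cell table
#' @param x a `cell_table`.
#' @return integer count.
#' @export
n_cells <- function(x) {
  stopifnot(inherits(x, "cell_table"))
  nrow(x$cells)
}

#' Read a cell table from CSV
#'
#' Expects columns `cell_id`, `x_um`, `y_um`, optionally `radius_um`, and one
#' 0/1 column per marker. Row order and ids are preserved; unknown columns are
#' kept as-is in the underlying data.frame.
#'
#' @param path CSV file path.
#' @param markers marker column names to validate as binary flags. When `NULL`,
#'   every column whose values are all 0/1 (other than the reserved columns) is
#'   taken as a marker.
#' @param specimen_id,section_id identifiers; default to the file name.
#' @return a [cell_table()].
#' @export
read_cell_table <- function(path, markers = NULL,
                            specimen_id = NULL, section_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("x_um", "y_um") %in% names(df)))
    stop("cell table CSV must contain x_um and y_um coordinate columns: ", path)
  if (!"cell_id" %in% names(df))
    df$cell_id <- if (nrow(df)) as.character(seq_len(nrow(df))) else character(0)
  reserved <- c("cell_id", "x_um", "y_um", "radius_um", "lineage", "region",
                "field_id")
  if (is.null(markers)) {
    cand <- setdiff(names(df), reserved)
    is_flag <- vapply(cand, function(cn) {
      v <- df[[cn]]
      is.numeric(v) && (nrow(df) == 0 || all(v %in% c(0, 1)))
    }, logical(1))
    markers <- cand[is_flag]
  }
  base <- if (is.null(specimen_id)) sub("\\.csv$", "", basename(path)) else specimen_id
  sect <- if (is.null(section_id)) base else section_id
  cell_table(df, markers = markers, specimen_id = base, section_id = sect)
}

#' Write a cell table to CSV
#'
#' Round-trips losslessly with [read_cell_table()]: coordinates are written at
#' full precision (15 significant digits) and row order is preserved.
#'
#' @param x a `cell_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(x, path) {
  stopifnot(inherits(x, "cell_table"))
  df <- x$cells
  num <- vapply(df, is.numeric, logical(1))
  for (cn in names(df)[num]) {
    if (is.integer(df[[cn]])) next
    df[[cn]] <- formatC(df[[cn]], format = "g", digits = 17)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Threshold raw marker intensities into positivity flags
#'
#' Positivity calls normally come from upstream software; this helper derives
#' them from raw intensities with a fixed per-marker cutoff when only
#' intensities are available.
#'
#' @param x a `cell_table` whose data.frame carries `<marker>_intensity`
#'   columns.
#' @param cutoffs named numeric vector of per-marker intensity cutoffs; a cell
#'   is positive when intensity >= cutoff.
#' @return the `cell_table` with 0/1 marker columns added/overwritten.
#' @export
call_positivity <- function(x, cutoffs) {
  stopifnot(inherits(x, "cell_table"), !is.null(names(cutoffs)))
  for (m in names(cutoffs)) {
    icol <- paste0(m, "_intensity")
    if (!icol %in% names(x$cells))
      stop("no intensity column for marker: ", m)
    v <- x$cells[[icol]]
    if (any(v < 0, na.rm = TRUE)) stop("intensities must be nonnegative")
    x$cells[[m]] <- as.integer(v >= cutoffs[[m]])
  }
  x$markers <- union(x$markers, names(cutoffs))
  x
}

#' Specimen-level metadata record
#'
#' @param specimen_id identifier.
#' @param response RECIST category: CR, PR, SD, PD or NE.
#' @param viral_status Merkel cell polyomavirus status.
#' @param lesion primary lesion or metastasis.
#' @return a one-row data.frame with a derived logical `responder` column
#'   (TRUE for CR or PR).
#' @export
specimen_meta <- function(specimen_id,
                          response = c("CR", "PR", "SD", "PD", "NE"),
                          viral_status = c("unknown", "MCPyV+", "MCPyV-"),
                          lesion = c("primary", "metastasis")) {
  response <- match.arg(response)
  data.frame(
    specimen_id = specimen_id,
    response = response,
    responder = response %in% c("CR", "PR"),
    viral_status = match.arg(viral_status),
    lesion = match.arg(lesion),
    stringsAsFactors = FALSE
  )
}

#' Write derived metric records to CSV
#'
#' @param records data.frame of per-specimen metrics sharing one schema.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(records, path) {
  stopifnot(is.data.frame(records))
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
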