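#' Count source cells with a target cell within a fixed radius
#'
#' The spatial-interaction metric at the core of the analysis: the number of
#' source-marker cells (e.g. PD-1+) having at least one target-marker cell
#' (e.g. PD-L1+) within `radius` micrometres, together with that count
#' normalized by the total TME area. A source cell is counted once however
#' many targets are near it. The comparison is strict (`distance < radius`)
#' by default; set `inclusive = TRUE` for `<=`.
#'
#' Distances are centroid-to-centroid by default. With
#' `edge_mode = "surface"` the cell-surface convention is used: centroid
#' distance minus the two cell radii, floored at zero, which requires
#' `radius_um` columns in both tables.
#'
#' When `source` and `target` describe the same physical cells (same section
#' id), a cell is never its own neighbour: pairs with equal `cell_id` are
#' skipped. Set `exclude_self = FALSE` to disable, or `TRUE` to force id
#' matching across tables.
#'
#' @param source,target [cell_table()]s in one coordinate frame. Cells from
#'   serial sections must be registered first ([apply_transform()]); if the
#'   source table carries a registration RMSE above the radius a warning was
#'   already raised at fitting time.
#' @param radius interaction radius in micrometres (> 0); default 20.
#' @param area_mm2 normalizing area, usually the total (IT + PT) TME area.
#'   `NA` leaves the density unset.
#' @param edge_mode `"centroid"` or `"surface"`.
#' @param inclusive use `<=` instead of strict `<` at the radius.
#' @param exclude_self `NULL` (auto: exclude when section ids match),
#'   `TRUE` or `FALSE`.
#' @param keep_pairs also return the (source, nearest target, distance) pair
#'   list for counted cells, for plotting interaction lines.
#' @param restrict_tme drop source/target cells labelled OUTSIDE or EXCLUDED
#'   before counting (cells must then be region-labelled); default TRUE when
#'   region labels are assigned.
#' @return object of class `proximity_result`: list with `specimen_id`,
#'   `source_marker`/`target_marker` (when the tables carry a single implied
#'   marker this is informative only), `radius`, `count`, `n_source`,
#'   `density` (count / `area_mm2`), `indicator` (logical per source cell) and
#'   optionally `pairs`.
#' @export
count_within_radius <- function(source, target, radius = 20, area_mm2 = NA,
                                edge_mode = c("centroid", "surface"),
                                inclusive = FALSE, exclude_self = NULL,
                                keep_pairs = FALSE, restrict_tme = NULL) {
  edge_mode <- match.arg(edge_mode)
  stopifnot(inherits(source, "cell_table"), inherits(target, "cell_table"))
  if (!is.finite(radius) || radius <= 0) stop("radius must be > 0")

  sdf <- source$cells
  tdf <- target$cells
  if (is.null(restrict_tme))
    restrict_tme <- !any(c(sdf$region, tdf$region) == "UNASSIGNED")
  if (restrict_tme) {
    if (any(c(sdf$region, tdf$region) == "UNASSIGNED"))
      stop("restrict_tme = TRUE requires region-labelled cells")
    sdf <- sdf[sdf$region %in% c("IT", "PT"), , drop = FALSE]
    tdf <- tdf[tdf$region %in% c("IT", "PT"), , drop = FALSE]
  }
  if (is.null(exclude_self))
    exclude_self <- identical(source$section_id, target$section_id)

  ns <- nrow(sdf)
  indicator <- logical(ns)
  nn <- NULL
  if (ns > 0 && nrow(tdf) > 0) {
    ids <- if (exclude_self) {
      all_ids <- union(sdf$cell_id, tdf$cell_id)
      list(s = match(sdf$cell_id, all_ids), t = match(tdf$cell_id, all_ids))
    } else list(s = integer(0), t = integer(0))
    nn <- cpp_nearest(sdf$x_um, sdf$y_um, sdf$radius_um,
                      tdf$x_um, tdf$y_um, tdf$radius_um,
                      surface = (edge_mode == "surface"),
                      sid = ids$s, tid = ids$t)
    indicator <- !is.na(nn$distance) &
      (if (inclusive) nn$distance <= radius else nn$distance < radius)
  }
  out <- structure(list(
    specimen_id = source$specimen_id,
    source_section = source$section_id, target_section = target$section_id,
    radius = radius, edge_mode = edge_mode, inclusive = inclusive,
    count = sum(indicator), n_source = ns,
    area_mm2 = area_mm2,
    density = if (is.finite(area_mm2)) sum(indicator) / area_mm2 else NA_real_,
    indicator = indicator
  ), class = "proximity_result")
  if (keep_pairs && !is.null(nn)) {
    sel <- which(indicator)
    out$pairs <- data.frame(
      source_id = sdf$cell_id[sel],
      target_id = tdf$cell_id[nn$index[sel]],
      distance_um = nn$distance[sel],
      stringsAsFactors = FALSE)
  }
  out
}

#' @export
print.proximity_result <- function(x, ...) {
  cat(sprintf(
    "proximity_result: %d / %d source cells with a target within %s%g um%s\n",
    x$count, x$n_source, if (x$inclusive) "<= " else "< ", x$radius,
    if (is.finite(x$area_mm2))
      sprintf(" (density %.2f /mm^2 over %.3f mm^2)", x$density, x$area_mm2)
    else ""))
  invisible(x)
}

#' Transposed proximity metric
#'
#' Same contract as [count_within_radius()] with the roles of the two
#' populations reversed (e.g. PD-L1+ cells near a PD-1+ cell instead of
#' PD-1+ cells near a PD-L1+ cell). The metric is asymmetric in its count but
#' symmetric in existence: one direction is positive iff the other is.
#'
#' @inheritParams count_within_radius
#' @param ... passed to [count_within_radius()].
#' @return a `proximity_result`.
#' @export
transpose_metric <- function(source, target, ...) {
  count_within_radius(target, source, ...)
}

#' Nearest-neighbour distances between two populations
#'
#' One distance per source cell: the minimum distance to any target cell.
#'
#' @inheritParams count_within_radius
#' @return numeric vector of distances (um), one per source cell, with the
#'   matched target ids as the `target_id` attribute.
#' @export
nearest_neighbor_distances <- function(source, target,
                                       edge_mode = c("centroid", "surface"),
                                       exclude_self = NULL) {
  edge_mode <- match.arg(edge_mode)
  stopifnot(inherits(source, "cell_table"), inherits(target, "cell_table"))
  sdf <- source$cells
  tdf <- target$cells
  if (nrow(tdf) == 0) stop("target table is empty; distances undefined")
  if (nrow(sdf) == 0) return(numeric(0))
  if (is.null(exclude_self))
    exclude_self <- identical(source$section_id, target$section_id)
  ids <- if (exclude_self) {
    all_ids <- union(sdf$cell_id, tdf$cell_id)
    list(s = match(sdf$cell_id, all_ids), t = match(tdf$cell_id, all_ids))
  } else list(s = integer(0), t = integer(0))
  nn <- cpp_nearest(sdf$x_um, sdf$y_um, sdf$radius_um,
                    tdf$x_um, tdf$y_um, tdf$radius_um,
                    surface = (edge_mode == "surface"),
                    sid = ids$s, tid = ids$t)
  d <- nn$distance
  attr(d, "target_id") <- tdf$cell_id[nn$index]
  d
}

#' Subset a cell table to marker-positive cells
#'
#' @param cells a [cell_table()].
#' @param marker marker column; only cells with flag 1 are kept.
#' @return a `cell_table` of the positive cells.
#' @export
marker_positive <- function(cells, marker) {
  stopifnot(inherits(cells, "cell_table"))
  if (!marker %in% names(cells$cells))
    stop("marker not present in cell table: ", marker)
  cells$cells <- cells$cells[cells$cells[[marker]] == 1, , drop = FALSE]
  cells
}
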