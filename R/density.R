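#' Marker-positive cell density in a region
#'
#' Counts marker-positive cells carrying the requested region label and
#' divides by the corresponding region area. `TOTAL` pools the IT and PT
#' counts over the pooled IT + PT area (a union region, not a mean of the two
#' densities). Cells labelled `EXCLUDED` or `OUTSIDE` are never counted, and
#' excluded areas never enter the denominator.
#'
#' @param cells a region-labelled [cell_table()] (see [assign_regions()]).
#' @param partition the matching [partition_regions()] result.
#' @param marker marker column name.
#' @param region one of `"IT"`, `"PT"`, `"TOTAL"`.
#' @return data.frame with `specimen_id`, `marker`, `region`, `count`,
#'   `area_mm2`, `density` (cells/mm^2).
#' @export
compute_density <- function(cells, partition, marker,
                            region = c("TOTAL", "IT", "PT")) {
  region <- match.arg(region)
  stopifnot(inherits(cells, "cell_table"), inherits(partition, "region_partition"))
  if (!marker %in% names(cells$cells))
    stop("marker not present in cell table: ", marker)
  if (any(cells$cells$region == "UNASSIGNED"))
    stop("cells are not region-labelled; run assign_regions() first")
  lab <- cells$cells$region
  keep <- switch(region,
                 IT = lab == "IT",
                 PT = lab == "PT",
                 TOTAL = lab %in% c("IT", "PT"))
  area <- switch(region,
                 IT = partition$it_area_mm2,
                 PT = partition$pt_area_mm2,
                 TOTAL = partition$total_area_mm2)
  if (!is.finite(area) || area <= 0)
    stop("region ", region, " has zero area; density undefined")
  count <- sum(cells$cells[[marker]][keep] == 1)
  data.frame(specimen_id = cells$specimen_id, marker = marker,
             region = region, count = count, area_mm2 = area,
             density = count / area, stringsAsFactors = FALSE)
}

#' Densities for several markers and regions at once
#'
#' @inheritParams compute_density
#' @param markers character vector of marker columns.
#' @param regions character vector drawn from IT, PT, TOTAL.
#' @return row-bound data.frame of [compute_density()] results.
#' @export
density_table <- function(cells, partition, markers,
                          regions = c("IT", "PT", "TOTAL")) {
  do.call(rbind, lapply(markers, function(m)
    do.call(rbind, lapply(regions, function(r)
      compute_density(cells, partition, m, r)))))
}

#' Positive tissue-area fraction from binary masks
#'
#' The fraction of tissue surface area staining positive (total positive
#' pixels / total tissue pixels), with excluded pixels removed from both the
#' numerator and the denominator.
#'
#' @param mask binary/numeric matrix; nonzero = marker positive.
#' @param tissue_mask optional matrix of the same shape; nonzero = tissue.
#'   Defaults to all pixels.
#' @param exclusion_mask optional matrix of the same shape; nonzero pixels are
#'   dropped from the analysis.
#' @return data.frame with `positive_pixels`, `total_pixels`, `fraction`.
#' @export
area_fraction <- function(mask, tissue_mask = NULL, exclusion_mask = NULL) {
  mask <- as.matrix(mask)
  if (is.null(tissue_mask)) tissue_mask <- matrix(1, nrow(mask), ncol(mask))
  if (is.null(exclusion_mask)) exclusion_mask <- matrix(0, nrow(mask), ncol(mask))
  if (!identical(dim(mask), dim(as.matrix(tissue_mask))) ||
      !identical(dim(mask), dim(as.matrix(exclusion_mask))))
    stop("mask, tissue_mask and exclusion_mask must share the same shape")
  keep <- (as.matrix(tissue_mask) != 0) & (as.matrix(exclusion_mask) == 0)
  total <- sum(keep)
  if (total == 0) stop("tissue mask is empty after exclusions")
  pos <- sum(mask != 0 & keep)
  data.frame(positive_pixels = pos, total_pixels = total,
             fraction = pos / total)
}

#' Read a single-channel binary mask from TIFF or PNG
#'
#' Nonzero pixels are positive. Multi-channel images are reduced by their
#' first channel. The pixel size must be supplied by the caller; it is stored
#' as an attribute but not inferred from file headers.
#'
#' @param path `.tif`/`.tiff` or `.png` file.
#' @param pixel_size_um physical pixel edge length in micrometres.
#' @return numeric matrix with attribute `pixel_size_um`.
#' @export
read_mask <- function(path, pixel_size_um) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (missing(pixel_size_um) || !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be supplied and > 0")
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported mask format '", ext, "'; use PNG or TIFF"))
  if (length(dim(img)) == 3) img <- img[, , 1]
  attr(img, "pixel_size_um") <- pixel_size_um
  img
}

#' Pathologist-style PD-L1 score for a compartment
#'
#' Percent PD-L1-positive cells within the tumor-cell (TC), immune-cell (IC)
#' or combined compartment, reported three ways: the continuous percentage,
#' the standard discrete bin (`<1%`, `1%`, `2-4%`, `5-9%`, `10-19%`, then 10%
#' intervals up to `90-100%`), and the binomial call (positive at >= 1%).
#'
#' @param cells a [cell_table()] with lineage labels (see
#'   [classify_phenotypes()]) or an NSE tumor marker column.
#' @param compartment `"TC"`, `"IC"` or `"TC+IC"`.
#' @param pdl1_marker PD-L1 flag column name.
#' @param tumor_marker NSE flag column used to split TC from IC when no
#'   lineage labels are present.
#' @return data.frame with `compartment`, `n_cells`, `percent_positive`,
#'   `bin`, `binomial_call`.
#' @export
score_pdl1 <- function(cells, compartment = c("TC+IC", "TC", "IC"),
                       pdl1_marker = "PDL1", tumor_marker = "NSE") {
  compartment <- match.arg(compartment)
  stopifnot(inherits(cells, "cell_table"))
  df <- cells$cells
  if (!pdl1_marker %in% names(df))
    stop("PD-L1 marker column not found: ", pdl1_marker)
  is_tumor <- if (all(!is.na(df$lineage)) && nrow(df) > 0 &&
                  any(df$lineage == "tumor"))
    df$lineage == "tumor"
  else if (tumor_marker %in% names(df))
    df[[tumor_marker]] == 1
  else
    stop("need lineage labels or a '", tumor_marker,
         "' column to define the TC compartment")
  keep <- switch(compartment, TC = is_tumor, IC = !is_tumor,
                 `TC+IC` = rep(TRUE, nrow(df)))
  n <- sum(keep)
  if (n == 0) stop("compartment ", compartment, " contains no cells")
  pct <- 100 * sum(df[[pdl1_marker]][keep] == 1) / n
  data.frame(compartment = compartment, n_cells = n,
             percent_positive = pct, bin = pdl1_bin(pct),
             binomial_call = if (pct >= 1) "positive" else "negative",
             stringsAsFactors = FALSE)
}

#' Discrete PD-L1 expression bin for a percentage
#' @param percent value in \[0, 100\].
#' @return the bin label.
#' @export
pdl1_bin <- function(percent) {
  stopifnot(is.finite(percent), percent >= 0, percent <= 100)
  if (percent < 1) return("<1%")
  if (percent < 2) return("1%")
  if (percent < 5) return("2-4%")
  if (percent < 10) return("5-9%")
  lo <- as.integer(10 * (percent %/% 10))
  if (lo >= 90) return("90-100%")
  sprintf("%d-%d%%", lo, lo + 9L)
}
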