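#' Construct an annotation set
#'
#' Pathologist annotations for one section: tumor boundary polygon(s),
#' exclusion polygon(s) for acellular/necrotic areas, and an optional outer
#' tissue boundary. Polygons are simple (non-self-intersecting) rings stored
#' as n x 2 matrices of micrometre coordinates, not explicitly closed.
#'
#' @param tumor list of n x 2 coordinate matrices (or a single matrix).
#' @param exclusion list of n x 2 coordinate matrices.
#' @param tissue optional single n x 2 matrix bounding the tissue.
#' @return object of class `annotation_set`.
#' @export
annotation_set <- function(tumor, exclusion = list(), tissue = NULL) {
  as_ring_list <- function(p, what) {
    if (is.matrix(p)) p <- list(p)
    lapply(seq_along(p), function(i) {
      m <- p[[i]]
      if (!is.matrix(m) || ncol(m) != 2 || nrow(m) < 3)
        stop(what, " polygon ", i, " must be an n x 2 matrix with n >= 3")
      storage.mode(m) <- "double"
      if (!all(is.finite(m))) stop(what, " polygon ", i,
                                   " has non-finite coordinates")
      # drop an explicit closing vertex
      if (all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
      if (!is_simple_polygon(m))
        stop(what, " polygon ", i, " is self-intersecting")
      if (abs(polygon_area(m)) < 1e-9)
        stop(what, " polygon ", i, " is degenerate (zero area)")
      dimnames(m) <- NULL
      m
    })
  }
  tumor <- as_ring_list(tumor, "tumor")
  exclusion <- if (length(exclusion)) as_ring_list(exclusion, "exclusion") else list()
  if (!is.null(tissue)) tissue <- as_ring_list(tissue, "tissue")[[1]]
  structure(list(tumor = tumor, exclusion = exclusion, tissue = tissue),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", length(x$tumor), "tumor polygon(s),",
      length(x$exclusion), "exclusion polygon(s),",
      if (is.null(x$tissue)) "no tissue boundary" else "with tissue boundary",
      "\n")
  invisible(x)
}

#' Signed shoelace area of a polygon ring (um^2)
#' @param m n x 2 coordinate matrix (open ring).
#' @return signed area; positive for counter-clockwise vertex order in a
#'   y-down frame appears negative, callers typically take `abs()`.
#' @export
polygon_area <- function(m) {
  x <- m[, 1]; y <- m[, 2]
  j <- c(seq_len(nrow(m))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# TRUE when no two non-adjacent edges of the (open) ring intersect.
is_simple_polygon <- function(m) {
  n <- nrow(m)
  if (n < 3) return(FALSE)
  a1 <- m
  a2 <- m[c(2:n, 1), , drop = FALSE]
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    # edge i and edge n are adjacent (share vertex 1)
    if (i == 1) js <- js[js != n]
    if (!length(js)) next
    d1 <- cross(a1[i, 1], a1[i, 2], a2[i, 1], a2[i, 2], a1[js, 1], a1[js, 2])
    d2 <- cross(a1[i, 1], a1[i, 2], a2[i, 1], a2[i, 2], a2[js, 1], a2[js, 2])
    d3 <- cross(a1[js, 1], a1[js, 2], a2[js, 1], a2[js, 2],
                rep(a1[i, 1], length(js)), rep(a1[i, 2], length(js)))
    d4 <- cross(a1[js, 1], a1[js, 2], a2[js, 1], a2[js, 2],
                rep(a2[i, 1], length(js)), rep(a2[i, 2], length(js)))
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(FALSE)
  }
  TRUE
}

#' Read annotations from GeoJSON
#'
#' Expects a FeatureCollection whose features carry a `role` property in
#' `{tumor, exclusion, tissue}` and Polygon or MultiPolygon geometry.
#' Coordinates are interpreted as micrometres. MultiPolygon features are split
#' into one ring per part; interior rings (holes) are not supported and raise
#' an error naming the feature.
#'
#' @param path GeoJSON file.
#' @return an [annotation_set()].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("annotations must be a GeoJSON FeatureCollection: ", path)
  roles <- c("tumor", "exclusion", "tissue")
  polys <- list(tumor = list(), exclusion = list(), tissue = list())
  ring_to_matrix <- function(ring, label) {
    m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    storage.mode(m) <- "double"
    m
  }
  for (k in seq_along(gj$features)) {
    f <- gj$features[[k]]
    role <- f$properties$role
    if (is.null(role) || !role %in% roles)
      stop("feature ", k, " has role '", if (is.null(role)) "<missing>" else role,
           "'; allowed roles are: ", paste(roles, collapse = ", "))
    geom <- f$geometry
    parts <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop("feature ", k, " has unsupported geometry type: ", geom$type))
    for (p in parts) {
      if (length(p) > 1)
        stop("feature ", k, " has interior rings (holes), which are not supported")
      m <- ring_to_matrix(p[[1]], k)
      if (!is_simple_polygon(if (all(m[1, ] == m[nrow(m), ]))
                               m[-nrow(m), , drop = FALSE] else m))
        stop("feature ", k, " (role ", role, ") is self-intersecting")
      polys[[role]] <- c(polys[[role]], list(m))
    }
  }
  if (length(polys$tissue) > 1)
    stop("at most one tissue polygon is supported")
  annotation_set(tumor = polys$tumor, exclusion = polys$exclusion,
                 tissue = if (length(polys$tissue)) polys$tissue[[1]] else NULL)
}

#' Write annotations to GeoJSON
#'
#' @param ann an [annotation_set()].
#' @param path output path.
#' @param extra_properties optional named list merged into every feature's
#'   properties (e.g. band width for a serialized partition).
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path, extra_properties = list()) {
  stopifnot(inherits(ann, "annotation_set"))
  close_ring <- function(m) rbind(m, m[1, , drop = FALSE])
  feat <- function(m, role) {
    ring <- lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
    list(type = "Feature",
         properties = c(list(role = role), extra_properties),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  }
  features <- c(
    lapply(ann$tumor, function(m) feat(close_ring(m), "tumor")),
    lapply(ann$exclusion, function(m) feat(close_ring(m), "exclusion")),
    if (!is.null(ann$tissue)) list(feat(close_ring(ann$tissue), "tissue"))
  )
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
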