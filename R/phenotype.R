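#' Phenotype gating rules
#'
#' A rule assigns a lineage when all `requires` markers are positive and all
#' `forbids` markers are negative. Rules are evaluated in priority order
#' (rank 1 first) and a cell takes the first matching lineage; cells matching
#' no rule are `"other"`. The default hierarchy puts the tumor marker (NSE)
#' first so segmentation bleed of immune markers onto tumor cells cannot
#' re-label them, then CD8 T cells, Tregs (CD4+FoxP3+), CD4 effector T cells,
#' CD20+ B cells, and CD68+ macrophages.
#'
#' @param rules list of lists with fields `lineage`, `requires` (character),
#'   optional `forbids` (character), `priority` (unique integer rank).
#' @return object of class `phenotype_rules`.
#' @export
phenotype_rules <- function(rules = default_phenotype_rules()) {
  stopifnot(is.list(rules), length(rules) > 0)
  pr <- vapply(rules, function(r) as.integer(r$priority), integer(1))
  if (anyDuplicated(pr)) stop("rule priorities must be unique")
  nm <- vapply(rules, function(r) r$lineage, character(1))
  if (anyDuplicated(nm)) stop("lineage names must be unique")
  sig <- vapply(rules, function(r) paste(
    paste(sort(r$requires), collapse = ","), "|",
    paste(sort(if (is.null(r$forbids)) character(0) else r$forbids),
          collapse = ",")), character(1))
  if (anyDuplicated(sig)) stop("two rules share the same marker signature")
  structure(rules[order(pr)], class = "phenotype_rules")
}

#' @rdname phenotype_rules
#' @export
default_phenotype_rules <- function() {
  list(
    list(lineage = "tumor", requires = "NSE", priority = 1L),
    list(lineage = "CD8_T", requires = "CD8", priority = 2L),
    list(lineage = "Treg", requires = c("CD4", "FoxP3"), priority = 3L),
    list(lineage = "CD4_T", requires = "CD4", priority = 4L),
    list(lineage = "B_cell", requires = "CD20", priority = 5L),
    list(lineage = "macrophage", requires = "CD68", priority = 6L)
  )
}

#' Read phenotype rules from a YAML file
#'
#' Expects a top-level `rules:` sequence of mappings with keys `lineage`,
#' `requires`, optional `forbids`, `priority`.
#'
#' @param path YAML file.
#' @return a [phenotype_rules()] object.
#' @export
read_phenotype_rules <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$rules)) stop("YAML must have a top-level 'rules' sequence")
  phenotype_rules(lapply(obj$rules, function(r) {
    r$requires <- as.character(r$requires)
    if (!is.null(r$forbids)) r$forbids <- as.character(r$forbids)
    r
  }))
}

#' Assign a lineage to every cell
#'
#' PD-1 status is deliberately orthogonal: any lineage, including tumor, can
#' be PD-1 positive, so checkpoint co-expression survives gating. Cells
#' matching more than one rule are resolved by priority and tallied in the
#' `ambiguous` attribute of the returned table's `lineage` assignment.
#'
#' @param cells a [cell_table()].
#' @param rules a [phenotype_rules()] object.
#' @return the `cell_table` with `lineage` filled in; the number of
#'   multi-rule matches is in `attr(x$cells$lineage, "ambiguous")` and in
#'   `x$ambiguous_cells`.
#' @export
classify_phenotypes <- function(cells, rules = phenotype_rules()) {
  stopifnot(inherits(cells, "cell_table"))
  if (!inherits(rules, "phenotype_rules")) rules <- phenotype_rules(rules)
  df <- cells$cells
  used <- unique(unlist(lapply(rules, function(r) c(r$requires, r$forbids))))
  missing_m <- setdiff(used, names(df))
  if (length(missing_m))
    stop("rule references unknown marker(s): ", paste(missing_m, collapse = ", "))
  n <- nrow(df)
  lineage <- rep("other", n)
  matched <- matrix(FALSE, nrow = n, ncol = length(rules))
  for (k in seq_along(rules)) {
    r <- rules[[k]]
    ok <- rep(TRUE, n)
    for (m in r$requires) ok <- ok & df[[m]] == 1
    for (m in r$forbids) ok <- ok & df[[m]] == 0
    matched[, k] <- ok
  }
  if (n > 0) {
    first <- apply(matched, 1, function(z) if (any(z)) which(z)[1] else NA_integer_)
    hit <- !is.na(first)
    lineage[hit] <- vapply(rules[first[hit]], function(r) r$lineage, character(1))
  }
  cells$cells$lineage <- lineage
  cells$ambiguous_cells <- if (n > 0) sum(rowSums(matched) > 1) else 0L
  cells
}

#' Select immune hot-spot fields
#'
#' Picks the `k` high-power fields with the largest total immune-cell count
#' (all non-tumor lineages), emulating hot-spot selection along the
#' tumor-stroma interface. Ties are broken by field id so the selection is
#' deterministic and invariant to input order.
#'
#' @param fields data.frame with columns `field_id`, `immune_count` (or
#'   per-lineage counts from [summarize_fields()], in which case immune_count
#'   is derived), and optionally more.
#' @param k number of fields to keep (default 10).
#' @return the selected rows, ordered by decreasing count then field id.
#' @export
select_hotspot_fields <- function(fields, k = 10) {
  stopifnot(is.data.frame(fields), "field_id" %in% names(fields))
  if (k > nrow(fields))
    stop("k = ", k, " exceeds the ", nrow(fields), " available fields")
  cnt <- if ("immune_count" %in% names(fields)) fields$immune_count
         else stop("fields must have an immune_count column")
  ord <- order(-cnt, as.character(fields$field_id))
  out <- fields[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-field lineage counts and tumor-normalized fractions
#'
#' @param cells a lineage-labelled [cell_table()] whose data.frame carries a
#'   `field_id` column.
#' @param field_area_mm2 area of one high-power field.
#' @return data.frame with one row per field: lineage counts, tumor cell
#'   count, immune count, and per-lineage fractions normalized by the tumor
#'   cell count of the field.
#' @export
summarize_fields <- function(cells, field_area_mm2 = 0.335) {
  stopifnot(inherits(cells, "cell_table"))
  df <- cells$cells
  if (!"field_id" %in% names(df)) stop("cell table has no field_id column")
  if (any(is.na(df$lineage))) stop("cells are not lineage-labelled")
  lineages <- sort(unique(df$lineage))
  out <- do.call(rbind, lapply(split(df, df$field_id), function(fd) {
    cnts <- vapply(lineages, function(l) sum(fd$lineage == l), numeric(1))
    tum <- sum(fd$lineage == "tumor")
    row <- data.frame(field_id = fd$field_id[1],
                      immune_count = nrow(fd) - tum,
                      tumor_cell_count = tum,
                      area_mm2 = field_area_mm2,
                      stringsAsFactors = FALSE)
    for (l in lineages) row[[paste0("n_", l)]] <- cnts[[l]]
    for (l in setdiff(lineages, "tumor"))
      row[[paste0("frac_", l)]] <-
        if (tum > 0) cnts[[l]] / tum else NA_real_
    row
  }))
  rownames(out) <- NULL
  out
}

#' PD-1 co-expression summary across lineages
#'
#' Which cell types carry PD-1: densities of PD-1+ cells per lineage
#' (cells/mm^2 over the supplied area) and the composition of the PD-1+
#' population, including the FoxP3+ (Treg) share of the CD4+PD-1+ pool.
#'
#' @param cells a lineage-labelled [cell_table()] with a PD-1 flag column.
#' @param area_mm2 total analyzed area (> 0), e.g. number of fields times the
#'   field area.
#' @param pd1_marker PD-1 flag column name.
#' @return list with `densities` (data.frame lineage, n_pd1_pos, density),
#'   `composition` (share of each lineage within all PD-1+ cells),
#'   `treg_share_of_cd4_pd1` and `n_pd1_pos`.
#' @export
pd1_coexpression_summary <- function(cells, area_mm2, pd1_marker = "PD1") {
  stopifnot(inherits(cells, "cell_table"))
  if (!is.finite(area_mm2) || area_mm2 <= 0) stop("area_mm2 must be > 0")
  df <- cells$cells
  if (any(is.na(df$lineage))) stop("cells are not lineage-labelled")
  if (!pd1_marker %in% names(df)) stop("PD-1 column not found: ", pd1_marker)
  pos <- df[df[[pd1_marker]] == 1, , drop = FALSE]
  lineages <- sort(unique(df$lineage))
  dens <- data.frame(
    lineage = lineages,
    n_pd1_pos = vapply(lineages, function(l) sum(pos$lineage == l), numeric(1)),
    stringsAsFactors = FALSE)
  dens$density <- dens$n_pd1_pos / area_mm2
  npos <- nrow(pos)
  comp <- if (npos > 0) dens$n_pd1_pos / npos else rep(0, nrow(dens))
  names(comp) <- lineages
  cd4_pool <- sum(pos$lineage %in% c("CD4_T", "Treg"))
  treg_share <- if (cd4_pool > 0) sum(pos$lineage == "Treg") / cd4_pool else NA_real_
  list(densities = dens, composition = comp,
       treg_share_of_cd4_pd1 = treg_share, n_pd1_pos = npos)
}
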