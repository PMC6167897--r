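all_marker_combos <- function() {
  m <- expand.grid(NSE = 0:1, CD8 = 0:1, CD4 = 0:1, FoxP3 = 0:1,
                   CD20 = 0:1, CD68 = 0:1)
  m$cell_id <- seq_len(nrow(m))
  m$x_um <- seq_len(nrow(m)); m$y_um <- 0
  m
}

# independent truth-table oracle for the default hierarchy
oracle_lineage <- function(row) {
  if (row[["NSE"]] == 1) "tumor"
  else if (row[["CD8"]] == 1) "CD8_T"
  else if (row[["CD4"]] == 1 && row[["FoxP3"]] == 1) "Treg"
  else if (row[["CD4"]] == 1) "CD4_T"
  else if (row[["CD20"]] == 1) "B_cell"
  else if (row[["CD68"]] == 1) "macrophage"
  else "other"
}

test_that("classification agrees with the truth table over all combinations", {
  df <- all_marker_combos()
  ct <- cell_table(df, markers = c("NSE", "CD8", "CD4", "FoxP3", "CD20", "CD68"))
  ct <- classify_phenotypes(ct)
  expected <- vapply(seq_len(nrow(df)), function(i)
    oracle_lineage(df[i, ]), character(1))
  expect_identical(ct$cells$lineage, expected)
  # every cell has exactly one lineage; counts conserve
  expect_equal(sum(table(ct$cells$lineage)), nrow(df))
  # multi-rule matches are tallied
  multi <- sum(rowSums(df[, c("NSE", "CD8", "CD4", "CD20", "CD68")]) > 1 |
                 (df$CD4 == 1 & df$FoxP3 == 1))
  expect_equal(ct$ambiguous_cells, multi)
})

test_that("checkpoint flags stay orthogonal to lineage", {
  df <- data.frame(cell_id = 1:3, x_um = 1:3, y_um = 0,
                   NSE = c(0L, 0L, 1L), CD8 = c(1L, 0L, 0L),
                   CD4 = c(0L, 1L, 0L), FoxP3 = c(0L, 1L, 0L),
                   CD20 = 0L, CD68 = 0L, PD1 = c(1L, 1L, 1L))
  ct <- classify_phenotypes(cell_table(df, markers = names(df)[4:10]))
  expect_equal(ct$cells$lineage, c("CD8_T", "Treg", "tumor"))
  expect_equal(ct$cells$PD1, c(1L, 1L, 1L))  # tumor PD-1 retained
})

test_that("rules referencing unknown markers fail, custom hierarchies work", {
  df <- data.frame(cell_id = 1, x_um = 0, y_um = 0, CD8 = 1L)
  ct <- cell_table(df, markers = "CD8")
  expect_error(classify_phenotypes(ct), "unknown marker")
  custom <- phenotype_rules(list(
    list(lineage = "CD8_T", requires = "CD8", priority = 1L)))
  expect_equal(classify_phenotypes(ct, custom)$cells$lineage, "CD8_T")
  expect_error(phenotype_rules(list(
    list(lineage = "a", requires = "CD8", priority = 1L),
    list(lineage = "b", requires = "CD4", priority = 1L))), "unique")
})

test_that("rules load from YAML", {
  yf <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("rules:",
               "  - lineage: tumor", "    requires: NSE", "    priority: 1",
               "  - lineage: CD8_T", "    requires: CD8", "    priority: 2"),
             yf)
  rules <- read_phenotype_rules(yf)
  expect_s3_class(rules, "phenotype_rules")
  expect_equal(rules[[1]]$lineage, "tumor")
})

test_that("hot-spot selection takes the top-k immune fields deterministically", {
  set.seed(1)
  fields <- data.frame(field_id = sprintf("f%02d", 1:20),
                       immune_count = sample(100, 20))
  sel <- select_hotspot_fields(fields, k = 10)
  expect_equal(sort(sel$immune_count, decreasing = TRUE), sel$immune_count)
  expect_equal(sel$immune_count, sort(fields$immune_count, decreasing = TRUE)[1:10])
  # ties broken by field id
  tied <- data.frame(field_id = sprintf("f%02d", 5:1), immune_count = 7)
  expect_equal(select_hotspot_fields(tied, 3)$field_id, c("f01", "f02", "f03"))
  # invariant to input permutation
  perm <- fields[sample(20), ]
  expect_equal(select_hotspot_fields(perm, 10)$field_id, sel$field_id)
  expect_error(select_hotspot_fields(fields, 21), "exceeds")
})

test_that("field summaries normalize lineage counts by tumor cells", {
  df <- data.frame(
    cell_id = 1:10, x_um = 1:10, y_um = 0,
    NSE = c(rep(1L, 4), rep(0L, 6)), CD8 = c(rep(0L, 4), rep(1L, 4), 0L, 0L),
    CD4 = c(rep(0L, 8), 1L, 1L), FoxP3 = 0L, CD20 = 0L, CD68 = 0L,
    field_id = c(rep("f1", 7), rep("f2", 3)))
  ct <- classify_phenotypes(cell_table(df, markers = names(df)[4:8]))
  fs <- summarize_fields(ct, field_area_mm2 = 0.335)
  expect_equal(nrow(fs), 2)
  f1 <- fs[fs$field_id == "f1", ]
  expect_equal(f1$tumor_cell_count, 4)
  expect_equal(f1$frac_CD8_T, 3 / 4)
  expect_equal(f1$immune_count, 3)
})

test_that("PD-1 co-expression summary reports densities and composition", {
  df <- data.frame(
    cell_id = 1:14, x_um = 1:14, y_um = 0,
    NSE = 0L,
    CD8 = c(rep(1L, 4), rep(0L, 10)),
    CD4 = c(rep(0L, 4), rep(1L, 10)),
    FoxP3 = c(rep(0L, 4), rep(1L, 2), rep(0L, 8)),
    CD20 = 0L, CD68 = 0L,
    PD1 = c(1L, 1L, 0L, 0L, 1L, 1L, rep(1L, 8)))
  ct <- classify_phenotypes(cell_table(df, markers = names(df)[4:10]))
  s <- pd1_coexpression_summary(ct, area_mm2 = 2)
  # 10 CD4+PD-1+ cells of which 2 FoxP3+: Treg share 20%
  expect_equal(s$treg_share_of_cd4_pd1, 0.2)
  expect_equal(s$densities$density[s$densities$lineage == "CD8_T"], 1)  # 2/2mm^2
  expect_equal(sum(s$composition), 1)
  # no PD-1+ cells: all densities zero
  df0 <- df; df0$PD1 <- 0L
  ct0 <- classify_phenotypes(cell_table(df0, markers = names(df0)[4:10]))
  s0 <- pd1_coexpression_summary(ct0, area_mm2 = 2)
  expect_true(all(s0$densities$density == 0))
  expect_error(pd1_coexpression_summary(ct, area_mm2 = 0), "area")
})

test_that("composition is area-invariant while densities scale inversely", {
  sp <- simulate_specimen(sim_params(seed = 31,
                                     pd1_target_density = 90,
                                     cd8_target_density = 250,
                                     pdl1_target_density = 400))
  ct <- classify_phenotypes(sp$cells)
  s1 <- pd1_coexpression_summary(ct, area_mm2 = 1)
  s2 <- pd1_coexpression_summary(ct, area_mm2 = 2)
  expect_equal(s1$composition, s2$composition)
  expect_equal(s1$densities$density, 2 * s2$densities$density)
})
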