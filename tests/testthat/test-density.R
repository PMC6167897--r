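square_partition <- function(side = 1000, res = 2) {
  partition_regions(annotation_set(tumor = unit_square(side)),
                    band_width = 100, resolution_um = res)
}

test_that("density is count over region area, with TOTAL as the pooled region", {
  p <- square_partition()
  # 50 positive IT cells on a 0.5 x 1 mm strip tumor: density = count / area
  strip <- partition_regions(annotation_set(
    tumor = rbind(c(0, 0), c(500, 0), c(500, 1000), c(0, 1000))),
    band_width = 100, resolution_um = 1)
  ct <- make_table(runif(50, 10, 490), runif(50, 10, 990),
                   markers = list(PD1 = rep(1, 50)))
  ct <- assign_regions(ct, strip)
  d <- compute_density(ct, strip, "PD1", "IT")
  expect_equal(d$count, 50)
  expect_equal(d$density, 50 / strip$it_area_mm2, tolerance = 1e-12)
  expect_equal(d$density, 100, tolerance = 0.02)

  # no positive cells
  ct0 <- make_table(500, 500, markers = list(CD8 = 0))
  ct0 <- assign_regions(ct0, p)
  expect_equal(compute_density(ct0, p, "CD8", "IT")$density, 0)
})

test_that("TOTAL counts equal IT + PT counts for every marker", {
  sp <- simulate_specimen(sim_params(seed = 21, necrosis_prob = 1))
  for (m in sp$cells$markers) {
    it <- compute_density(sp$cells, sp$partition, m, "IT")
    pt <- compute_density(sp$cells, sp$partition, m, "PT")
    tot <- compute_density(sp$cells, sp$partition, m, "TOTAL")
    expect_equal(tot$count, it$count + pt$count)
    expect_equal(tot$area_mm2, it$area_mm2 + pt$area_mm2)
  }
})

test_that("excluded and outside cells never enter a density", {
  p <- partition_regions(annotation_set(
    tumor = unit_square(), exclusion = list(unit_square(200, c(100, 100)))),
    band_width = 100, resolution_um = 2)
  ct <- make_table(c(150, 500, 1500), c(150, 500, 1500),
                   markers = list(PD1 = c(1, 1, 1)))
  ct <- assign_regions(ct, p)
  expect_equal(ct$cells$region, c("EXCLUDED", "IT", "OUTSIDE"))
  expect_equal(compute_density(ct, p, "PD1", "TOTAL")$count, 1)
})

test_that("densities are invariant under a rigid motion of the whole specimen", {
  sp <- simulate_specimen(sim_params(seed = 22))
  tr <- random_rigid()
  moved_cells <- apply_transform(sp$cells, tr)
  moved_ann <- annotation_set(
    tumor = lapply(sp$geometry$tumor, transform_points, trans = tr),
    exclusion = lapply(sp$geometry$exclusion, transform_points, trans = tr))
  moved_part <- partition_regions(moved_ann, sp$partition$band_width,
                                  resolution_um = sp$partition$resolution_um)
  moved_cells <- assign_regions(moved_cells, moved_part)
  for (m in c("PD1", "CD8", "PDL1")) {
    a <- compute_density(sp$cells, sp$partition, m, "TOTAL")
    b <- compute_density(moved_cells, moved_part, m, "TOTAL")
    expect_equal(b$count, a$count)
    expect_equal(b$density, a$density, tolerance = 0.02)  # raster re-measured
  }
})

test_that("homogeneous Poisson intensity is recovered within 3 SD", {
  # 2 mm^2 tumor at 100 cells/mm^2
  big <- partition_regions(annotation_set(
    tumor = rbind(c(0, 0), c(2000, 0), c(2000, 1000), c(0, 1000))),
    band_width = 100, resolution_um = 2)
  set.seed(33)
  lambda <- 100
  n <- rpois(1, lambda * 2)
  ct <- make_table(runif(n, 0, 2000), runif(n, 0, 1000),
                   markers = list(CD8 = rep(1, n)))
  ct <- assign_regions(ct, big)
  d <- compute_density(ct, big, "CD8", "IT")
  sd3 <- 3 * sqrt(lambda * 2) / 2
  expect_lt(abs(d$density - lambda), sd3)
})

test_that("zero region area makes the density an explicit error", {
  p <- square_partition()
  p$pt_area_mm2 <- 0
  ct <- assign_regions(make_table(500, 500, markers = list(PD1 = 1)), p)
  expect_error(compute_density(ct, p, "PD1", "PT"), "zero area")
  expect_error(compute_density(ct, p, "XYZ", "IT"), "marker")
})

test_that("area fraction counts pixels with exclusions removed from both sides", {
  m <- matrix(0, 100, 100)
  expect_equal(area_fraction(m + 1)$fraction, 1)
  m[, 1:50] <- 1
  expect_equal(area_fraction(m)$fraction, 0.5)

  set.seed(4)
  mask <- matrix(0, 250, 400)
  mask[sample(length(mask), 12345)] <- 1
  af <- area_fraction(mask)
  expect_identical(af$positive_pixels, 12345L)
  expect_equal(af$fraction, 12345 / 100000)

  # rotation by 90 degrees leaves the fraction unchanged
  rot <- t(mask[nrow(mask):1, ])
  expect_equal(area_fraction(rot)$fraction, af$fraction)

  # excluded pixels leave numerator and denominator together
  excl <- matrix(0, 250, 400); excl[1:100, ] <- 1
  af2 <- area_fraction(mask, exclusion_mask = excl)
  keep <- mask[101:250, ]
  expect_equal(af2$fraction, sum(keep) / (150 * 400))
  expect_error(area_fraction(mask, tissue_mask = matrix(0, 250, 400)), "empty")
  expect_error(area_fraction(mask, tissue_mask = matrix(1, 10, 10)), "shape")
})

test_that("masks read back from PNG and TIFF with the supplied pixel size", {
  m <- matrix(0, 40, 60); m[5:20, 10:30] <- 1
  pf <- withr::local_tempfile(fileext = ".png")
  png::writePNG(m, pf)
  back <- read_mask(pf, pixel_size_um = 0.5)
  expect_equal(attr(back, "pixel_size_um"), 0.5)
  expect_equal(sum(back != 0), sum(m))
  tf <- withr::local_tempfile(fileext = ".tiff")
  tiff::writeTIFF(m, tf)
  expect_equal(sum(read_mask(tf, 1) != 0), sum(m))
  expect_error(read_mask(pf), "pixel_size_um")
})

test_that("PD-L1 scoring bins and binomial call follow the clinical convention", {
  tc <- function(n_pos, n_tot) {
    make_table(seq_len(n_tot), seq_len(n_tot),
               markers = list(NSE = rep(1, n_tot),
                              PDL1 = c(rep(1, n_pos), rep(0, n_tot - n_pos))))
  }
  s0 <- score_pdl1(tc(0, 200), "TC")
  expect_equal(s0$bin, "<1%")
  expect_equal(s0$binomial_call, "negative")
  s1 <- score_pdl1(tc(1, 100), "TC")
  expect_equal(s1$percent_positive, 1)
  expect_equal(s1$binomial_call, "positive")
  expect_equal(s1$bin, "1%")
  expect_equal(score_pdl1(tc(7, 100), "TC")$bin, "5-9%")
  expect_equal(score_pdl1(tc(15, 100), "TC")$bin, "10-19%")
  expect_equal(score_pdl1(tc(95, 100), "TC")$bin, "90-100%")
  expect_equal(pdl1_bin(3), "2-4%")
  expect_equal(pdl1_bin(25), "20-29%")
  expect_equal(pdl1_bin(100), "90-100%")
  expect_error(score_pdl1(tc(5, 10), "IC"), "no cells")
})
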