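test_that("within-radius counting is strict by default and once per source", {
  s <- make_table(0, 0, markers = list(PD1 = 1), section = "S")
  t1 <- make_table(c(0, 5), c(10, 0), markers = list(PDL1 = c(1, 1)),
                   section = "T")
  r <- count_within_radius(s, t1, radius = 20)
  expect_equal(r$count, 1)  # two targets near one source still count it once

  exact <- make_table(20, 0, markers = list(PDL1 = 1), section = "T")
  expect_equal(count_within_radius(s, exact, radius = 20)$count, 0)
  expect_equal(count_within_radius(s, exact, radius = 20,
                                   inclusive = TRUE)$count, 1)
})

test_that("the transposed metric is asymmetric in count, symmetric in existence", {
  a <- make_table(c(0, 10), c(0, 0), markers = list(PD1 = c(1, 1)),
                  section = "S")
  b <- make_table(5, 0, markers = list(PDL1 = 1), section = "T")
  ab <- count_within_radius(a, b, radius = 20)
  ba <- transpose_metric(a, b, radius = 20)
  expect_equal(ab$count, 2)
  expect_equal(ba$count, 1)
  expect_equal(ab$count > 0, ba$count > 0)

  set.seed(11)
  for (i in 1:20) {
    s <- make_table(runif(40, 0, 300), runif(40, 0, 300),
                    markers = list(M = rep(1, 40)), section = "S")
    t <- make_table(runif(30, 0, 300), runif(30, 0, 300),
                    markers = list(M = rep(1, 30)), section = "T")
    r <- runif(1, 1, 60)
    expect_equal(count_within_radius(s, t, r)$count > 0,
                 count_within_radius(t, s, r)$count > 0)
  }
})

test_that("nearest-neighbour distances match hand geometry and the oracle", {
  s <- make_table(0, 0, markers = list(M = 1), section = "S")
  t <- make_table(3, 4, markers = list(M = 1), section = "T")
  expect_equal(as.numeric(nearest_neighbor_distances(s, t)), 5)
  t2 <- make_table(c(0, 100), c(0, 0), markers = list(M = c(1, 1)),
                   section = "T")
  expect_equal(as.numeric(nearest_neighbor_distances(s, t2)), 0)
  expect_error(nearest_neighbor_distances(
    s, make_table(numeric(0), numeric(0), markers = list(M = integer(0)),
                  section = "T")), "empty")
})

test_that("grid index equals the exhaustive oracle on random instances", {
  set.seed(99)
  for (i in 1:40) {
    ns <- sample(5:600, 1); nt <- sample(5:600, 1)
    sx <- runif(ns, 0, 1000); sy <- runif(ns, 0, 1000)
    tx <- runif(nt, 0, 1000); ty <- runif(nt, 0, 1000)
    s <- make_table(sx, sy, markers = list(M = rep(1, ns)), section = "S")
    t <- make_table(tx, ty, markers = list(M = rep(1, nt)), section = "T")
    d <- as.numeric(nearest_neighbor_distances(s, t))
    expect_equal(d, bf_nn(sx, sy, tx, ty), tolerance = 1e-12)
    r <- runif(1, 2, 80)
    expect_identical(count_within_radius(s, t, r)$count,
                     bf_count_within(sx, sy, tx, ty, r))
  }
})

test_that("counts are monotone in the radius and rigid-motion invariant", {
  set.seed(5)
  s <- make_table(runif(300, 0, 1000), runif(300, 0, 1000),
                  markers = list(M = rep(1, 300)), section = "S")
  t <- make_table(runif(300, 0, 1000), runif(300, 0, 1000),
                  markers = list(M = rep(1, 300)), section = "T")
  radii <- c(1, 5, 10, 20, 40, 80)
  counts <- vapply(radii, function(r)
    count_within_radius(s, t, r)$count, numeric(1))
  expect_true(all(diff(counts) >= 0))

  tr <- random_rigid()
  s2 <- apply_transform(s, tr); t2 <- apply_transform(t, tr)
  expect_equal(count_within_radius(s2, t2, 20)$count,
               count_within_radius(s, t, 20)$count)
  expect_equal(as.numeric(nearest_neighbor_distances(s2, t2)),
               as.numeric(nearest_neighbor_distances(s, t)), tolerance = 1e-9)
})

test_that("count equals the number of sources with nn distance under the radius", {
  set.seed(6)
  s <- make_table(runif(400, 0, 800), runif(400, 0, 800),
                  markers = list(M = rep(1, 400)), section = "S")
  t <- make_table(runif(200, 0, 800), runif(200, 0, 800),
                  markers = list(M = rep(1, 200)), section = "T")
  nn <- as.numeric(nearest_neighbor_distances(s, t))
  for (r in c(5, 20, 50))
    expect_equal(count_within_radius(s, t, r)$count, sum(nn < r))
})

test_that("surface mode subtracts cell radii and floors at zero", {
  s <- make_table(0, 0, markers = list(M = 1), section = "S", radius = 4)
  t <- make_table(25, 0, markers = list(M = 1), section = "T", radius = 3)
  expect_equal(as.numeric(nearest_neighbor_distances(s, t, edge_mode = "surface")),
               25 - 4 - 3)
  expect_equal(count_within_radius(s, t, 20, edge_mode = "surface")$count, 1)
  expect_equal(count_within_radius(s, t, 18, edge_mode = "surface")$count, 0)
  # overlapping cells: surface distance floors at 0
  t0 <- make_table(5, 0, markers = list(M = 1), section = "T", radius = 3)
  expect_equal(as.numeric(nearest_neighbor_distances(s, t0, edge_mode = "surface")), 0)
})

test_that("a cell is never its own neighbour when tables share a section", {
  df <- data.frame(cell_id = c("a", "b"), x_um = c(0, 100), y_um = 0,
                   PD1 = c(1L, 0L), PDL1 = c(1L, 0L))
  ct <- cell_table(df, markers = c("PD1", "PDL1"), section_id = "A")
  src <- marker_positive(ct, "PD1")
  tgt <- marker_positive(ct, "PDL1")
  # the only PD-L1+ cell is the PD-1+ cell itself
  expect_equal(count_within_radius(src, tgt, 20)$count, 0)
  expect_equal(count_within_radius(src, tgt, 20, exclude_self = FALSE)$count, 1)
})

test_that("TME restriction drops OUTSIDE and EXCLUDED cells from both sides", {
  regions <- c("IT", "PT", "OUTSIDE", "EXCLUDED")
  s <- make_table(c(0, 1, 2, 3), rep(0, 4), markers = list(M = rep(1, 4)),
                  section = "S", region = regions)
  t <- make_table(c(0, 1, 2, 3), rep(5, 4), markers = list(M = rep(1, 4)),
                  section = "T", region = regions)
  r <- count_within_radius(s, t, 20, area_mm2 = 2)
  expect_equal(r$count, 2)          # only the IT and PT sources
  expect_equal(r$density, 1)        # 2 / 2 mm^2
  expect_equal(r$n_source, 2)
})

test_that("pair export lists each counted source with its nearest target", {
  set.seed(8)
  s <- make_table(runif(50, 0, 200), runif(50, 0, 200),
                  markers = list(M = rep(1, 50)), section = "S")
  t <- make_table(runif(50, 0, 200), runif(50, 0, 200),
                  markers = list(M = rep(1, 50)), section = "T")
  r <- count_within_radius(s, t, 25, keep_pairs = TRUE)
  expect_equal(nrow(r$pairs), r$count)
  expect_true(all(r$pairs$distance_um < 25))
  nn <- bf_nn(s$cells$x_um, s$cells$y_um, t$cells$x_um, t$cells$y_um)
  expect_equal(r$pairs$distance_um, nn[nn < 25], tolerance = 1e-12)
})

test_that("invalid radii are rejected", {
  s <- make_table(0, 0, markers = list(M = 1))
  expect_error(count_within_radius(s, s, radius = -5), "radius")
  expect_error(count_within_radius(s, s, radius = 0), "radius")
})
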