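#' Parameters for one synthetic specimen
#'
#' The generator emulates the spatial structure the analysis assumes: a
#' blob-shaped tumor nodule (radial Fourier perturbation of a disk), tumor
#' cells as a homogeneous Poisson process inside it, an immune infiltrate as
#' an inhomogeneous Poisson process whose intensity decays exponentially with
#' distance from the tumor-stroma interface on both sides (interface
#' enrichment), marker flags drawn per lineage, and PD-L1 assigned either
#' adaptively (logistic in the local PD-1+ cell count within the proximity
#' radius, i.e. ligand induced by attack) or constitutively (tumor-cell
#' Bernoulli, independent of infiltrate).
#'
#' When target densities are supplied, the matching intensities and
#' probabilities are solved from the realized geometry (intensity integral
#' over the TME raster times area), so cohort medians are calibrated in
#' expectation by construction rather than by rejection.
#'
#' @param seed RNG seed for this specimen (integer < 2^31 - 10). Geometry,
#'   cells and sectioning draw from streams seeded `seed`, `seed + 1`,
#'   `seed + 2` so each stage is individually reproducible.
#' @param tumor_radius_um mean tumor radius; `roughness` scales the radial
#'   harmonic amplitudes (0 gives a circle); `n_vertices` polygon resolution.
#' @param necrosis_prob probability of one necrotic exclusion blob;
#'   `necrosis_radius_frac` its radius as a fraction of the tumor radius.
#' @param tumor_intensity tumor cells per mm^2 inside the tumor.
#' @param immune_peak_intensity immune cells per mm^2 at the interface (used
#'   when `cd8_target_density` is `NULL`); `immune_decay_um` the exponential
#'   decay length of the infiltrate.
#' @param immune_composition probabilities of CD8 / CD4 / CD20 / CD68 lineage
#'   for an immune cell (sums to 1); `p_foxp3_given_cd4` the Treg share of
#'   CD4 cells; `p_nkp46` NK marker probability; `p_pd1_lymphoid` PD-1
#'   positivity of lymphoid cells (used when `pd1_target_density` is `NULL`).
#' @param pdl1_mode `"adaptive"`, `"constitutive"` or `"none"`.
#' @param adaptive_beta logistic slope per PD-1+ neighbour within
#'   `proximity_radius_um`; `adaptive_alpha` the intercept used when
#'   `pdl1_target_density` is `NULL`.
#' @param constitutive_pdl1_prob tumor-cell PD-L1 probability when
#'   `pdl1_target_density` is `NULL`.
#' @param pd1_target_density,pdl1_target_density,cd8_target_density optional
#'   calibration targets in cells/mm^2 over the total TME.
#' @param band_width peritumoral band width (um); `resolution_um` raster
#'   pixel size for area measurement; `proximity_radius_um` the interaction
#'   radius.
#' @param section_rotation_deg,section_offset_um ranges (+/-) of the random
#'   rigid transform between serial sections; `section_jitter_um` per-cell
#'   resectioning jitter SD; `section_dropout` per-cell loss probability;
#'   `landmark_n`, `landmark_noise_um` fiducial landmarks emitted for
#'   registration.
#' @param specimen_id identifier.
#' @return a `sim_params` list.
#' @export
sim_params <- function(seed = 1L,
                       specimen_id = sprintf("sim%05d", seed %% 100000L),
                       tumor_radius_um = 350, roughness = 0.15,
                       n_vertices = 96L,
                       necrosis_prob = 0.25, necrosis_radius_frac = 0.15,
                       tumor_intensity = 2500,
                       immune_peak_intensity = 800, immune_decay_um = 75,
                       immune_composition = c(CD8 = 0.45, CD4 = 0.35,
                                              CD20 = 0.08, CD68 = 0.12),
                       p_foxp3_given_cd4 = 0.22,
                       p_nkp46 = 0.002,
                       p_pd1_lymphoid = 0.12,
                       pdl1_mode = c("adaptive", "constitutive", "none"),
                       adaptive_beta = 0.8, adaptive_alpha = -4,
                       constitutive_pdl1_prob = 0.15,
                       pd1_target_density = NULL,
                       pdl1_target_density = NULL,
                       cd8_target_density = NULL,
                       band_width = 100, resolution_um = 3,
                       proximity_radius_um = 20,
                       section_rotation_deg = 10, section_offset_um = 100,
                       section_jitter_um = 1, section_dropout = 0.1,
                       landmark_n = 8L, landmark_noise_um = 0) {
  pdl1_mode <- match.arg(pdl1_mode)
  stopifnot(abs(sum(immune_composition) - 1) < 1e-9,
            all(immune_composition >= 0),
            p_foxp3_given_cd4 >= 0, p_foxp3_given_cd4 <= 1,
            p_pd1_lymphoid >= 0, p_pd1_lymphoid <= 1,
            tumor_intensity >= 0, immune_peak_intensity >= 0,
            immune_decay_um > 0, seed == as.integer(seed))
  as.list(environment())
}

#' Generate a synthetic tumor geometry
#'
#' One simple blob polygon per specimen: radial Fourier perturbation of a
#' disk (harmonics 2-6, amplitudes scaled by `roughness` and damped by
#' harmonic order). The radial construction is star-shaped and clamped away
#' from zero, so the polygon is simple by construction; the simplicity check
#' still runs and, defensively, regenerates with damped roughness if it ever
#' failed. Optionally adds one necrotic exclusion blob inside the tumor.
#'
#' @param params a [sim_params()] list.
#' @return an [annotation_set()].
#' @export
generate_geometry <- function(params) {
  set.seed(params$seed)
  R <- params$tumor_radius_um
  nv <- params$n_vertices
  rough <- params$roughness
  for (attempt in 1:5) {
    theta <- seq(0, 2 * pi, length.out = nv + 1)[-(nv + 1)]
    r <- rep(1, nv)
    for (k in 2:6) {
      a <- stats::rnorm(1, 0, rough / k)
      b <- stats::rnorm(1, 0, rough / k)
      r <- r + a * cos(k * theta) + b * sin(k * theta)
    }
    r <- pmin(pmax(r, 0.25), 2) * R
    poly <- cbind(r * cos(theta), r * sin(theta))
    if (is_simple_polygon(poly)) break
    rough <- rough * 0.5
    warning("tumor outline self-intersected; retrying with damped roughness")
  }
  exclusion <- list()
  if (stats::runif(1) < params$necrosis_prob) {
    ang <- stats::runif(1, 0, 2 * pi)
    rad <- stats::runif(1, 0, 0.4 * R)
    cx <- rad * cos(ang); cy <- rad * sin(ang)
    er <- params$necrosis_radius_frac * R
    th <- seq(0, 2 * pi, length.out = 49)[-49]
    exclusion <- list(cbind(cx + er * cos(th), cy + er * sin(th)))
  }
  annotation_set(tumor = poly, exclusion = exclusion)
}

# signed distance to the tumor-stroma interface (positive everywhere;
# measures distance to the boundary polyline from either side)
interface_distance <- function(x, y, annotations) {
  cpp_dist_to_boundary(x, y, annotations$tumor)
}

#' Simulate the cell population of one specimen
#'
#' Tumor cells are a homogeneous Poisson process inside the tumor polygon
#' (exclusions carved out); immune cells are an inhomogeneous Poisson process
#' with intensity `lambda0 * exp(-d / decay)` in the distance `d` to the
#' tumor-stroma interface, realized by thinning a homogeneous proposal.
#' Marker flags are drawn per the lineage probabilities; PD-L1 follows
#' `pdl1_mode` (see [sim_params()]). All cells get exact region labels.
#'
#' @param geometry an [annotation_set()] from [generate_geometry()].
#' @param params the [sim_params()] list.
#' @param partition optional precomputed [partition_regions()] result with
#'   `keep_raster = TRUE` (computed internally when missing).
#' @return a region-labelled [cell_table()] with markers NSE, CD8, CD4,
#'   FoxP3, CD20, CD68, NKP46, PD1, PDL1.
#' @export
simulate_cells <- function(geometry, params, partition = NULL) {
  if (is.null(partition))
    partition <- partition_regions(geometry, band_width = params$band_width,
                                   resolution_um = params$resolution_um,
                                   keep_raster = TRUE)
  if (is.null(partition$raster))
    stop("partition must be computed with keep_raster = TRUE")
  set.seed(params$seed + 1L)
  ras <- partition$raster
  px_mm2 <- ras$px^2 / UM2_PER_MM2

  # interface distance on the raster (both sides of the boundary)
  d_in <- sqrt(cpp_edt_sq(!ras$tumor)) * ras$px
  d_iface <- ifelse(ras$tumor, d_in, ras$dist_um)
  tme <- ras$it | ras$pt
  intensity_integral_mm2 <- sum(exp(-d_iface[tme] / params$immune_decay_um)) * px_mm2

  lambda0 <- if (!is.null(params$cd8_target_density)) {
    frac_cd8 <- params$immune_composition[["CD8"]]
    params$cd8_target_density * partition$total_area_mm2 /
      (frac_cd8 * max(intensity_integral_mm2, 1e-9))
  } else params$immune_peak_intensity

  bbox <- apply(do.call(rbind, geometry$tumor), 2, range)
  pad <- params$band_width + 2 * params$immune_decay_um
  xlim <- c(bbox[1, 1] - pad, bbox[2, 1] + pad)
  ylim <- c(bbox[1, 2] - pad, bbox[2, 2] + pad)
  bbox_mm2 <- diff(xlim) * diff(ylim) / UM2_PER_MM2

  # tumor cells: homogeneous Poisson inside the tumor polygons
  n_prop_t <- stats::rpois(1, params$tumor_intensity * bbox_mm2)
  tx <- stats::runif(n_prop_t, xlim[1], xlim[2])
  ty <- stats::runif(n_prop_t, ylim[1], ylim[2])
  keep_t <- cpp_points_in_any(tx, ty, geometry$tumor)
  if (length(geometry$exclusion))
    keep_t <- keep_t & !cpp_points_in_any(tx, ty, geometry$exclusion)
  tx <- tx[keep_t]; ty <- ty[keep_t]

  # immune cells: thinning of a homogeneous proposal at the peak intensity
  n_prop_i <- stats::rpois(1, lambda0 * bbox_mm2)
  ix <- stats::runif(n_prop_i, xlim[1], xlim[2])
  iy <- stats::runif(n_prop_i, ylim[1], ylim[2])
  d_i <- interface_distance(ix, iy, geometry)
  keep_i <- stats::runif(n_prop_i) < exp(-d_i / params$immune_decay_um)
  if (length(geometry$exclusion))
    keep_i <- keep_i & !cpp_points_in_any(ix, iy, geometry$exclusion)
  ix <- ix[keep_i]; iy <- iy[keep_i]

  nt <- length(tx); ni <- length(ix)
  comp <- params$immune_composition
  lin <- if (ni > 0)
    sample(names(comp), ni, replace = TRUE, prob = comp) else character(0)
  df <- data.frame(
    cell_id = sprintf("c%06d", seq_len(nt + ni)),
    x_um = c(tx, ix), y_um = c(ty, iy), radius_um = 0,
    NSE = c(rep(1L, nt), rep(0L, ni)),
    CD8 = c(rep(0L, nt), as.integer(lin == "CD8")),
    CD4 = c(rep(0L, nt), as.integer(lin == "CD4")),
    FoxP3 = 0L, CD20 = c(rep(0L, nt), as.integer(lin == "CD20")),
    CD68 = c(rep(0L, nt), as.integer(lin == "CD68")),
    NKP46 = 0L, PD1 = 0L, PDL1 = 0L,
    stringsAsFactors = FALSE)
  if (ni > 0) {
    imm <- nt + seq_len(ni)
    cd4 <- df$CD4[imm] == 1
    df$FoxP3[imm][cd4] <- stats::rbinom(sum(cd4), 1, params$p_foxp3_given_cd4)
    df$NKP46[imm] <- stats::rbinom(ni, 1, params$p_nkp46)
  }

  cells <- cell_table(df, markers = c("NSE", "CD8", "CD4", "FoxP3", "CD20",
                                      "CD68", "NKP46", "PD1", "PDL1"),
                      specimen_id = params$specimen_id,
                      section_id = paste0(params$specimen_id, "_A"))
  cells <- assign_regions(cells, partition)
  df <- cells$cells
  in_tme <- df$region %in% c("IT", "PT")

  # PD-1 on lymphoid cells (CD8 / CD4 / CD20), calibrated to the target
  lymphoid <- df$CD8 == 1 | df$CD4 == 1 | df$CD20 == 1
  p_pd1 <- if (!is.null(params$pd1_target_density)) {
    n_l <- sum(lymphoid & in_tme)
    if (n_l > 0)
      min(0.98, params$pd1_target_density * partition$total_area_mm2 / n_l)
    else 0
  } else params$p_pd1_lymphoid
  df$PD1[lymphoid] <- stats::rbinom(sum(lymphoid), 1, p_pd1)

  # PD-L1 per expression mode
  if (params$pdl1_mode == "adaptive") {
    k <- cpp_count_within(df$x_um, df$y_um,
                          df$x_um[df$PD1 == 1], df$y_um[df$PD1 == 1],
                          params$proximity_radius_um, FALSE,
                          seq_len(nrow(df)), which(df$PD1 == 1))
    beta <- params$adaptive_beta
    alpha <- if (!is.null(params$pdl1_target_density)) {
      target_n <- params$pdl1_target_density * partition$total_area_mm2
      expected <- function(a) sum(stats::plogis(a + beta * k[in_tme]))
      if (expected(12) <= target_n) 12
      else if (expected(-25) >= target_n) -25
      else stats::uniroot(function(a) expected(a) - target_n,
                          c(-25, 12), tol = 1e-8)$root
    } else params$adaptive_alpha
    df$PDL1 <- stats::rbinom(nrow(df), 1, stats::plogis(alpha + beta * k))
  } else if (params$pdl1_mode == "constitutive") {
    tum <- df$NSE == 1
    p_c <- if (!is.null(params$pdl1_target_density)) {
      n_t <- sum(tum & in_tme)
      if (n_t > 0)
        min(0.95, params$pdl1_target_density * partition$total_area_mm2 / n_t)
      else 0
    } else params$constitutive_pdl1_prob
    df$PDL1[tum] <- stats::rbinom(sum(tum), 1, p_c)
  }
  cells$cells <- df
  cells
}

#' Simulate one full specimen
#'
#' Geometry, partition and cells in one call.
#'
#' @param params a [sim_params()] list.
#' @return list with `params`, `geometry`, `partition` (rasters kept) and
#'   `cells`.
#' @export
simulate_specimen <- function(params) {
  geometry <- generate_geometry(params)
  partition <- partition_regions(geometry, band_width = params$band_width,
                                 resolution_um = params$resolution_um,
                                 keep_raster = TRUE)
  cells <- simulate_cells(geometry, params, partition)
  list(params = params, geometry = geometry, partition = partition,
       cells = cells)
}

#' Simulate serial sections with ground truth
#'
#' Section B is a rigid transform of section A plus per-cell jitter and
#' random dropout (sectioning loss). Fiducial landmark pairs and the
#' ground-truth aligning transform (B -> A) are returned for registration.
#'
#' @param cells section A as a [cell_table()].
#' @param params the [sim_params()] list.
#' @return list with `section_a`, `section_b`, `landmarks` (data.frame
#'   moving_x/y in B's frame, fixed_x/y in A's frame) and `true_transform`
#'   (the `affine2d` aligning B onto A).
#' @export
simulate_serial_sections <- function(cells, params) {
  stopifnot(inherits(cells, "cell_table"))
  set.seed(params$seed + 2L)
  ang <- stats::runif(1, -params$section_rotation_deg,
                      params$section_rotation_deg) * pi / 180
  off <- stats::runif(2, -params$section_offset_um, params$section_offset_um)
  Rm <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  t_ab <- structure(list(matrix = cbind(Rm, off), model = "rigid",
                         rmse = 0, n = 0L), class = "affine2d")

  section_b <- apply_transform(cells, t_ab)
  nb <- nrow(section_b$cells)
  if (nb > 0) {
    section_b$cells$x_um <- section_b$cells$x_um +
      stats::rnorm(nb, 0, params$section_jitter_um)
    section_b$cells$y_um <- section_b$cells$y_um +
      stats::rnorm(nb, 0, params$section_jitter_um)
    keep <- stats::runif(nb) >= params$section_dropout
    section_b$cells <- section_b$cells[keep, , drop = FALSE]
  }
  section_b$section_id <- paste0(cells$specimen_id, "_B")

  xy <- cells$cells[, c("x_um", "y_um")]
  lo <- if (nrow(xy)) apply(xy, 2, min) else c(0, 0)
  hi <- if (nrow(xy)) apply(xy, 2, max) else c(1, 1)
  lm_fixed <- cbind(stats::runif(params$landmark_n, lo[1], hi[1]),
                    stats::runif(params$landmark_n, lo[2], hi[2]))
  lm_moving <- transform_points(lm_fixed, t_ab) +
    matrix(stats::rnorm(2 * params$landmark_n, 0, params$landmark_noise_um),
           ncol = 2)
  landmarks <- data.frame(moving_x = lm_moving[, 1], moving_y = lm_moving[, 2],
                          fixed_x = lm_fixed[, 1], fixed_y = lm_fixed[, 2])
  list(section_a = cells, section_b = section_b, landmarks = landmarks,
       true_transform = invert_transform(t_ab))
}

#' Render a marker-positive mask from cells
#'
#' Stamps a disk of `spot_radius_um` around every marker-positive TME cell on
#' the partition raster; used to derive the positive tissue-area fraction the
#' way mask-based quantification would.
#'
#' @param cells a region-labelled [cell_table()].
#' @param partition a [partition_regions()] result with rasters kept.
#' @param marker marker column.
#' @param spot_radius_um stamped disk radius.
#' @return list of binary matrices: `mask` (positive), `tissue` (TME),
#'   `exclusion`.
#' @export
render_marker_mask <- function(cells, partition, marker, spot_radius_um = 5) {
  stopifnot(inherits(partition, "region_partition"))
  if (is.null(partition$raster)) stop("partition must keep rasters")
  ras <- partition$raster
  df <- cells$cells
  pos <- df[df[[marker]] == 1 & df$region %in% c("IT", "PT"), , drop = FALSE]
  seedm <- matrix(FALSE, ras$ny, ras$nx)
  if (nrow(pos) > 0) {
    j <- pmin(pmax(floor((pos$x_um - ras$x0) / ras$px), 0), ras$nx - 1) + 1
    i <- pmin(pmax(floor((pos$y_um - ras$y0) / ras$px), 0), ras$ny - 1) + 1
    seedm[cbind(i, j)] <- TRUE
  }
  mask <- if (any(seedm))
    sqrt(cpp_edt_sq(seedm)) * ras$px <= spot_radius_um
  else seedm
  list(mask = mask * 1, tissue = (ras$it | ras$pt) * 1,
       exclusion = ras$excluded * 1)
}

cohort_preset_names <- c("responder_like", "nonresponder_like", "archival_like")

# Per-specimen parameter draws for a named preset. Location parameters are
# the printed cohort medians; log-scale spreads are chosen so simulated
# ranges echo the printed ranges.
preset_draw <- function(preset, seed_i, specimen_id) {
  draw <- switch(preset,
    responder_like = list(
      pd1 = stats::rlnorm(1, log(70.7), 0.55),
      pdl1 = stats::rlnorm(1, log(855.4), 0.5),
      cd8 = stats::rlnorm(1, log(264), 0.9),
      mode = "adaptive"),
    nonresponder_like = list(
      pd1 = stats::rlnorm(1, log(6.7), 1.0),
      pdl1 = stats::rlnorm(1, log(245), 0.6),
      cd8 = stats::rlnorm(1, log(216.6), 0.9),
      mode = "constitutive"),
    archival_like = list(
      pd1 = stats::rlnorm(1, log(91), 0.7),
      pdl1 = stats::rlnorm(1, log(400), 0.6),
      cd8 = stats::rlnorm(1, log(240), 0.8),
      mode = "adaptive"),
    stop("unknown preset: ", preset))
  sim_params(seed = seed_i, specimen_id = specimen_id,
             pd1_target_density = draw$pd1,
             pdl1_target_density = draw$pdl1,
             cd8_target_density = draw$cd8,
             pdl1_mode = draw$mode)
}

#' Simulate a responder / non-responder cohort
#'
#' Draws per-specimen calibration targets from the preset distributions
#' (responder-like PD-1+ and PD-L1+ densities centred on 70.7 and 855.4
#' cells/mm^2 with adaptive PD-L1; non-responder-like centred on 6.7 and
#' 245.0 with constitutive PD-L1; CD8 densities drawn from overlapping
#' distributions in both groups so CD8 does not separate them), then runs
#' every specimen through the real pipeline — geometry, partition, cell
#' simulation, region assignment, density, proximity and area-fraction
#' metrics. No metric is short-cut analytically.
#'
#' @param n_r,n_nr number of responder-like and non-responder-like specimens.
#' @param seed cohort seed; per-specimen streams are derived from
#'   (seed, specimen index).
#' @param preset_r,preset_nr preset names (see `cohort_preset_names`).
#' @param keep_specimens keep the full specimen objects (geometry, cells).
#' @param resolution_um raster resolution passed to every specimen.
#' @return list with `records` (one row per specimen: group, responder flag
#'   and all derived metrics) and, when requested, `specimens`.
#' @export
simulate_cohort <- function(n_r = 17, n_nr = 8, seed = 1L,
                            preset_r = "responder_like",
                            preset_nr = "nonresponder_like",
                            keep_specimens = FALSE, resolution_um = 3,
                            band_width = 100, radius = 20) {
  stopifnot(n_r >= 1, n_nr >= 1)
  n <- n_r + n_nr
  groups <- c(rep(preset_r, n_r), rep(preset_nr, n_nr))
  responder <- c(rep(TRUE, n_r), rep(FALSE, n_nr))
  # specimen-level parameter draws from the cohort stream
  set.seed(seed)
  seeds_i <- (as.integer(seed %% 100000L) * 10007L +
                7919L * seq_len(n)) %% 2147483000L
  plist <- lapply(seq_len(n), function(i) {
    p <- preset_draw(groups[i], seeds_i[i],
                     sprintf("%s_%02d", if (responder[i]) "R" else "NR",
                             if (responder[i]) i else i - n_r))
    p$resolution_um <- resolution_um
    p$band_width <- band_width
    p
  })
  specimens <- vector("list", n)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- simulate_specimen(plist[[i]])
    records[[i]] <- cbind(
      data.frame(specimen_id = plist[[i]]$specimen_id,
                 group = groups[i], responder = responder[i],
                 response = if (responder[i]) "PR" else "PD",
                 pdl1_mode = plist[[i]]$pdl1_mode,
                 stringsAsFactors = FALSE),
      specimen_metrics(sp$cells, sp$partition, radius = radius))
    if (keep_specimens) specimens[[i]] <- sp
  }
  out <- list(records = do.call(rbind, records), seed = seed,
              n_r = n_r, n_nr = n_nr)
  if (keep_specimens) out$specimens <- specimens
  out
}

#' Derived spatial metrics for one specimen
#'
#' The per-specimen metric panel: total/IT/PT densities of PD-1+, CD8+ and
#' PD-L1+ cells, proximity densities (PD-1+ and CD8+ cells within the radius
#' of a PD-L1+ cell, and the transposed PD-L1-near-PD-1 metric), the PD-L1
#' positive tissue-area fraction from a rendered mask, and the percent of
#' cells PD-L1+.
#'
#' @param cells a region-labelled [cell_table()].
#' @param partition the matching [partition_regions()] result (rasters kept
#'   for the area-fraction metric; that metric is `NA` otherwise).
#' @param radius proximity radius (um).
#' @return one-row data.frame of metrics.
#' @export
specimen_metrics <- function(cells, partition, radius = 20) {
  dens <- function(m, r) compute_density(cells, partition, m, r)$density
  pd1 <- marker_positive(cells, "PD1")
  pdl1 <- marker_positive(cells, "PDL1")
  cd8 <- marker_positive(cells, "CD8")
  area <- partition$total_area_mm2
  prox <- function(src, tgt)
    count_within_radius(src, tgt, radius = radius, area_mm2 = area)$density
  af <- if (!is.null(partition$raster)) {
    mk <- render_marker_mask(cells, partition, "PDL1")
    area_fraction(mk$mask, mk$tissue, mk$exclusion)$fraction
  } else NA_real_
  n_tme <- sum(cells$cells$region %in% c("IT", "PT"))
  pdl1_pct <- if (n_tme > 0)
    100 * sum(cells$cells$PDL1 == 1 &
                cells$cells$region %in% c("IT", "PT")) / n_tme
  else NA_real_
  data.frame(
    pd1_total = dens("PD1", "TOTAL"), pd1_it = dens("PD1", "IT"),
    pd1_pt = dens("PD1", "PT"),
    cd8_total = dens("CD8", "TOTAL"),
    pdl1_total = dens("PDL1", "TOTAL"),
    prox_pd1_near_pdl1 = prox(pd1, pdl1),
    prox_cd8_near_pdl1 = prox(cd8, pdl1),
    prox_pdl1_near_pd1 = prox(pdl1, pd1),
    pdl1_area_fraction = af,
    pdl1_percent_cells = pdl1_pct,
    it_area_mm2 = partition$it_area_mm2,
    pt_area_mm2 = partition$pt_area_mm2,
    total_area_mm2 = area)
}
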