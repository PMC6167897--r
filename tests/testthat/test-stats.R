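test_that("small-sample Mann-Whitney p equals full enumeration", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$statistic, 0)
  expect_true(mw$exact)
  expect_equal(mw$p_value, 0.1)
  expect_equal(mw$p_value, mw_enum_p(c(1, 2, 3), c(4, 5, 6)))

  set.seed(1)
  for (i in 1:10) {
    a <- round(runif(sample(3:6, 1), 0, 100), 3)
    b <- round(runif(sample(3:6, 1), 0, 100), 3)
    expect_equal(mann_whitney(a, b)$p_value, mw_enum_p(a, b),
                 tolerance = 1e-12)
  }
})

test_that("the test is symmetric in group order and reports group summaries", {
  set.seed(2)
  a <- rnorm(10); b <- rnorm(12, 1)
  expect_equal(mann_whitney(a, b)$p_value, mann_whitney(b, a)$p_value)
  mw <- mann_whitney(a, b)
  expect_equal(mw$group_a$median, median(a))
  expect_equal(mw$group_a$n, 10)
  expect_true(mw$p_value >= 0 && mw$p_value <= 1)
  expect_error(mann_whitney(numeric(0), b), "non-empty")
})

test_that("exact and normal-approximation p agree closely at n = 8 vs 8", {
  set.seed(3)
  for (i in 1:25) {
    a <- rnorm(8); b <- rnorm(8, runif(1, -1, 1))
    exact_p <- mann_whitney(a, b)$p_value
    approx_p <- suppressWarnings(stats::wilcox.test(
      a, b, exact = FALSE, correct = TRUE))$p.value
    expect_lt(abs(exact_p - approx_p), 0.02)
  }
})

test_that("ties and constant data are handled without failure", {
  mw <- mann_whitney(c(1, 1, 2), c(1, 2, 2))
  expect_false(mw$exact)
  expect_true(mw$p_value >= 0 && mw$p_value <= 1)
  expect_equal(mann_whitney(rep(3, 5), rep(3, 4))$p_value, 1)
})

test_that("chi-square matches hand computation and is row-swap invariant", {
  ind <- chi_square(rbind(c(10, 10), c(10, 10)))
  expect_equal(ind$statistic, 0)
  expect_equal(ind$p_value, 1)
  diag40 <- chi_square(rbind(c(20, 0), c(0, 20)))
  expect_equal(diag40$statistic, 40)
  expect_equal(diag40$df, 1)
  swapped <- chi_square(rbind(c(0, 20), c(20, 0)))
  expect_equal(swapped$statistic, diag40$statistic)
  # Yates correction shrinks the 2x2 statistic
  expect_lt(chi_square(rbind(c(12, 5), c(4, 14)), yates = TRUE)$statistic,
            chi_square(rbind(c(12, 5), c(4, 14)))$statistic)
  expect_error(chi_square(rbind(c(0, 0), c(1, 2))), "degenerate")
})

test_that("quartiles partition by rank with ties to the lower quartile", {
  rec <- data.frame(specimen_id = letters[1:8], responder = rep(c(TRUE, FALSE), 4),
                    dens = 1:8)
  q <- quartile_stratify(rec, "dens")
  expect_equal(q$assignments$quartile[rec$dens %in% c(7, 8)], c("Q4", "Q4"))
  expect_equal(q$assignments$quartile[rec$dens %in% c(1, 2)], c("Q1", "Q1"))
  expect_equal(as.integer(table(q$assignments$quartile)), rep(2L, 4))

  # all responders in the top quartile
  rec2 <- data.frame(specimen_id = letters[1:8],
                     responder = c(rep(FALSE, 6), TRUE, TRUE), dens = 1:8)
  q2 <- quartile_stratify(rec2, "dens")
  expect_equal(q2$summary$responder_fraction[q2$summary$quartile == "Q4"], 1)
  expect_equal(q2$summary$responder_fraction[q2$summary$quartile == "Q1"], 0)

  # a tie across the Q3/Q4 boundary drops to the lower quartile
  rec3 <- data.frame(specimen_id = letters[1:8], responder = TRUE,
                     dens = c(1, 2, 3, 4, 5, 6, 6, 8))
  q3 <- quartile_stratify(rec3, "dens")
  tied <- q3$assignments$quartile[q3$assignments$value == 6]
  expect_equal(tied, c("Q3", "Q3"))
  expect_error(quartile_stratify(rec[1:3, ], "dens"), "at least 4")
})

test_that("quartile sizes differ by at most one for continuous metrics", {
  set.seed(4)
  for (n in c(16, 25, 26)) {
    rec <- data.frame(specimen_id = seq_len(n), responder = TRUE,
                      dens = rnorm(n))
    q <- quartile_stratify(rec, "dens")
    sizes <- table(q$assignments$quartile)
    expect_lte(diff(range(sizes)), 1)
    expect_equal(sum(sizes), n)
  }
})

test_that("perfectly mediated proximity has null adjusted signal", {
  set.seed(5)
  n <- 20
  rec <- data.frame(specimen_id = seq_len(n),
                    responder = rep(c(TRUE, FALSE), each = n / 2),
                    pd1_total = rlnorm(n, 3, 1))
  rec$pdl1_total <- rlnorm(n, 5, 0.5)
  rec$prox_pd1_near_pdl1 <- 0.6 * rec$pd1_total  # pure function of PD-1 density
  out <- density_adjusted_proximity(rec)
  expect_equal(out$p_value, 1)
})

test_that("adjusted comparison has power for genuine proximity signal", {
  set.seed(6)
  reject <- replicate(200, {
    n <- 24
    responder <- rep(c(TRUE, FALSE), each = 12)
    pd1 <- rlnorm(n, 3, 0.6)
    pdl1 <- rlnorm(n, 5, 0.6)
    # proximity carries responder signal beyond the marginals
    prox <- 0.4 * pd1 * exp(rnorm(n, 0, 0.25)) * ifelse(responder, 2.2, 1)
    rec <- data.frame(specimen_id = seq_len(n), responder = responder,
                      pd1_total = pd1, pdl1_total = pdl1,
                      prox_pd1_near_pdl1 = prox)
    density_adjusted_proximity(rec)$p_value < 0.05
  })
  expect_gte(mean(reject), 0.8)
})

test_that("permuting responder labels gives a uniform adjusted p-value", {
  set.seed(7)
  n <- 20
  rec <- data.frame(specimen_id = seq_len(n),
                    responder = rep(c(TRUE, FALSE), each = n / 2),
                    pd1_total = rlnorm(n, 3, 0.6),
                    pdl1_total = rlnorm(n, 5, 0.6))
  rec$prox_pd1_near_pdl1 <- 0.4 * rec$pd1_total * exp(rnorm(n, 0, 0.4))
  ps <- replicate(500, {
    rec$responder <- sample(rec$responder)
    density_adjusted_proximity(rec)$p_value
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_error(density_adjusted_proximity(rec[1:5, ]), "at least 6")
})
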