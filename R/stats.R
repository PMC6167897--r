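group_summary <- function(v) {
  list(n = length(v), median = stats::median(v),
       min = min(v), max = max(v),
       iqr_lo = unname(stats::quantile(v, 0.25)),
       iqr_hi = unname(stats::quantile(v, 0.75)))
}

#' Two-sided Mann-Whitney U test
#'
#' Compares a metric between two groups (typically responders vs
#' non-responders). The p-value is exact by enumeration over all label
#' assignments when the combined sample size is at most 16 and there are no
#' ties, and otherwise uses the normal approximation with tie and continuity
#' corrections — the conventions of `stats::wilcox.test`, which this wraps.
#'
#' @param group_a,group_b numeric vectors, each non-empty.
#' @return object of class `stat_result`: list with `test`, `statistic`
#'   (the U statistic for `group_a`), `p_value`, `exact` flag, and per-group
#'   summaries (n, median, range, IQR).
#' @export
mann_whitney <- function(group_a, group_b) {
  group_a <- as.numeric(group_a); group_b <- as.numeric(group_b)
  if (length(group_a) < 1 || length(group_b) < 1)
    stop("both groups must be non-empty")
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- (length(group_a) + length(group_b) <= 16) && !ties
  if (stats::sd(c(group_a, group_b)) == 0) {
    # all observations identical: no evidence either way
    wt <- list(statistic = length(group_a) * length(group_b) / 2, p.value = 1)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(
      group_a, group_b, alternative = "two.sided",
      exact = exact, correct = TRUE))
  }
  structure(list(
    test = "mann_whitney", statistic = unname(wt$statistic),
    p_value = wt$p.value, exact = exact,
    group_a = group_summary(group_a), group_b = group_summary(group_b)
  ), class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$test, x$statistic,
              x$p_value))
  for (g in c("group_a", "group_b")) {
    if (!is.null(x[[g]]))
      cat(sprintf("  %s: n = %d, median %.3g (range %.3g-%.3g)\n", g,
                  x[[g]]$n, x[[g]]$median, x[[g]]$min, x[[g]]$max))
  }
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Pearson chi-square test on a contingency table
#'
#' Used for the fraction of PD-L1+ tumors and the PD-L1 expression gradient
#' between groups. Wraps `stats::chisq.test` without continuity correction by
#' default; set `yates = TRUE` for the Yates-corrected 2x2 statistic.
#'
#' @param contingency matrix of nonnegative counts (2 x k typical).
#' @param yates apply the continuity correction (2x2 only).
#' @return a `stat_result` with the X-squared statistic, df and p-value.
#' @export
chi_square <- function(contingency, yates = FALSE) {
  m <- as.matrix(contingency)
  if (any(m < 0) || any(!is.finite(m))) stop("counts must be nonnegative")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("degenerate table: empty row or column")
  ct <- suppressWarnings(stats::chisq.test(m, correct = yates))
  structure(list(test = "chi_square", statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value,
                 yates = yates),
            class = "stat_result")
}

#' Quartile stratification of a cohort metric
#'
#' Splits specimens into quartiles Q1 (lowest) to Q4 (highest) of a metric by
#' rank, with quartile sizes differing by at most one; tied values are
#' assigned to the lower quartile. Reports the responder fraction per
#' quartile.
#'
#' @param records data.frame with `specimen_id`, a logical `responder`
#'   column, and the metric column.
#' @param metric metric column name.
#' @return list with `assignments` (data.frame specimen_id, value, quartile)
#'   and `summary` (per-quartile n, responders, responder fraction).
#' @export
quartile_stratify <- function(records, metric) {
  stopifnot(is.data.frame(records), metric %in% names(records),
            "responder" %in% names(records))
  ok <- !is.na(records[[metric]])
  rec <- records[ok, , drop = FALSE]
  n <- nrow(rec)
  if (n < 4) stop("need at least 4 non-missing values for quartiles")
  ord <- order(rec[[metric]], as.character(rec$specimen_id))
  pos <- integer(n)
  pos[ord] <- seq_len(n)
  q <- ceiling(4 * pos / n)
  # ties share the quartile of the lowest-ranked tied value
  for (qq in 4:2) {
    idx <- which(q == qq)
    for (i in idx) {
      lower <- rec[[metric]] == rec[[metric]][i] & q < qq
      if (any(lower)) q[i] <- min(q[lower])
    }
  }
  assignments <- data.frame(specimen_id = rec$specimen_id,
                            value = rec[[metric]],
                            quartile = paste0("Q", q),
                            stringsAsFactors = FALSE)
  summary <- do.call(rbind, lapply(1:4, function(k) {
    sel <- q == k
    data.frame(quartile = paste0("Q", k), n = sum(sel),
               responders = sum(rec$responder[sel]),
               responder_fraction = if (any(sel))
                 sum(rec$responder[sel]) / sum(sel) else NA_real_)
  }))
  list(metric = metric, assignments = assignments, summary = summary)
}

#' Density-adjusted proximity comparison
#'
#' Tests whether the proximity metric carries responder signal beyond the
#' marginal PD-1+ and PD-L1+ densities. The published analysis "controlled
#' for" the two densities without specifying how; here the proximity density
#' is regressed on the ranks of the two marginal densities (rank-based
#' residualization, robust to the heavy right-skew of density data) and the
#' residuals are compared between responders and non-responders with
#' [mann_whitney()]. The output is labelled with this interpretation.
#'
#' @param records data.frame with logical `responder` and the three metric
#'   columns.
#' @param proximity,pd1,pdl1 column names of the proximity density and the
#'   two marginal densities.
#' @return a `stat_result` (Mann-Whitney on residuals) with a `note` field
#'   documenting the adjustment method.
#' @export
density_adjusted_proximity <- function(records, proximity = "prox_pd1_near_pdl1",
                                       pd1 = "pd1_total", pdl1 = "pdl1_total") {
  stopifnot(is.data.frame(records), "responder" %in% names(records))
  need <- c(proximity, pd1, pdl1)
  if (!all(need %in% names(records)))
    stop("records must contain columns: ", paste(need, collapse = ", "))
  ok <- stats::complete.cases(records[, need])
  rec <- records[ok, , drop = FALSE]
  if (nrow(rec) < 6) stop("need at least 6 complete records for adjustment")
  ry <- rank(rec[[proximity]])
  r1 <- rank(rec[[pd1]])
  r2 <- rank(rec[[pdl1]])
  fit <- stats::lm(ry ~ r1 + r2)
  res <- stats::residuals(fit)
  res[abs(res) < 1e-8] <- 0  # exact mediation leaves only numerical noise
  out <- mann_whitney(res[rec$responder], res[!rec$responder])
  out$test <- "density_adjusted_proximity"
  out$note <- paste("rank-based residualization: proximity density regressed",
                    "on ranks of PD-1+ and PD-L1+ densities; residuals",
                    "compared R vs NR by Mann-Whitney")
  out
}

#' Benjamini-Hochberg adjustment helper (off by default in all outputs)
#'
#' The published comparisons are unadjusted; this is provided for users who
#' want FDR control across a metric panel.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values via `stats::p.adjust(method = "BH")`.
#' @export
adjust_bh <- function(p) stats::p.adjust(p, method = "BH")
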