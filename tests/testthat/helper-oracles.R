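# Fixtures and independent oracles shared across the suite.

# bare cell table from coordinates
make_table <- function(x, y, markers = list(), section = "A",
                       specimen = "spec", radius = 0, region = NULL) {
  df <- data.frame(cell_id = if (length(x)) paste0(section, seq_along(x))
                             else character(0),
                   x_um = x, y_um = y,
                   radius_um = rep(radius, length.out = length(x)),
                   stringsAsFactors = FALSE)
  for (m in names(markers)) df[[m]] <- as.integer(markers[[m]])
  if (!is.null(region)) df$region <- region
  cell_table(df, markers = names(markers), specimen_id = specimen,
             section_id = section)
}

unit_square <- function(side = 1000, origin = c(0, 0)) {
  rbind(origin,
        origin + c(side, 0),
        origin + c(side, side),
        origin + c(0, side))
}

# exhaustive O(ns x nt) pairwise distances
bf_cross_dist <- function(sx, sy, tx, ty) {
  sqrt(outer(sx, tx, "-")^2 + outer(sy, ty, "-")^2)
}

bf_nn <- function(sx, sy, tx, ty) apply(bf_cross_dist(sx, sy, tx, ty), 1, min)

bf_count_within <- function(sx, sy, tx, ty, r, inclusive = FALSE) {
  d <- bf_cross_dist(sx, sy, tx, ty)
  hit <- if (inclusive) d <= r else d < r
  sum(apply(hit, 1, any))
}

# exact distance from a point to an axis-aligned square [0, s] x [0, s]
square_dist <- function(x, y, s = 1000) {
  dx <- pmax(pmax(-x, x - s), 0)
  dy <- pmax(pmax(-y, y - s), 0)
  sqrt(dx^2 + dy^2)
}

# exact min distance from points to polygon boundary segments (R-side)
r_dist_to_ring <- function(px, py, ring) {
  n <- nrow(ring)
  best <- rep(Inf, length(px))
  for (a in seq_len(n)) {
    b <- if (a == 1) n else a - 1
    x1 <- ring[b, 1]; y1 <- ring[b, 2]; x2 <- ring[a, 1]; y2 <- ring[a, 2]
    l2 <- (x2 - x1)^2 + (y2 - y1)^2
    t <- if (l2 > 0) pmin(pmax(((px - x1) * (x2 - x1) +
                                  (py - y1) * (y2 - y1)) / l2, 0), 1) else 0
    d <- sqrt((x1 + t * (x2 - x1) - px)^2 + (y1 + t * (y2 - y1) - py)^2)
    best <- pmin(best, d)
  }
  best
}

# exact two-sided Mann-Whitney p by enumeration over all label assignments
mw_enum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  u_stat <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  obs <- u_stat(seq_len(na))
  combos <- utils::combn(n, na)
  us <- apply(combos, 2, u_stat)
  mu <- na * (n - na) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# random rigid transform as an affine2d
random_rigid <- function() {
  a <- stats::runif(1, -pi, pi)
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  structure(list(matrix = cbind(R, stats::runif(2, -500, 500)),
                 model = "rigid", rmse = 0, n = 0L), class = "affine2d")
}
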