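#' Fit a 2D transform between serial-section landmark sets
#'
#' Serial sections stained for different markers are brought into one
#' coordinate frame ("Z-stacked") by least-squares alignment of matched
#' landmark pairs. The rigid and similarity models are solved in closed form
#' by orthogonal Procrustes (SVD of the cross-covariance), with reflections
#' disallowed; the affine model is an ordinary least-squares fit with six free
#' coefficients.
#'
#' @param moving n x 2 matrix of landmark coordinates on the section to be
#'   transformed (um).
#' @param fixed n x 2 matrix of the matching landmarks on the reference
#'   section.
#' @param model `"rigid"` (rotation + translation), `"similarity"` (adds a
#'   global scale), or `"affine"`.
#' @return object of class `affine2d`: list with `matrix` (2 x 3 coefficients
#'   mapping (x, y, 1) to (x', y')), `model`, `rmse` (root-mean-square residual
#'   in um) and `n` landmarks. A warning is raised when the residual RMSE
#'   exceeds 20 um, the proximity radius, since within-radius counts across
#'   sections are then unreliable.
#' @export
fit_affine <- function(moving, fixed, model = c("rigid", "similarity", "affine")) {
  model <- match.arg(model)
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  storage.mode(moving) <- "double"; storage.mode(fixed) <- "double"
  if (ncol(moving) != 2 || ncol(fixed) != 2 || nrow(moving) != nrow(fixed))
    stop("moving and fixed must be n x 2 matrices with matching rows")
  n <- nrow(moving)
  min_n <- if (model == "affine") 3L else 2L
  if (n < min_n)
    stop("model '", model, "' needs at least ", min_n, " landmark pairs")
  if (n >= 2 && nrow(unique(moving)) < 2)
    stop("landmarks are degenerate (coincident points)")

  if (model == "affine") {
    X <- cbind(moving, 1)
    if (qr(X)$rank < 3)
      stop("landmarks are collinear; affine fit is underdetermined")
    beta <- qr.solve(X, fixed)              # 3 x 2
    A <- t(beta)                            # 2 x 3, [linear | translation]
    A <- A[, c(1, 2, 3), drop = FALSE]
  } else {
    mu_m <- colMeans(moving); mu_f <- colMeans(fixed)
    Xc <- sweep(moving, 2, mu_m); Yc <- sweep(fixed, 2, mu_f)
    H <- crossprod(Xc, Yc)                  # 2 x 2 cross-covariance
    sv <- svd(H)
    R <- sv$v %*% t(sv$u)
    if (det(R) < 0)
      stop("landmarks require a reflection, which '", model,
           "' does not allow; use model = 'affine'")
    s <- 1
    if (model == "similarity") {
      denom <- sum(Xc^2)
      if (denom <= 0) stop("landmarks are degenerate (coincident points)")
      s <- sum(sv$d) / denom
    } else {
      if (sum(Xc^2) <= 0) stop("landmarks are degenerate (coincident points)")
    }
    t_vec <- mu_f - s * as.vector(R %*% mu_m)
    A <- cbind(s * R, t_vec)
  }
  if (abs(det(A[, 1:2])) < 1e-12)
    stop("fitted linear part is singular")

  pred <- t(A[, 1:2] %*% t(moving) + A[, 3])
  rmse <- sqrt(mean(rowSums((fixed - pred)^2)))
  out <- structure(list(matrix = unname(A), model = model, rmse = rmse, n = n),
                   class = "affine2d")
  if (rmse > 20)
    warning(sprintf(paste0(
      "registration residual RMSE %.1f um exceeds the 20 um proximity ",
      "radius; cross-section proximity counts will be unreliable"), rmse))
  out
}

#' @export
print.affine2d <- function(x, ...) {
  cat(sprintf("affine2d (%s): RMSE %.4g um over %d landmarks\n",
              x$model, x$rmse, x$n))
  print(round(x$matrix, 6))
  invisible(x)
}

#' Identity transform
#' @return an `affine2d` mapping every point to itself.
#' @export
identity_transform <- function() {
  structure(list(matrix = cbind(diag(2), c(0, 0)), model = "rigid",
                 rmse = 0, n = 0L), class = "affine2d")
}

#' Invert a 2D affine transform
#' @param trans an `affine2d`.
#' @return the inverse `affine2d`.
#' @export
invert_transform <- function(trans) {
  stopifnot(inherits(trans, "affine2d"))
  L <- trans$matrix[, 1:2]
  Linv <- solve(L)
  structure(list(matrix = cbind(Linv, -Linv %*% trans$matrix[, 3]),
                 model = trans$model, rmse = trans$rmse, n = trans$n),
            class = "affine2d")
}

#' Apply a transform to a cell table
#'
#' Maps the coordinates; every non-coordinate field (ids, flags, labels,
#' radii) is untouched.
#'
#' @param cells a [cell_table()].
#' @param trans an `affine2d` from [fit_affine()].
#' @return the transformed `cell_table`.
#' @export
apply_transform <- function(cells, trans) {
  stopifnot(inherits(cells, "cell_table"), inherits(trans, "affine2d"))
  if (nrow(cells$cells) == 0) return(cells)
  xy <- cbind(cells$cells$x_um, cells$cells$y_um)
  new <- t(trans$matrix[, 1:2] %*% t(xy) + trans$matrix[, 3])
  cells$cells$x_um <- new[, 1]
  cells$cells$y_um <- new[, 2]
  cells
}

#' Apply a transform to raw coordinates
#' @param xy n x 2 matrix.
#' @param trans an `affine2d`.
#' @return n x 2 matrix of mapped coordinates.
#' @export
transform_points <- function(xy, trans) {
  stopifnot(inherits(trans, "affine2d"))
  xy <- as.matrix(xy)
  t(trans$matrix[, 1:2] %*% t(xy) + trans$matrix[, 3])
}

#' Serialize / deserialize a transform as JSON (6 coefficients, row-major)
#' @param trans an `affine2d`.
#' @param path file path.
#' @return `write_transform` returns `path` invisibly; `read_transform`
#'   returns the `affine2d`.
#' @export
write_transform <- function(trans, path) {
  stopifnot(inherits(trans, "affine2d"))
  jsonlite::write_json(
    list(model = trans$model, rmse = trans$rmse, n = trans$n,
         coefficients = as.vector(t(trans$matrix))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::fromJSON(path)
  m <- matrix(obj$coefficients, nrow = 2, byrow = TRUE)
  structure(list(matrix = m, model = obj$model, rmse = obj$rmse,
                 n = as.integer(obj$n)),
            class = "affine2d")
}

#' Read landmark pairs from CSV
#'
#' Expects columns `moving_x`, `moving_y`, `fixed_x`, `fixed_y` (um).
#' @param path CSV path.
#' @return list with `moving` and `fixed` n x 2 matrices.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path)
  need <- c("moving_x", "moving_y", "fixed_x", "fixed_y")
  if (!all(need %in% names(df)))
    stop("landmark CSV needs columns: ", paste(need, collapse = ", "))
  list(moving = cbind(df$moving_x, df$moving_y),
       fixed = cbind(df$fixed_x, df$fixed_y))
}
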