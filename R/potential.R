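# Scalar-potential reconstruction of a bias field: least-squares phi with
# -grad(phi) approximating the interpolated field; isoclines are the level
# sets of phi (bias vectors cross them perpendicularly, pointing downhill).

#' Fit a scalar potential to a bias map
#'
#' Finds the scalar field `phi` on a regular grid minimizing
#' `sum ||grad(phi) + F||^2 + lambda * ||L phi||^2`, where `F` is the bias
#' field sampled (via [interpolate_bias()]) at the grid nodes, the gradient is
#' taken by centered differences (second-order one-sided at the grid
#' boundary), and `L` is
#' the 5-point Laplacian used as a Tikhonov smoother. The additive constant is
#' fixed so that `phi = 0` at the node nearest the center target; forces point
#' downhill (`F` approximately `-grad(phi)`).
#'
#' @param map a `bias_map` from [aggregate_bias_map()], or any list with a
#'   `measurements` data.frame.
#' @param grid_spacing node spacing, cm.
#' @param lambda Laplacian smoothing weight.
#' @param expand margin added around the measured bounding box, cm.
#' @param center reference point where `phi` is pinned to 0 (default the
#'   center target, `c(0, 0)`).
#' @return object of class `potential_map`: list with `grid` (data.frame of
#'   node x, y), `phi` (N.cm, matrix nx x ny), `x`, `y` (node coordinate
#'   vectors), and `fit_residual` (RMS of `grad(phi) + F`, N).
#' @export
fit_potential <- function(map, grid_spacing = 1, lambda = 1e-3, expand = 0,
                          center = c(0, 0)) {
  meas <- map$measurements
  xr <- range(meas$x) + c(-expand, expand)
  yr <- range(meas$y) + c(-expand, expand)
  xs <- seq(xr[1], xr[2], by = grid_spacing)
  ys <- seq(yr[1], yr[2], by = grid_spacing)
  nx <- length(xs); ny <- length(ys)
  if (nx < 3L || ny < 3L) stop("grid degenerate (< 3 x 3 nodes)",
                               call. = FALSE)
  n <- nx * ny
  id <- function(i, j) (j - 1L) * nx + i  # column-major over (i = x, j = y)

  grid <- expand.grid(x = xs, y = ys)
  if (is.null(map$.tri) && nrow(meas) >= 3) {
    map$.tri <- delaunay_triangulate(as.matrix(meas[, c("x", "y")]))
  }
  F <- t(apply(grid, 1, function(p) {
    as.numeric(interpolate_bias(map, as.numeric(p)))
  }))

  h <- grid_spacing
  add <- function(lst, r, c, v) { lst[[length(lst) + 1L]] <- cbind(r, c, v); lst }
  ex <- list(); ey <- list()
  row_ct <- 0L
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    row_ct <- row_ct + 1L
    if (i == 1L) {
      # second-order one-sided: exact on quadratics, like the interior rows
      ex <- add(ex, row_ct, id(1L, j), -3 / (2 * h))
      ex <- add(ex, row_ct, id(2L, j), 4 / (2 * h))
      ex <- add(ex, row_ct, id(3L, j), -1 / (2 * h))
    } else if (i == nx) {
      ex <- add(ex, row_ct, id(nx, j), 3 / (2 * h))
      ex <- add(ex, row_ct, id(nx - 1L, j), -4 / (2 * h))
      ex <- add(ex, row_ct, id(nx - 2L, j), 1 / (2 * h))
    } else {
      ex <- add(ex, row_ct, id(i + 1L, j), 1 / (2 * h))
      ex <- add(ex, row_ct, id(i - 1L, j), -1 / (2 * h))
    }
    if (j == 1L) {
      ey <- add(ey, row_ct, id(i, 1L), -3 / (2 * h))
      ey <- add(ey, row_ct, id(i, 2L), 4 / (2 * h))
      ey <- add(ey, row_ct, id(i, 3L), -1 / (2 * h))
    } else if (j == ny) {
      ey <- add(ey, row_ct, id(i, ny), 3 / (2 * h))
      ey <- add(ey, row_ct, id(i, ny - 1L), -4 / (2 * h))
      ey <- add(ey, row_ct, id(i, ny - 2L), 1 / (2 * h))
    } else {
      ey <- add(ey, row_ct, id(i, j + 1L), 1 / (2 * h))
      ey <- add(ey, row_ct, id(i, j - 1L), -1 / (2 * h))
    }
  }
  ex <- do.call(rbind, ex); ey <- do.call(rbind, ey)
  Gx <- Matrix::sparseMatrix(i = ex[, 1], j = ex[, 2], x = ex[, 3],
                             dims = c(n, n))
  Gy <- Matrix::sparseMatrix(i = ey[, 1], j = ey[, 2], x = ey[, 3],
                             dims = c(n, n))

  # 5-point Laplacian on interior nodes
  el <- list(); row_l <- 0L
  for (j in 2:(ny - 1)) for (i in 2:(nx - 1)) {
    row_l <- row_l + 1L
    el <- add(el, row_l, id(i, j), -4 / h^2)
    el <- add(el, row_l, id(i + 1L, j), 1 / h^2)
    el <- add(el, row_l, id(i - 1L, j), 1 / h^2)
    el <- add(el, row_l, id(i, j + 1L), 1 / h^2)
    el <- add(el, row_l, id(i, j - 1L), 1 / h^2)
  }
  el <- do.call(rbind, el)
  L <- Matrix::sparseMatrix(i = el[, 1], j = el[, 2], x = el[, 3],
                            dims = c(row_l, n))

  A <- Matrix::t(Gx) %*% Gx + Matrix::t(Gy) %*% Gy +
    lambda * Matrix::t(L) %*% L
  b <- -(Matrix::t(Gx) %*% F[, 1] + Matrix::t(Gy) %*% F[, 2])
  # pin the gauge (constant offset) at the node nearest `center`: A has the
  # constant vector in its null space, so adding a penalty on phi[ic] selects
  # the exact least-squares minimizer with phi[ic] = 0
  ic <- which.min((grid$x - center[1])^2 + (grid$y - center[2])^2)
  A[ic, ic] <- A[ic, ic] + 1
  phi <- as.numeric(Matrix::solve(A, b))
  phi <- phi - phi[ic]

  res <- sqrt(mean((as.numeric(Gx %*% phi) + F[, 1])^2 +
                     (as.numeric(Gy %*% phi) + F[, 2])^2))
  structure(list(grid = grid, phi = matrix(phi, nx, ny), x = xs, y = ys,
                 fit_residual = res),
            class = "potential_map")
}
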