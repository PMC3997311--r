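## Fixed-kernel utilization distributions.
##
## Kernel: isotropic Gaussian with a single global smoothing parameter (the
## "fixed kernel"), per the convention of classical home-range tools.

#' Bivariate-normal reference bandwidth
#'
#' `h_ref = sqrt((s_x^2 + s_y^2) / 2) * n^(-1/6)`, the plug-in bandwidth for
#' a bivariate normal reference with a single isotropic smoothing
#' parameter.  The reference rule tends to oversmooth multimodal ranges,
#' which is why [select_bandwidth()] scans multipliers 0.6-0.9 of it.
#'
#' @param points two-column matrix or data.frame of x/y coordinates
#'   (metres).
#' @return bandwidth in metres.
#' @examples
#' set.seed(1)
#' reference_bandwidth(matrix(rnorm(128, sd = 1000), ncol = 2))
#' @export
reference_bandwidth <- function(points) {
  xy <- as.matrix(points)[, 1:2, drop = FALSE]
  n <- nrow(xy)
  if (n < 2) stopf("need at least 2 points for a reference bandwidth")
  s2 <- (var(xy[, 1]) + var(xy[, 2])) / 2
  if (s2 <= 0) stopf("degenerate point set: all points identical")
  sqrt(s2) * n^(-1 / 6)
}

#' Estimate a fixed-kernel utilization distribution
#'
#' Gaussian kernel density on a regular grid:
#' `f(x) = (1/n) * sum_j phi(x - x_j; h) * phi(y - y_j; h)` with isotropic
#' SD `h`.  The grid covers the points plus `margin_bw` bandwidths of margin
#' and is renormalized so that `sum(z) * cell^2 = 1` exactly (cell-sum mass
#' convention; see the methods vignette).
#'
#' @param points two-column matrix/data.frame of relocations (metres), or a
#'   telemetry data.frame with `x`/`y` columns.
#' @param bandwidth kernel SD in metres.
#' @param cell grid cell size in metres; default `bandwidth / 4`.  Must be
#'   at most `bandwidth / 2` (resolution guard).
#' @param margin_bw grid margin in bandwidths (default 3).
#' @param animal_id,period,multiplier provenance labels stored on the
#'   object.
#' @return object of class `camtel_ud`: list with grid centre coordinates
#'   `x` (length nx), `y` (length ny), density matrix `z` (nx x ny,
#'   `z[i, j]` is the density per m^2 at `(x[i], y[j])`; x varies along
#'   rows), `cell`, `h`, `multiplier`, `n`, `animal_id`, `period`, and the
#'   relocation bounding box `bbox`.
#' @export
estimate_ud <- function(points, bandwidth, cell = bandwidth / 4,
                        margin_bw = 3, animal_id = NA_character_,
                        period = NA_character_, multiplier = NA_real_) {
  if (is.data.frame(points) && all(c("x", "y") %in% names(points)))
    points <- points[, c("x", "y")]
  xy <- as.matrix(points)[, 1:2, drop = FALSE]
  n <- nrow(xy)
  if (n < 1) stopf("no relocations supplied")
  if (!is.finite(bandwidth) || bandwidth <= 0)
    stopf("bandwidth must be positive")
  if (cell > bandwidth / 2)
    stopf("grid cell (%g m) exceeds bandwidth/2; use cell <= %g m",
          cell, bandwidth / 2)
  margin <- margin_bw * bandwidth
  gx <- seq(min(xy[, 1]) - margin, max(xy[, 1]) + margin, by = cell)
  gy <- seq(min(xy[, 2]) - margin, max(xy[, 2]) + margin, by = cell)
  # separable Gaussian kernel: z = Ax %*% t(Ay) / n, Ax[i,j] = phi(gx_i - x_j)
  Ax <- outer(gx, xy[, 1], function(g, p) dnorm(g, p, bandwidth))
  Ay <- outer(gy, xy[, 2], function(g, p) dnorm(g, p, bandwidth))
  z <- (Ax %*% t(Ay)) / n
  z <- z / (sum(z) * cell^2)
  structure(list(x = gx, y = gy, z = z, cell = cell, h = bandwidth,
                 multiplier = multiplier, n = n, animal_id = animal_id,
                 period = period,
                 bbox = c(xmin = min(xy[, 1]), xmax = max(xy[, 1]),
                          ymin = min(xy[, 2]), ymax = max(xy[, 2]))),
            class = "camtel_ud")
}

#' @export
print.camtel_ud <- function(x, ...) {
  cat(sprintf(
    "<camtel_ud> %s / %s: %d x %d grid @ %.0f m, h = %.0f m (x%.2g), n = %d\n",
    x$animal_id, x$period, length(x$x), length(x$y), x$cell, x$h,
    x$multiplier, x$n))
  invisible(x)
}

#' Utilization density at arbitrary points
#'
#' Bilinear interpolation on the UD grid; points beyond the grid margin get
#' density 0.
#'
#' @param ud a `camtel_ud`.
#' @param x,y point coordinates in metres (vectorized).
#' @return numeric vector of densities (per m^2).
#' @export
ud_at <- function(ud, x, y) {
  nx <- length(ud$x); ny <- length(ud$y)
  ix <- findInterval(x, ud$x)
  iy <- findInterval(y, ud$y)
  out <- numeric(length(x))
  ok <- ix >= 1 & ix < nx & iy >= 1 & iy < ny
  # points in the half-cell fringe between the last node and the edge are
  # clamped to the boundary node rather than dropped
  edge_x <- (ix == nx & x <= ud$x[nx] + ud$cell / 2) |
    (ix == 0 & x >= ud$x[1] - ud$cell / 2)
  edge_y <- (iy == ny & y <= ud$y[ny] + ud$cell / 2) |
    (iy == 0 & y >= ud$y[1] - ud$cell / 2)
  if (any(ok)) {
    i <- ix[ok]; j <- iy[ok]
    tx <- (x[ok] - ud$x[i]) / ud$cell
    ty <- (y[ok] - ud$y[j]) / ud$cell
    out[ok] <- ud$z[cbind(i, j)] * (1 - tx) * (1 - ty) +
      ud$z[cbind(i + 1L, j)] * tx * (1 - ty) +
      ud$z[cbind(i, j + 1L)] * (1 - tx) * ty +
      ud$z[cbind(i + 1L, j + 1L)] * tx * ty
  }
  clamp <- !ok & (edge_x | edge_y) &
    ix >= 0 & ix <= nx & iy >= 0 & iy <= ny
  if (any(clamp)) {
    i <- pmin(pmax(ix[clamp], 1L), nx)
    j <- pmin(pmax(iy[clamp], 1L), ny)
    out[clamp] <- ud$z[cbind(i, j)]
  }
  out
}
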