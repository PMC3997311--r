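## Isopleth extraction and bandwidth selection.
##
## An isopleth at p% is the smallest-area region holding p% of the UD mass:
## on the grid, the cells with density >= the p% threshold, where the
## threshold is found by accumulating cell mass in decreasing-density order
## (cell-sum mass, "to 1% accuracy").

# connected components of a logical grid mask, 4-connectivity, by
# vectorized label propagation (labels flow to the component minimum)
count_components <- function(mask) {
  if (!any(mask)) return(0L)
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(as.numeric(seq_len(nr * nc)), nr, nc)
  lab[!mask] <- Inf
  repeat {
    new <- lab
    if (nr > 1) {
      new[-1, ] <- pmin(new[-1, ], lab[-nr, ])
      new[-nr, ] <- pmin(new[-nr, ], lab[-1, ])
    }
    if (nc > 1) {
      new[, -1] <- pmin(new[, -1], lab[, -nc])
      new[, -nc] <- pmin(new[, -nc], lab[, -1])
    }
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  length(unique(lab[mask]))
}

#' Extract isopleths from a utilization distribution
#'
#' For each requested percentage `p`, finds the smallest density level such
#' that cells at or above it hold at least `p`% of the total mass, together
#' with the region's area and (optionally) its number of connected
#' fragments (4-connectivity).
#'
#' @param ud a `camtel_ud` from [estimate_ud()].
#' @param percentiles integer percentages in `[1, 99]`.
#' @param fragments count connected components per isopleth (set `FALSE`
#'   when only thresholds/areas are needed, e.g. for percentile lookup at
#'   1% steps).
#' @return object of class `isopleth_set`: data.frame with columns
#'   `percentile`, `threshold` (per m^2), `area_ha`, `fragments`
#'   (NA when not counted), plus attribute `cell`.
#' @export
isopleths <- function(ud, percentiles = 1:99, fragments = TRUE) {
  if (!inherits(ud, "camtel_ud")) stopf("ud must be a camtel_ud")
  percentiles <- as.integer(percentiles)
  if (any(percentiles < 1 | percentiles > 99))
    stopf("percentiles must lie in [1, 99]")
  z <- as.vector(ud$z)
  if (length(z) == 0 || all(z == 0)) stopf("empty utilization distribution")
  zs <- sort(z, decreasing = TRUE)
  cz <- cumsum(zs) * ud$cell^2
  total <- cz[length(cz)]
  out <- data.frame(percentile = percentiles, threshold = NA_real_,
                    area_ha = NA_real_, fragments = NA_integer_)
  for (r in seq_along(percentiles)) {
    p <- percentiles[r]
    idx <- which(cz >= total * p / 100)[1]
    thr <- zs[idx]
    out$threshold[r] <- thr
    out$area_ha[r] <- sum(z >= thr) * ud$cell^2 / 1e4
    if (fragments)
      out$fragments[r] <- count_components(ud$z >= thr)
  }
  structure(out[order(out$percentile), ], class = c("isopleth_set",
                                                    "data.frame"),
            cell = ud$cell)
}

iso_threshold <- function(isos, p) {
  i <- match(p, isos$percentile)
  if (is.na(i)) stopf("isopleth set has no %d%% level", p)
  isos$threshold[i]
}

#' Isopleth percentile of points on a UD
#'
#' Returns, for each point, the smallest isopleth percentage whose region
#' contains it (1 = innermost core).  When `truncate` is set (default the
#' 90% home-range extent), points with density below the `truncate`%
#' threshold are reported as outside (`NA`).
#'
#' @param ud a `camtel_ud`.
#' @param isos an [isopleths()] set computed at 1% steps covering
#'   `truncate`.
#' @param x,y point coordinates (vectorized).
#' @param truncate maximum-extent isopleth in percent, or `NULL` for no
#'   truncation.
#' @return integer vector of percentiles; `NA` for points outside the
#'   truncation extent (or beyond every computed level).
#' @export
isopleth_percentile_at <- function(ud, isos, x, y, truncate = 90) {
  stopifnot(inherits(isos, "isopleth_set"))
  thr <- isos$threshold
  pct <- isos$percentile
  if (!is.null(truncate) && !(truncate %in% pct))
    stopf("isopleth set lacks the %d%% truncation level", truncate)
  d <- ud_at(ud, x, y)
  out <- rep(NA_integer_, length(d))
  for (k in seq_along(d)) {
    if (!is.null(truncate) && d[k] < thr[match(truncate, pct)]) next
    hit <- which(thr <= d[k])
    if (length(hit)) out[k] <- pct[hit[1]]
  }
  out
}

# bounding box (in grid coordinates) of cells at/above a threshold
mask_bbox <- function(ud, thr) {
  mask <- ud$z >= thr
  ix <- which(rowSums(mask) > 0)
  iy <- which(colSums(mask) > 0)
  c(xmin = ud$x[min(ix)], xmax = ud$x[max(ix)],
    ymin = ud$y[min(iy)], ymax = ud$y[max(iy)])
}

#' Select a kernel bandwidth multiplier by cohesion and extent criteria
#'
#' Scans multipliers of the reference bandwidth in ascending order and
#' returns the smallest one whose UD passes both selection criteria:
#' *cohesion* — the 90% and 95% isopleths break into at most
#' `max_fragments` connected fragments; *extent* — those isopleths extend
#' beyond the relocation bounding box by at most `extent_margin` bandwidths
#' on every side.  When no multiplier passes, the reference bandwidth
#' (`fallback`, multiplier 1.0) is used.
#'
#' @param points two-column matrix/data.frame of relocations.
#' @param multipliers candidate multipliers, ascending.
#' @param fallback multiplier used when all candidates fail.
#' @param max_fragments cohesion limit (default 3).
#' @param extent_margin extent limit, in bandwidths (default 2).
#' @param cell grid cell size; default `h / 4` per candidate.
#' @param criteria set `FALSE` to disable the criteria and return the
#'   smallest multiplier.
#' @param ... passed to [estimate_ud()] (provenance labels).
#' @return list with `multiplier`, `ud` (the selected `camtel_ud`),
#'   `h_ref`, and `diagnostics` (per-candidate fragment counts and extent
#'   margins in bandwidth units).
#' @export
select_bandwidth <- function(points, multipliers = c(0.6, 0.7, 0.8, 0.9),
                             fallback = 1.0, max_fragments = 3,
                             extent_margin = 2, cell = NULL,
                             criteria = TRUE, ...) {
  if (is.data.frame(points) && all(c("x", "y") %in% names(points)))
    points <- points[, c("x", "y")]
  xy <- as.matrix(points)[, 1:2, drop = FALSE]
  h_ref <- reference_bandwidth(xy)
  multipliers <- sort(multipliers)
  diag_rows <- list()
  fit_one <- function(m) {
    h <- m * h_ref
    estimate_ud(xy, h, cell = cell %||% (h / 4), multiplier = m, ...)
  }
  if (!criteria) {
    m <- multipliers[1]
    return(list(multiplier = m, ud = fit_one(m), h_ref = h_ref,
                diagnostics = NULL))
  }
  bbox <- c(xmin = min(xy[, 1]), xmax = max(xy[, 1]),
            ymin = min(xy[, 2]), ymax = max(xy[, 2]))
  for (m in multipliers) {
    ud <- fit_one(m)
    isos <- isopleths(ud, c(90L, 95L), fragments = TRUE)
    frag <- max(isos$fragments)
    overshoot <- 0
    for (p in c(90L, 95L)) {
      bb <- mask_bbox(ud, iso_threshold(isos, p))
      overshoot <- max(overshoot,
                       bbox["xmin"] - bb["xmin"], bb["xmax"] - bbox["xmax"],
                       bbox["ymin"] - bb["ymin"], bb["ymax"] - bbox["ymax"])
    }
    pass <- frag <= max_fragments && overshoot <= extent_margin * ud$h
    diag_rows[[length(diag_rows) + 1L]] <- data.frame(
      multiplier = m, h = ud$h, max_fragments = frag,
      overshoot_bw = unname(overshoot / ud$h), pass = pass)
    if (pass)
      return(list(multiplier = m, ud = ud, h_ref = h_ref,
                  diagnostics = do.call(rbind, diag_rows)))
  }
  ud <- fit_one(fallback)
  list(multiplier = fallback, ud = ud, h_ref = h_ref,
       diagnostics = do.call(rbind, diag_rows))
}

#' Export a UD as an ESRI ASCII grid
#'
#' Plain-text `ncols/nrows/xllcorner/yllcorner/cellsize` header followed by
#' the density matrix, rows from north to south.
#'
#' @param ud a `camtel_ud`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ud_asc <- function(ud, path) {
  nx <- length(ud$x); ny <- length(ud$y)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", nx), sprintf("nrows %d", ny),
               sprintf("xllcorner %.3f", ud$x[1] - ud$cell / 2),
               sprintf("yllcorner %.3f", ud$y[1] - ud$cell / 2),
               sprintf("cellsize %.3f", ud$cell),
               "NODATA_value -9999"), con)
  for (j in ny:1)
    writeLines(paste(formatC(ud$z[, j], format = "e", digits = 6),
                     collapse = " "), con)
  invisible(path)
}

#' Export isopleth contours as GeoJSON
#'
#' Contour lines at each isopleth threshold become GeoJSON `Polygon`
#' features with a `percentile` property (open contours that hit the grid
#' edge are closed by joining last to first vertex).
#'
#' @param ud a `camtel_ud`.
#' @param isos an [isopleths()] set.
#' @param path optional output file; when `NULL` the GeoJSON string is
#'   returned.
#' @return GeoJSON string (invisibly when written to `path`).
#' @export
isopleth_geojson <- function(ud, isos, path = NULL) {
  feats <- list()
  for (r in seq_len(nrow(isos))) {
    cl <- contourLines(ud$x, ud$y, ud$z, levels = isos$threshold[r])
    for (ring in cl) {
      coords <- cbind(ring$x, ring$y)
      if (!all(coords[1, ] == coords[nrow(coords), ]))
        coords <- rbind(coords, coords[1, ])
      feats[[length(feats) + 1L]] <- list(
        type = "Feature",
        properties = list(percentile = isos$percentile[r],
                          threshold = isos$threshold[r]),
        geometry = list(type = "Polygon",
                        coordinates = list(lapply(seq_len(nrow(coords)),
                                                  function(i) coords[i, ]))))
    }
  }
  js <- jsonlite::toJSON(list(type = "FeatureCollection", features = feats),
                         auto_unbox = TRUE, digits = 8)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(as.character(js))
}
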