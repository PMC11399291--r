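# Inverse-distance-weighting interpolation onto regular grids, buffer
# clipping and hot/cold-spot fold ratios. Coordinates are planar (projected)
# units; all distances Euclidean.

#' Regular grid geometry
#'
#' Describes a regular planar grid by its lower-left corner, square cell
#' size and dimensions. Cell centers are at
#' `x0 + (col - 0.5) * cell_size`, `y0 + (row - 0.5) * cell_size`, with row
#' 1 the southernmost row.
#'
#' @param origin numeric length-2, lower-left corner `(x0, y0)`.
#' @param cell_size side length of a square cell, > 0.
#' @param nrows,ncols grid dimensions.
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(origin, cell_size, nrows, ncols) {
  stopifnot(length(origin) == 2, is.finite(origin),
            cell_size > 0, nrows >= 1, ncols >= 1)
  structure(list(origin = as.numeric(origin), cell_size = cell_size,
                 nrows = as.integer(nrows), ncols = as.integer(ncols)),
            class = "grid_spec")
}

#' Default grid over a point set
#'
#' A square-celled grid covering the bounding box of the points expanded by
#' `pad` on every side, with the longer axis split into `n` cells.
#'
#' @param x,y point coordinates.
#' @param n cells along the longer axis, default 100.
#' @param pad expansion of the bounding box (same length units); defaults
#'   to the default buffer radius, 2x the median nearest-neighbor distance,
#'   so that clipped rasters are not truncated at the hull.
#' @return a `grid_spec`.
#' @export
default_grid <- function(x, y, n = 100, pad = NULL) {
  stopifnot(length(x) >= 1, length(x) == length(y))
  if (is.null(pad)) pad <- default_buffer_radius(x, y)
  x0 <- min(x) - pad; x1 <- max(x) + pad
  y0 <- min(y) - pad; y1 <- max(y) + pad
  w <- max(x1 - x0, .Machine$double.eps)
  h <- max(y1 - y0, .Machine$double.eps)
  cell <- max(w, h) / n
  grid_spec(c(x0, y0), cell,
            nrows = max(1L, ceiling(h / cell)),
            ncols = max(1L, ceiling(w / cell)))
}

#' Default buffer radius: twice the median nearest-neighbor distance
#'
#' @param x,y point coordinates (at least one point).
#' @return radius in the coordinate length units. With a single point the
#'   nearest-neighbor distance is undefined; a nominal radius of 1 is used.
#' @export
default_buffer_radius <- function(x, y) {
  n <- length(x)
  if (n < 2) return(1)
  d <- as.matrix(stats::dist(cbind(x, y)))
  diag(d) <- Inf
  2 * stats::median(apply(d, 1, min))
}

#' Cell-center coordinates of a grid
#'
#' @param grid a `grid_spec` or `raster_field`.
#' @return list with vectors `x` (length ncols) and `y` (length nrows) plus
#'   matrices `X`, `Y` of cell-center coordinates (nrows x ncols).
#' @export
grid_centers <- function(grid) {
  g <- if (inherits(grid, "raster_field")) grid$grid else grid
  x <- g$origin[1] + (seq_len(g$ncols) - 0.5) * g$cell_size
  y <- g$origin[2] + (seq_len(g$nrows) - 0.5) * g$cell_size
  list(x = x, y = y,
       X = matrix(x, g$nrows, g$ncols, byrow = TRUE),
       Y = matrix(y, g$nrows, g$ncols))
}

new_raster_field <- function(grid, values, mask) {
  stopifnot(inherits(grid, "grid_spec"),
            is.matrix(values), nrow(values) == grid$nrows,
            ncol(values) == grid$ncols,
            is.matrix(mask), all(dim(mask) == dim(values)))
  structure(list(grid = grid, values = values, mask = mask),
            class = "raster_field")
}

#' Inverse distance weighting interpolation
#'
#' Predicts the value at every cell center as the distance-decay weighted
#' average of the sample values:
#' \deqn{\hat v(c) = \sum_i w_i v_i / \sum_i w_i,\qquad w_i = d(c, p_i)^{-p}}
#' optionally restricted to the `max_neighbors` nearest samples. A cell
#' within `snap_tol` of a sample point takes that sample's value exactly
#' (IDW is an exact interpolator). Predictions are always bounded by the
#' data range.
#'
#' @param x,y,values sample coordinates and values (equal lengths, >= 1
#'   point). Duplicate coordinates with conflicting values are an error;
#'   duplicates with equal values are collapsed.
#' @param grid a `grid_spec`; default [default_grid()] over the points.
#' @param power inverse-distance exponent, > 0; default 2.
#' @param max_neighbors number of nearest samples used per cell; default
#'   `Inf` (all samples).
#' @param snap_tol distance below which a cell is considered coincident with
#'   a sample; default `1e-9 * cell_size`.
#' @return a `raster_field` with an all-true mask (see [clip_to_buffer()]).
#' @examples
#' f <- idw_interpolate(c(0, 10), c(0, 0), c(0, 10),
#'                      grid_spec(c(0, -1), 1, 2, 10))
#' range(f$values)
#' @export
idw_interpolate <- function(x, y, values, grid = NULL, power = 2,
                            max_neighbors = Inf, snap_tol = NULL) {
  n <- length(x)
  if (n == 0L) stop("IDW needs at least one sample point", call. = FALSE)
  stopifnot(length(y) == n, length(values) == n, power > 0,
            all(is.finite(x)), all(is.finite(y)), all(is.finite(values)))
  key <- paste(x, y)
  if (anyDuplicated(key)) {
    agg <- tapply(values, key, function(v) diff(range(v)))
    if (any(agg > 0)) {
      stop("duplicate coordinates with conflicting values", call. = FALSE)
    }
    keep <- !duplicated(key)
    x <- x[keep]; y <- y[keep]; values <- values[keep]
    n <- length(x)
  }
  if (is.null(grid)) grid <- default_grid(x, y)
  if (is.null(snap_tol)) snap_tol <- 1e-9 * grid$cell_size
  cc <- grid_centers(grid)
  ncell <- grid$nrows * grid$ncols
  # squared distances, cells x points
  d2 <- outer(as.vector(cc$X), x, "-")^2 + outer(as.vector(cc$Y), y, "-")^2
  d <- sqrt(d2)
  k <- min(max_neighbors, n)
  if (k < n) {
    # drop all but the k nearest samples per cell
    for (i in seq_len(ncell)) {
      thr <- sort.int(d[i, ], partial = k)[k]
      d[i, d[i, ] > thr] <- Inf
    }
  }
  w <- d^(-power)
  w[!is.finite(w)] <- 0            # Inf distances (dropped neighbors)
  snap <- d <= snap_tol
  pred <- numeric(ncell)
  has_snap <- rowSums(snap) > 0
  if (any(has_snap)) {
    nearest <- apply(d[has_snap, , drop = FALSE], 1, which.min)
    pred[has_snap] <- values[nearest]
  }
  ok <- !has_snap
  if (any(ok)) {
    pred[ok] <- (w[ok, , drop = FALSE] %*% values) / rowSums(w[ok, , drop = FALSE])
  }
  vals <- matrix(pred, grid$nrows, grid$ncols)
  new_raster_field(grid, vals, matrix(TRUE, grid$nrows, grid$ncols))
}

#' Clip a raster field to a buffer around the sampling points
#'
#' Interpolated surfaces are only meaningful near the data; the field is
#' masked to the union of disks of the given radius centered on the
#' sampling points. A cell is retained iff its center lies within `radius`
#' of at least one point. Masking composes: cells already masked stay
#' masked.
#'
#' @param field a `raster_field`.
#' @param x,y sampling-point coordinates.
#' @param radius buffer radius, > 0; default
#'   [default_buffer_radius()] of the points.
#' @return the clipped `raster_field`; masked cells hold `NA`.
#' @export
clip_to_buffer <- function(field, x, y, radius = NULL) {
  if (is.null(radius)) radius <- default_buffer_radius(x, y)
  stopifnot(radius > 0, length(x) == length(y), length(x) >= 1)
  cc <- grid_centers(field)
  d2min <- Reduce(pmin, lapply(seq_along(x), function(i) {
    (as.vector(cc$X) - x[i])^2 + (as.vector(cc$Y) - y[i])^2
  }))
  inside <- matrix(d2min <= radius^2, field$grid$nrows, field$grid$ncols)
  mask <- field$mask & inside
  vals <- field$values
  vals[!mask] <- NA_real_
  new_raster_field(field$grid, vals, mask)
}

#' Hot-spot / cold-spot fold ratio of a field
#'
#' Summarizes the contrast of a surface as the ratio of the mean over its
#' hot spots (cells at or above the `hot_q` quantile of unmasked values) to
#' the mean over its cold spots (cells at or below the `cold_q` quantile).
#' A constant field has ratio 1.
#'
#' @param field a `raster_field` with at least 10 unmasked cells.
#' @param hot_q,cold_q quantiles defining hot and cold spots; defaults 0.90
#'   and 0.10.
#' @return dimensionless fold ratio; `Inf` with a warning when the
#'   cold-spot mean is zero.
#' @export
fold_ratio <- function(field, hot_q = 0.90, cold_q = 0.10) {
  stopifnot(hot_q > cold_q, hot_q <= 1, cold_q >= 0)
  v <- field$values[field$mask]
  v <- v[!is.na(v)]
  if (length(v) < 10) stop("fold_ratio needs >= 10 unmasked cells", call. = FALSE)
  hot <- v[v >= stats::quantile(v, hot_q)]
  cold <- v[v <= stats::quantile(v, cold_q)]
  mc <- mean(cold)
  if (mc == 0) {
    warning("cold-spot mean is zero; fold ratio infinite", call. = FALSE)
    return(Inf)
  }
  mean(hot) / mc
}

#' @export
print.raster_field <- function(x, ...) {
  g <- x$grid
  cat(sprintf("raster_field: %d x %d cells of %g units, origin (%g, %g)\n",
              g$nrows, g$ncols, g$cell_size, g$origin[1], g$origin[2]))
  v <- x$values[x$mask]
  cat(sprintf("  %d/%d cells unmasked; value range %.4g-%.4g\n",
              sum(x$mask), length(x$mask),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  invisible(x)
}

#' @export
summary.raster_field <- function(object, ...) {
  summary(object$values[object$mask], ...)
}

#' Quicklook plot of a raster field
#'
#' @param x a `raster_field`.
#' @param points optional two-column matrix/data.frame of sampling points to
#'   overlay.
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @return invisibly, `x`.
#' @export
plot.raster_field <- function(x, points = NULL, main = "", ...) {
  cc <- grid_centers(x)
  z <- t(x$values)  # image() wants x-by-y
  graphics::image(cc$x, cc$y, z, asp = 1, xlab = "x", ylab = "y",
                  main = main, col = grDevices::hcl.colors(64, "YlOrRd",
                                                           rev = TRUE), ...)
  if (!is.null(points)) {
    graphics::points(points[, 1], points[, 2], pch = 3, cex = 0.6)
  }
  invisible(x)
}

#' Write a raster field as an ESRI ASCII grid
#'
#' Plain-text raster format readable by QGIS and most GIS software. Masked
#' cells are written as the no-data value.
#'
#' @param field a `raster_field`.
#' @param path output `.asc` path.
#' @param nodata no-data value, default -9999.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(field, path, nodata = -9999) {
  g <- field$grid
  vals <- field$values
  vals[!field$mask | is.na(vals)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", g$ncols),
               paste("nrows", g$nrows),
               paste("xllcorner", format(g$origin[1], scientific = FALSE)),
               paste("yllcorner", format(g$origin[2], scientific = FALSE)),
               paste("cellsize", format(g$cell_size, scientific = FALSE)),
               paste("NODATA_value", nodata)), con)
  # ESRI ASCII stores the top row first; our row 1 is the southernmost
  for (r in rev(seq_len(g$nrows))) {
    writeLines(paste(format(vals[r, ], trim = TRUE, digits = 10),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid into a raster field
#'
#' @param path `.asc` path written by [write_esri_ascii()] or a GIS.
#' @return a `raster_field`; cells equal to the file's no-data value are
#'   masked.
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  nrows <- as.integer(hdr$nrows); ncols <- as.integer(hdr$ncols)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  body <- lines[i:(i + nrows - 1)]
  vals <- t(vapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]),
                   numeric(ncols), USE.NAMES = FALSE))
  vals <- vals[rev(seq_len(nrows)), , drop = FALSE]  # back to south-first rows
  mask <- vals != nodata
  vals[!mask] <- NA_real_
  new_raster_field(grid_spec(c(hdr$xllcorner, hdr$yllcorner), hdr$cellsize,
                             nrows, ncols),
                   vals, mask)
}

same_geometry <- function(a, b, tol = 1e-9) {
  ga <- a$grid; gb <- b$grid
  ga$nrows == gb$nrows && ga$ncols == gb$ncols &&
    abs(ga$cell_size - gb$cell_size) <= tol * ga$cell_size &&
    all(abs(ga$origin - gb$origin) <= tol * max(1, abs(ga$origin)))
}
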