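#' Define a regular analysis grid
#'
#' Constructs the regular square grid that all per-cell quantities are keyed
#' to. Cells are indexed `(row, col)` with the origin at the lower-left corner
#' of cell `(1, 1)`; rows increase northwards, columns eastwards. Cell ids are
#' stable integers in row-major order, `id = (row - 1) * n_cols + col`.
#' Membership is half-open, `[x, x + cell_size) x [y, y + cell_size)`, so every
#' point maps to exactly one cell.
#'
#' @param n_rows,n_cols Number of grid rows and columns (positive integers).
#' @param cell_size Side length of a cell, in the (planar) coordinate units of
#'   the point and raster data. Nominally 5 (km) for a 5 km x 5 km grid.
#' @param origin Numeric length-2, the `(x, y)` lower-left corner of the grid.
#'
#' @return An object of class `grid_def`: a list with elements `origin`,
#'   `cell_size`, `n_rows`, `n_cols` and `n_cells`.
#' @examples
#' g <- grid_def(4, 5, cell_size = 5)
#' g$n_cells
#' @export
grid_def <- function(n_rows, n_cols, cell_size = 5, origin = c(0, 0)) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L)
    stop("n_rows and n_cols must be integers >= 1")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number")
  if (length(origin) != 2L || !all(is.finite(origin)))
    stop("origin must be a finite (x, y) pair")
  structure(
    list(origin = as.numeric(origin), cell_size = as.numeric(cell_size),
         n_rows = n_rows, n_cols = n_cols, n_cells = n_rows * n_cols),
    class = "grid_def")
}

#' @export
print.grid_def <- function(x, ...) {
  cat(sprintf("Analysis grid: %d x %d cells (%d total), cell size %g, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$n_cells, x$cell_size, x$origin[1], x$origin[2]))
  invisible(x)
}

#' Cell ids and centroids of a grid
#'
#' @param grid A [grid_def()] object.
#' @return `cell_ids()` returns the integer vector `1:n_cells` (row-major).
#'   `cell_centroids()` returns a data frame with columns `cell_id`, `row`,
#'   `col`, `x`, `y` where `(x, y)` is the cell centre.
#' @export
cell_ids <- function(grid) seq_len(grid$n_cells)

#' @rdname cell_ids
#' @export
cell_centroids <- function(grid) {
  stopifnot(inherits(grid, "grid_def"))
  id <- cell_ids(grid)
  row <- (id - 1L) %/% grid$n_cols + 1L
  col <- (id - 1L) %% grid$n_cols + 1L
  data.frame(
    cell_id = id, row = row, col = col,
    x = grid$origin[1] + (col - 0.5) * grid$cell_size,
    y = grid$origin[2] + (row - 0.5) * grid$cell_size)
}

# Map point coordinates to row-major cell ids; NA for out-of-bounds points.
locate_cells <- function(x, y, grid) {
  col <- floor((x - grid$origin[1]) / grid$cell_size) + 1
  row <- floor((y - grid$origin[2]) / grid$cell_size) + 1
  ok <- col >= 1 & col <= grid$n_cols & row >= 1 & row <= grid$n_rows
  id <- ifelse(ok, (row - 1) * grid$n_cols + col, NA_real_)
  as.integer(id)
}

#' Bin categorised points into grid cells
#'
#' Counts points per cell and per category under the grid's half-open cell
#' convention. Every in-bounds point is counted exactly once; out-of-bounds
#' points are counted and reported via the `out_of_bounds` attribute rather
#' than silently dropped.
#'
#' @param points A data frame with numeric columns `x`, `y` and a `category`
#'   column (character or factor).
#' @param grid A [grid_def()] object.
#' @return An integer matrix of counts with one row per cell (rownames are
#'   cell ids) and one column per category (sorted unique categories), with
#'   attribute `out_of_bounds` giving the number of points falling outside the
#'   grid.
#' @examples
#' g <- grid_def(2, 2, cell_size = 1)
#' pts <- data.frame(x = c(0, 0.5, 1.5), y = c(0, 0.5, 1.5),
#'                   category = c("a", "a", "b"))
#' bin_points_to_cells(pts, g)
#' @export
bin_points_to_cells <- function(points, grid) {
  stopifnot(inherits(grid, "grid_def"))
  if (grid$n_cells < 1L) stop("empty grid")
  if (!all(c("x", "y", "category") %in% names(points)))
    stop("points must have columns x, y, category")
  if (!all(is.finite(points$x)) || !all(is.finite(points$y)))
    stop("point coordinates must be finite")
  cat_levels <- sort(unique(as.character(points$category)))
  id <- locate_cells(points$x, points$y, grid)
  oob <- sum(is.na(id))
  counts <- matrix(0L, nrow = grid$n_cells, ncol = length(cat_levels),
                   dimnames = list(cell_ids(grid), cat_levels))
  if (nrow(points) > 0L && length(cat_levels) > 0L) {
    keep <- !is.na(id)
    tab <- table(factor(id[keep], levels = cell_ids(grid)),
                 factor(as.character(points$category)[keep], levels = cat_levels))
    counts[] <- as.integer(tab)
  }
  attr(counts, "out_of_bounds") <- oob
  counts
}

#' Zonal sum of a raster over the analysis grid
#'
#' Aggregates a finer (or equal) resolution axis-aligned raster to per-cell
#' sums. Each raster pixel is assigned to the single analysis cell containing
#' its centre (pixel-centre rule), so raster mass is conserved for in-bounds
#' pixels. `NA` pixels are skipped and their count reported.
#'
#' @param raster A raster object as returned by [read_ascii_grid()] or
#'   [make_raster()]: a list with `origin` (lower-left corner), `pixel_size`
#'   and `values` (a matrix, row 1 = southernmost row).
#' @param grid A [grid_def()] object.
#' @return Numeric vector of per-cell sums, named by cell id, with attributes
#'   `out_of_bounds` (pixels whose centre falls outside the grid) and
#'   `n_na` (NA pixels skipped).
#' @examples
#' g <- grid_def(1, 1, cell_size = 5)
#' r <- make_raster(matrix(1, 5, 5), pixel_size = 1)
#' zonal_sum(r, g)  # 25
#' @export
zonal_sum <- function(raster, grid) {
  stopifnot(inherits(grid, "grid_def"))
  if (!is.list(raster) || is.null(raster$values) || is.null(raster$pixel_size))
    stop("raster must have elements origin, pixel_size, values")
  if (!is.matrix(raster$values)) stop("raster values must be a matrix")
  if (length(raster$pixel_size) != 1L || raster$pixel_size <= 0)
    stop("only axis-aligned rasters with a single positive pixel size are supported")
  v <- raster$values
  nr <- nrow(v); nc <- ncol(v)
  # pixel centres, row 1 = southernmost
  cx <- raster$origin[1] + (seq_len(nc) - 0.5) * raster$pixel_size
  cy <- raster$origin[2] + (seq_len(nr) - 0.5) * raster$pixel_size
  px <- rep(cx, each = nr)
  py <- rep(cy, times = nc)
  val <- as.vector(v)
  na <- is.na(val)
  id <- locate_cells(px, py, grid)
  oob <- sum(!na & is.na(id))
  keep <- !na & !is.na(id)
  out <- numeric(grid$n_cells)
  names(out) <- cell_ids(grid)
  if (any(keep)) {
    s <- rowsum(val[keep], group = id[keep])
    out[rownames(s)] <- s[, 1]
  }
  attr(out, "out_of_bounds") <- oob
  attr(out, "n_na") <- sum(na)
  out
}

#' Point density per grid cell
#'
#' Density of points per unit cell area: the per-cell count from
#' [bin_points_to_cells()] divided by `cell_size^2`. Used for bus-stop and
#' road-junction densities.
#'
#' @param points Data frame with columns `x`, `y` (a `category` column is
#'   optional and ignored).
#' @param grid A [grid_def()] object.
#' @return Numeric vector of densities named by cell id, attribute
#'   `out_of_bounds` as in [bin_points_to_cells()].
#' @export
point_density <- function(points, grid) {
  n <- length(points$x)
  if (n == 0L) {
    dens <- stats::setNames(numeric(grid$n_cells), cell_ids(grid))
    attr(dens, "out_of_bounds") <- 0L
    return(dens)
  }
  pts <- data.frame(x = points$x, y = points$y,
                    category = rep("point", n))
  counts <- bin_points_to_cells(pts, grid)
  dens <- as.numeric(counts[, 1]) / grid$cell_size^2
  names(dens) <- rownames(counts)
  attr(dens, "out_of_bounds") <- attr(counts, "out_of_bounds")
  dens
}

#' A straight dividing line for east/west stratification
#'
#' @param a,b Numeric length-2 endpoints `(x, y)`; must be distinct.
#' @return An object of class `line_split` with elements `a` and `b`.
#' @seealso [side_of_line()], [heihe_tengchong_line()]
#' @export
line_split <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != 2L || length(b) != 2L || !all(is.finite(c(a, b))))
    stop("endpoints must be finite (x, y) pairs")
  if (all(a == b)) stop("degenerate line: endpoints must be distinct")
  structure(list(a = a, b = b), class = "line_split")
}

#' The Heihe--Tengchong dividing line (default endpoints)
#'
#' The conventional line dividing China into a densely populated east and a
#' sparsely populated west, as a straight segment in lon/lat treated as planar
#' coordinates. Endpoints default to Tengchong (98.497 E, 25.020 N) and Heihe
#' (127.528 E, 50.245 N); the Tengchong-to-Heihe orientation puts geographic
#' east on the `east_side` of [side_of_line()].
#'
#' @param tengchong,heihe Endpoint overrides, `(lon, lat)`.
#' @return A [line_split()] object.
#' @export
heihe_tengchong_line <- function(tengchong = c(98.497, 25.020),
                                 heihe = c(127.528, 50.245)) {
  line_split(tengchong, heihe)
}

#' Which side of a dividing line a point falls on
#'
#' Classifies points by the sign of the 2-D cross product
#' `(b - a) x (p - a)`. The convention is fixed: `east_side` is the right-hand
#' side of the directed segment `a -> b` (cross product <= 0); points exactly
#' on the line are deterministically assigned to `east_side`. With `a` south of
#' `b` (segment pointing north), east in the compass sense is the right-hand
#' side, matching the label.
#'
#' @param points Data frame with numeric columns `x`, `y` (e.g. cell
#'   centroids), or a numeric length-2 vector for a single point.
#' @param line A [line_split()] object.
#' @return Character vector, `"east_side"` or `"west_side"`, one per point.
#' @examples
#' side_of_line(c(1, 0), line_split(c(0, 0), c(0, 1)))  # "east_side"
#' @export
side_of_line <- function(points, line) {
  stopifnot(inherits(line, "line_split"))
  if (is.numeric(points) && length(points) == 2L)
    points <- data.frame(x = points[1], y = points[2])
  if (!all(is.finite(points$x)) || !all(is.finite(points$y)))
    stop("point coordinates must be finite")
  a <- line$a; b <- line$b
  cross <- (b[1] - a[1]) * (points$y - a[2]) - (b[2] - a[2]) * (points$x - a[1])
  ifelse(cross <= 0, "east_side", "west_side")
}
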