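test_that("point binning follows the half-open cell convention", {
  g <- grid_def(2, 2, cell_size = 1)
  # a point at the exact lower-left corner of cell (1,1) belongs to it
  pts <- data.frame(x = 0, y = 0, category = "a")
  counts <- bin_points_to_cells(pts, g)
  expect_equal(unname(counts[1, "a"]), 1L)
  # a point on the shared edge belongs to the upper/right cell
  pts2 <- data.frame(x = c(1, 0.5), y = c(0.5, 1), category = "a")
  c2 <- bin_points_to_cells(pts2, g)
  expect_equal(unname(c2[, "a"]), c(0L, 1L, 1L, 0L))
})

test_that("binning conserves points and reports out-of-bounds", {
  g <- grid_def(10, 10, cell_size = 1)
  set.seed(42)
  pts <- data.frame(x = runif(10000, 0, 10), y = runif(10000, 0, 10),
                    category = sample(letters[1:3], 10000, TRUE))
  counts <- bin_points_to_cells(pts, g)
  expect_equal(sum(counts), 10000L)
  expect_equal(attr(counts, "out_of_bounds"), 0L)

  pts$x[1:7] <- -5  # push some points off-grid
  c2 <- bin_points_to_cells(pts, g)
  expect_equal(attr(c2, "out_of_bounds"), 7L)
  expect_equal(sum(c2), 10000L - 7L)
})

test_that("binning matches a naive point-in-rectangle oracle", {
  g <- grid_def(4, 5, cell_size = 2, origin = c(-1, 3))
  set.seed(7)
  pts <- data.frame(x = runif(500, -3, 11), y = runif(500, 1, 13),
                    category = sample(c("bus", "junction"), 500, TRUE))
  counts <- bin_points_to_cells(pts, g)
  oracle <- matrix(0L, g$n_cells, 2, dimnames = list(NULL, c("bus", "junction")))
  for (i in seq_len(nrow(pts))) {
    hit <- NA
    for (r in seq_len(g$n_rows)) for (cc in seq_len(g$n_cols)) {
      x0 <- g$origin[1] + (cc - 1) * g$cell_size
      y0 <- g$origin[2] + (r - 1) * g$cell_size
      if (pts$x[i] >= x0 && pts$x[i] < x0 + g$cell_size &&
          pts$y[i] >= y0 && pts$y[i] < y0 + g$cell_size)
        hit <- (r - 1) * g$n_cols + cc
    }
    if (!is.na(hit))
      oracle[hit, pts$category[i]] <- oracle[hit, pts$category[i]] + 1L
  }
  expect_equal(unname(counts[, c("bus", "junction")]), unname(oracle))
})

test_that("zonal sums follow the pixel-centre rule and conserve mass", {
  g <- grid_def(1, 1, cell_size = 5)
  r <- make_raster(matrix(1, 5, 5), pixel_size = 1)
  expect_equal(unname(zonal_sum(r, g)), 25, ignore_attr = TRUE)

  # exact tiling: totals conserved
  g2 <- grid_def(3, 4, cell_size = 2)
  set.seed(11)
  vals <- matrix(rexp(6 * 8), nrow = 6)  # 1-unit pixels tile the 6 x 8 area
  r2 <- make_raster(vals, pixel_size = 1)
  zs <- zonal_sum(r2, g2)
  expect_equal(sum(zs), sum(vals))

  # against a brute-force per-pixel assignment oracle
  oracle <- numeric(g2$n_cells)
  for (i in seq_len(nrow(vals))) for (j in seq_len(ncol(vals))) {
    cx <- (j - 0.5); cy <- (i - 0.5)
    col <- floor(cx / 2) + 1; row <- floor(cy / 2) + 1
    oracle[(row - 1) * 4 + col] <- oracle[(row - 1) * 4 + col] + vals[i, j]
  }
  expect_equal(unname(zs), oracle, ignore_attr = TRUE)
})

test_that("zonal_sum rejects malformed rasters and skips NA pixels", {
  g <- grid_def(2, 2, cell_size = 1)
  expect_error(zonal_sum(list(values = 1:4), g), "origin")
  r <- make_raster(matrix(c(1, NA, 2, 3), 2, 2), pixel_size = 1)
  zs <- zonal_sum(r, g)
  expect_equal(attr(zs, "n_na"), 1L)
  expect_equal(sum(zs), 6)
})

test_that("point density equals counts over cell area", {
  g <- grid_def(1, 1, cell_size = 5)
  pts <- data.frame(x = runif(25, 0, 5), y = runif(25, 0, 5))
  expect_equal(unname(point_density(pts, g)), 1, ignore_attr = TRUE)  # 25 points / 25 area

  g2 <- grid_def(3, 3, cell_size = 2)
  expect_equal(unname(point_density(data.frame(x = numeric(0), y = numeric(0)), g2)),
               rep(0, 9), ignore_attr = TRUE)
  set.seed(3)
  pts2 <- data.frame(x = runif(200, 0, 6), y = runif(200, 0, 6))
  dens <- point_density(pts2, g2)
  cnts <- bin_points_to_cells(cbind(pts2, category = "p"), g2)
  expect_equal(unname(dens), unname(cnts[, 1]) / 4, ignore_attr = TRUE)
})

test_that("side_of_line uses the documented right-of-segment convention", {
  l <- line_split(c(0, 0), c(0, 1))
  expect_equal(side_of_line(c(1, 0), l), "east_side")
  expect_equal(side_of_line(c(-1, 0), l), "west_side")
  # points exactly on the segment go east, deterministically
  expect_equal(side_of_line(c(0, 0.5), l), "east_side")
  expect_error(line_split(c(1, 1), c(1, 1)), "degenerate")
})

test_that("side_of_line matches a signed-area oracle and flips with the line", {
  set.seed(5)
  a <- c(-2, 1); b <- c(3, 4)
  l <- line_split(a, b)
  pts <- data.frame(x = runif(100, -5, 5), y = runif(100, -5, 5))
  got <- side_of_line(pts, l)
  oracle <- vapply(seq_len(100), function(i) {
    area2 <- (b[1] - a[1]) * (pts$y[i] - a[2]) - (b[2] - a[2]) * (pts$x[i] - a[1])
    if (area2 <= 0) "east_side" else "west_side"
  }, "")
  expect_identical(got, oracle)
  expect_true(all(got %in% c("east_side", "west_side")))
  # flipping endpoint order flips every off-line label
  flipped <- side_of_line(pts, line_split(b, a))
  off <- (b[1] - a[1]) * (pts$y - a[2]) - (b[2] - a[2]) * (pts$x - a[1]) != 0
  expect_true(all(got[off] != flipped[off]))
})

test_that("the default east/west line puts eastern China on east_side", {
  l <- heihe_tengchong_line()
  expect_equal(side_of_line(c(121.5, 31.2), l), "east_side")  # Shanghai
  expect_equal(side_of_line(c(87.6, 43.8), l), "west_side")   # Urumqi
})

test_that("ASCII grid files round-trip through read/write", {
  r <- make_raster(matrix(c(1.5, 2, NA, 4, 5, 6), 2, 3),
                   pixel_size = 2.5, origin = c(10, -5))
  path <- tempfile(fileext = ".asc")
  write_ascii_grid(r, path)
  r2 <- read_ascii_grid(path)
  expect_equal(r2$values, r$values)
  expect_equal(r2$pixel_size, r$pixel_size)
  expect_equal(r2$origin, r$origin)
})
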