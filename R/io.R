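#' Construct an in-memory raster
#'
#' @param values Numeric matrix; row 1 is the southernmost row of pixels,
#'   column 1 the westernmost.
#' @param pixel_size Side length of a (square) pixel.
#' @param origin `(x, y)` lower-left corner of the raster.
#' @return A list with class `ascii_raster`: `origin`, `pixel_size`, `values`.
#' @export
make_raster <- function(values, pixel_size, origin = c(0, 0)) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a single positive number")
  structure(list(origin = as.numeric(origin), pixel_size = as.numeric(pixel_size),
                 values = values), class = "ascii_raster")
}

#' Read / write a plain-text ESRI-ASCII-style grid
#'
#' The format is the usual six-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `nodata_value`) followed by `nrows` rows of
#' whitespace-separated values, first row northernmost. Nodata pixels become
#' `NA`.
#'
#' @param path File path.
#' @return For the reader, a raster as from [make_raster()].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-0-9.eE+]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ASCII grid: missing header fields ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  body <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(body) != nr * nc)
    stop(sprintf("expected %d values, found %d", nr * nc, length(body)))
  if (!is.null(hdr$nodata_value)) body[body == hdr$nodata_value] <- NA
  # file rows run north to south; flip so row 1 is southernmost
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)[nr:1, , drop = FALSE]
  make_raster(m, pixel_size = hdr$cellsize,
              origin = c(hdr$xllcorner, hdr$yllcorner))
}

#' @rdname read_ascii_grid
#' @param raster A raster from [make_raster()] / [read_ascii_grid()].
#' @param nodata Value written for `NA` pixels.
#' @export
write_ascii_grid <- function(raster, path, nodata = -9999) {
  v <- raster$values
  v[is.na(v)] <- nodata
  nr <- nrow(v)
  hdr <- c(
    paste("ncols", ncol(v)), paste("nrows", nr),
    paste("xllcorner", raster$origin[1]), paste("yllcorner", raster$origin[2]),
    paste("cellsize", raster$pixel_size), paste("nodata_value", nodata))
  rows <- apply(v[nr:1, , drop = FALSE], 1, paste, collapse = " ")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a point table from CSV or GeoJSON
#'
#' CSV files need `x` and `y` columns (plus any attribute columns, e.g.
#' `category`). GeoJSON must be a FeatureCollection of Point features;
#' feature properties become columns.
#'
#' @param path File path; format chosen by extension (`.geojson`/`.json` vs
#'   anything else = CSV).
#' @return A data frame with columns `x`, `y` and any attributes.
#' @export
read_points <- function(path) {
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    gj <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (is.null(gj$features)) stop("GeoJSON must be a FeatureCollection")
    rows <- lapply(gj$features, function(f) {
      if (!identical(f$geometry$type, "Point"))
        stop("only Point features are supported")
      props <- if (is.null(f$properties)) list() else f$properties
      c(list(x = f$geometry$coordinates[[1]], y = f$geometry$coordinates[[2]]),
        props)
    })
    nm <- unique(unlist(lapply(rows, names)))
    out <- lapply(nm, function(n) sapply(rows, function(r)
      if (is.null(r[[n]])) NA else r[[n]]))
    names(out) <- nm
    as.data.frame(out, stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
}

#' Write a point table as GeoJSON Point features
#'
#' @param points Data frame with `x`, `y` and attribute columns.
#' @param path Output path.
#' @export
write_points_geojson <- function(points, path) {
  attr_cols <- setdiff(names(points), c("x", "y"))
  feats <- lapply(seq_len(nrow(points)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(points$x[i], points$y[i])),
         properties = as.list(points[i, attr_cols, drop = FALSE]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

# Internal: seeded evaluation that never leaks into the caller's RNG stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
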