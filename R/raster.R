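#' Lightweight georeferenced single-band raster
#'
#' A minimal in-memory raster: a numeric matrix plus an origin (coordinates of
#' the lower-left corner, metres, projected CRS) and a square cell size.
#' Rows index northing (row 1 = southernmost row), columns index easting.
#' Categorical layers store integer codes with a `levels` attribute.
#'
#' All pipeline geometry is in a single projected metric coordinate system
#' (UTM-like); no geographic-coordinate math is performed anywhere.
#'
#' @param values numeric or integer matrix of cell values.
#' @param origin numeric length-2, easting/northing of the lower-left corner (m).
#' @param cellsize cell edge length in metres (cells are square).
#' @param levels optional character vector of category labels for integer-coded
#'   categorical rasters (codes are 1-based indices into `levels`).
#' @return an object of class `grid_raster`.
#' @export
grid_raster <- function(values, origin = c(0, 0), cellsize = 1000, levels = NULL) {
  stopifnot(is.matrix(values), length(origin) == 2, cellsize > 0)
  structure(
    list(values = values, origin = as.numeric(origin),
         cellsize = as.numeric(cellsize), levels = levels),
    class = "grid_raster"
  )
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

#' @export
print.grid_raster <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<grid_raster> %d rows x %d cols, cell %.0f m, origin (%.0f, %.0f)\n",
              d[1], d[2], x$cellsize, x$origin[1], x$origin[2]))
  if (!is.null(x$levels)) cat("  categorical:", paste(x$levels, collapse = ", "), "\n")
  rng <- suppressWarnings(range(x$values, na.rm = TRUE, finite = TRUE))
  cat(sprintf("  values in [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

#' Cell-centre coordinates of a raster
#'
#' @param r a `grid_raster`.
#' @return data.frame with columns `x`, `y`, `row`, `col`, one row per cell
#'   (column-major order, matching `as.vector(r$values)`).
#' @export
raster_xy <- function(r) {
  d <- dim(r$values)
  col <- rep(seq_len(d[2]), each = d[1])
  row <- rep(seq_len(d[1]), d[2])
  data.frame(
    x = r$origin[1] + (col - 0.5) * r$cellsize,
    y = r$origin[2] + (row - 0.5) * r$cellsize,
    row = row, col = col
  )
}

#' Extract raster values at point locations (nearest cell)
#'
#' Values are taken from the cell containing each point; no interpolation.
#' Points outside the grid return `NA`.
#'
#' @param r a `grid_raster`.
#' @param x,y point coordinates (m, same CRS as the raster).
#' @param factor if `TRUE` and the raster is categorical, return a factor.
#' @return vector of cell values at the points.
#' @export
raster_extract <- function(r, x, y, factor = TRUE) {
  d <- dim(r$values)
  col <- floor((x - r$origin[1]) / r$cellsize) + 1L
  row <- floor((y - r$origin[2]) / r$cellsize) + 1L
  ok <- col >= 1L & col <= d[2] & row >= 1L & row <= d[1]
  out <- rep(NA_real_, length(x))
  out[ok] <- r$values[cbind(row[ok], col[ok])]
  if (!is.null(r$levels) && factor) out <- factor(r$levels[out], levels = r$levels)
  out
}

#' Euclidean distance transform of a cell mask
#'
#' Per-cell Euclidean distance (metres, between cell centres) to the nearest
#' `TRUE` cell of `mask`; exactly zero on source cells. An empty source mask
#' yields an all-infinite layer with a warning.
#'
#' @param mask logical matrix or `grid_raster` whose `TRUE`/non-zero cells are
#'   the source set.
#' @param origin,cellsize georeferencing, used when `mask` is a bare matrix.
#' @return `grid_raster` of distances in metres.
#' @export
distance_transform <- function(mask, origin = c(0, 0), cellsize = 1000) {
  if (inherits(mask, "grid_raster")) {
    origin <- mask$origin; cellsize <- mask$cellsize; mask <- mask$values
  }
  m <- mask != 0 & !is.na(mask)
  if (!any(m)) {
    warning("empty source mask: distance layer is infinite everywhere")
    return(grid_raster(matrix(Inf, nrow(m), ncol(m)), origin, cellsize))
  }
  # distmap() measures pixel-centre distance to the nearest zero pixel,
  # so feed it the complement of the source mask
  d <- EBImage::distmap(matrix(as.numeric(!m), nrow(m), ncol(m)))
  grid_raster(as.matrix(d) * cellsize, origin, cellsize)
}

#' Write / read a raster as an ESRI ASCII grid
#'
#' Plain-text single-band format readable by standard GIS software. Category
#' labels are not stored in the file; pass `levels` when reading a categorical
#' layer back.
#'
#' @param r a `grid_raster`.
#' @param path file path (conventionally `.asc`).
#' @param digits significant digits written.
#' @return `write_asc` returns `path` invisibly; `read_asc` returns a
#'   `grid_raster`.
#' @export
write_asc <- function(r, path, digits = 8) {
  d <- dim(r$values)
  hdr <- c(
    paste("ncols", d[2]), paste("nrows", d[1]),
    paste("xllcorner", format(r$origin[1], scientific = FALSE)),
    paste("yllcorner", format(r$origin[2], scientific = FALSE)),
    paste("cellsize", format(r$cellsize, scientific = FALSE)),
    "NODATA_value -9999"
  )
  v <- r$values
  v[is.na(v)] <- -9999
  # ESRI rows run north -> south; internal storage is south -> north
  body <- apply(v[rev(seq_len(d[1])), , drop = FALSE], 1,
                function(row) paste(signif(row, digits), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_asc
#' @param levels optional category labels to attach on read.
#' @export
read_asc <- function(path, levels = NULL) {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  vals <- scan(path, skip = 6, quiet = TRUE)
  m <- matrix(vals, nrow = h[["nrows"]], ncol = h[["ncols"]], byrow = TRUE)
  m[m == h[["nodata_value"]]] <- NA
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  if (!is.null(levels)) m <- matrix(as.integer(m), nrow(m), ncol(m))
  grid_raster(m, c(h[["xllcorner"]], h[["yllcorner"]]), h[["cellsize"]], levels)
}

# shared category codings
veg_levels <- function() c("forest", "woodland", "nonforest")
region_levels <- function() c("lakeshore", "inland")
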