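#' Gridded fields on a regular latitude-longitude raster
#'
#' A `grid_field` holds one geophysical variable on a regular lat-lon grid.
#' Coordinates are unprojected degrees and always refer to **cell centers**;
#' the grid origin is the center of cell `[1, 1]` (south-west corner).
#' Values are stored as a matrix with rows indexing latitude (south to
#' north) and columns indexing longitude (west to east). Missing cells are
#' `NA`.
#'
#' @param values numeric matrix, `nrow` = number of latitude rows, `ncol` =
#'   number of longitude columns; `NA` marks missing cells.
#' @param origin length-2 numeric `c(lon, lat)`: center of cell `[1, 1]`,
#'   degrees east / north.
#' @param cell length-2 numeric `c(dlon, dlat)` cell size in degrees (a
#'   scalar is recycled to both axes); must be positive.
#' @param var variable name (e.g. `"aod550"`, `"pblh"`).
#' @param units unit string (e.g. `"km"`, `"%"`, `"1"` for unitless).
#' @param time optional valid time, anything coercible by [as.Date()].
#'
#' @return An object of class `grid_field`.
#' @export
grid_field <- function(values, origin, cell, var = "value", units = "1",
                       time = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(cell) == 1L) cell <- c(cell, cell)
  stopifnot(length(origin) == 2L, length(cell) == 2L)
  if (any(!is.finite(cell)) || any(cell <= 0)) {
    stop("grid cell size must be positive and finite", call. = FALSE)
  }
  structure(
    list(values = values, origin = as.numeric(origin),
         cell = as.numeric(cell), var = as.character(var),
         units = as.character(units),
         time = if (is.null(time)) NULL else as.Date(time)),
    class = "grid_field")
}

#' @export
print.grid_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<grid_field> %s [%s], %d x %d cells, %.4g x %.4g deg\n",
              x$var, x$units, d[1], d[2], x$cell[1], x$cell[2]))
  cat(sprintf("  origin (%.4f E, %.4f N); %d missing cells%s\n",
              x$origin[1], x$origin[2], sum(is.na(x$values)),
              if (is.null(x$time)) "" else paste0("; time ", x$time)))
  invisible(x)
}

#' Cell-center coordinate vectors of a grid
#'
#' @param field a [grid_field()].
#' @return list with numeric vectors `lon` (length `ncol`) and `lat`
#'   (length `nrow`).
#' @export
grid_coords <- function(field) {
  d <- dim(field$values)
  list(lon = field$origin[1] + (seq_len(d[2]) - 1) * field$cell[1],
       lat = field$origin[2] + (seq_len(d[1]) - 1) * field$cell[2])
}

## Cell index along one axis under the half-open [west, east) convention:
## cell i owns [center_i - h/2, center_i + h/2). A point on a shared edge
## belongs to the cell whose west/south edge it is; the 1e-9-cell epsilon
## keeps that deterministic for edge coordinates that are not exactly
## representable in binary. Returns NA outside the grid.
.axis_index <- function(x, origin, h, n) {
  i <- floor((x - (origin - h / 2)) / h + 1e-9) + 1
  i[i < 1 | i > n] <- NA_integer_
  as.integer(i)
}

#' Value of the grid cell containing a point
#'
#' Cell membership is half-open: each cell owns
#' `[center - h/2, center + h/2)` on both axes, so a point lying exactly on
#' a shared edge belongs to the cell whose west (or south) edge it is.
#' Satellite AOD is collocated to stations this way: the retrieval of the
#' pixel in which the station sits, never interpolated across pixels.
#'
#' @param field a [grid_field()].
#' @param lon,lat point coordinates, degrees.
#' @return the cell value, or `NA` if the point falls outside the grid or
#'   the containing cell is missing.
#' @export
pixel_at <- function(field, lon, lat) {
  d <- dim(field$values)
  j <- .axis_index(lon, field$origin[1], field$cell[1], d[2])
  i <- .axis_index(lat, field$origin[2], field$cell[2], d[1])
  out <- rep(NA_real_, length(i))
  ok <- !is.na(i) & !is.na(j)
  out[ok] <- field$values[cbind(i[ok], j[ok])]
  out
}

#' Bilinear interpolation at a point
#'
#' Standard bilinear combination of the four cell-center values surrounding
#' the point. Used for meteorological fields, which are smooth and coarser
#' than the AOD grid. Returns `NA` when the point lies outside the convex
#' hull of cell centers or any of the four neighbours is missing.
#'
#' @inheritParams pixel_at
#' @return interpolated value(s), `NA` where undefined.
#' @export
bilinear_at <- function(field, lon, lat) {
  d <- dim(field$values)
  fx <- (lon - field$origin[1]) / field$cell[1]   # 0-based fractional col
  fy <- (lat - field$origin[2]) / field$cell[2]
  j0 <- pmin(pmax(floor(fx), 0), d[2] - 2)        # clamp so j0+1 exists
  i0 <- pmin(pmax(floor(fy), 0), d[1] - 2)
  out <- rep(NA_real_, length(fx))
  ok <- fx >= 0 & fx <= d[2] - 1 & fy >= 0 & fy <= d[1] - 1 &
    is.finite(fx) & is.finite(fy)
  if (d[2] < 2 || d[1] < 2) return(out)
  tx <- fx - j0
  ty <- fy - i0
  v00 <- field$values[cbind(i0 + 1, j0 + 1)]
  v01 <- field$values[cbind(i0 + 1, j0 + 2)]
  v10 <- field$values[cbind(i0 + 2, j0 + 1)]
  v11 <- field$values[cbind(i0 + 2, j0 + 2)]
  val <- (1 - ty) * ((1 - tx) * v00 + tx * v01) +
    ty * ((1 - tx) * v10 + tx * v11)
  out[ok] <- val[ok]
  out
}

#' Read / write gridded fields as long-form CSV
#'
#' The on-disk dialect is a plain long-form CSV with columns
#' `lon,lat,time,value` (one row per cell, latitude varying fastest;
#' missing cells have an empty `value`), preceded by `#`-prefixed metadata
#' lines carrying the variable name, units, origin and cell size. The
#' format is text-only and round-trips values, mask and geometry exactly
#' (coordinates and values are written with 17 significant digits).
#'
#' @param field a [grid_field()].
#' @param path file path.
#' @return `read_grid` returns a [grid_field()]; `write_grid` returns
#'   `path` invisibly.
#' @export
write_grid <- function(field, path) {
  co <- grid_coords(field)
  d <- dim(field$values)
  lon <- rep(co$lon, each = d[1])
  lat <- rep(co$lat, times = d[2])
  val <- as.vector(field$values)
  meta <- c(
    sprintf("# variable: %s", field$var),
    sprintf("# units: %s", field$units),
    sprintf("# origin: %.17g %.17g", field$origin[1], field$origin[2]),
    sprintf("# cell: %.17g %.17g", field$cell[1], field$cell[2]),
    sprintf("# dim: %d %d", d[1], d[2]),
    sprintf("# time: %s", if (is.null(field$time)) "NA"
            else format(field$time)))
  tm <- if (is.null(field$time)) "" else format(field$time)
  body <- sprintf("%.17g,%.17g,%s,%s", lon, lat, tm,
                  ifelse(is.na(val), "", sprintf("%.17g", val)))
  writeLines(c(meta, "lon,lat,time,value", body), path)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  meta_l <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(sprintf("^# %s:", key), meta_l, value = TRUE)
    if (!length(m)) stop("grid file lacks '# ", key, ":' header",
                         call. = FALSE)
    trimws(sub(sprintf("^# %s:", key), "", m[1]))
  }
  origin <- as.numeric(strsplit(get("origin"), "\\s+")[[1]])
  cell <- as.numeric(strsplit(get("cell"), "\\s+")[[1]])
  dm <- as.integer(strsplit(get("dim"), "\\s+")[[1]])
  tms <- get("time")
  units <- get("units")
  known <- c("1", "km", "m", "%", "K", "Pa", "hPa", "m/s", "mm",
             "ug/m3", "1/km")
  if (!units %in% known) {
    warning("unrecognised units string '", units, "' passed through",
            call. = FALSE)
  }
  df <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]),
                        colClasses = c("numeric", "numeric", "character",
                                       "numeric"))
  if (nrow(df) != prod(dm)) {
    stop(sprintf("grid file has %d data rows but dim header implies %d",
                 nrow(df), prod(dm)), call. = FALSE)
  }
  values <- matrix(df$value, nrow = dm[1], ncol = dm[2])
  grid_field(values, origin = origin, cell = cell, var = get("variable"),
             units = units, time = if (tms == "NA") NULL else tms)
}

#' Evaluate a function of (lon, lat) on a grid
#'
#' Convenience constructor: builds a `grid_field` whose cell `[i, j]` holds
#' `f(lon_j, lat_i)` evaluated at cell centers.
#'
#' @param f vectorised function of two arguments `(lon, lat)`.
#' @param origin,cell,var,units,time as in [grid_field()].
#' @param nlat,nlon grid dimensions.
#' @return a [grid_field()].
#' @export
grid_from_function <- function(f, origin, cell, nlat, nlon, var = "value",
                               units = "1", time = NULL) {
  if (length(cell) == 1L) cell <- c(cell, cell)
  lon <- origin[1] + (seq_len(nlon) - 1) * cell[1]
  lat <- origin[2] + (seq_len(nlat) - 1) * cell[2]
  vals <- outer(lat, lon, function(la, lo) f(lo, la))
  grid_field(vals, origin, cell, var = var, units = units, time = time)
}
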