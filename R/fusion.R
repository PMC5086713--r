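#' Satellite AOD granules and Dark Target / Deep Blue fusion
#'
#' An `aod_granule` is a [grid_field()] of AOD at 550 nm plus a per-cell
#' quality-assurance (QA) flag and the retrieval algorithm tag. Dark
#' Target (DT) retrieves at 3 km over dark vegetated surfaces and fails
#' over bright desert/urban ground; Deep Blue (DB) retrieves at 10 km and
#' covers bright surfaces. The fusion stage keeps only trusted retrievals
#' (QA = 3 for DT; QA >= 2 for DB), brings DB onto the fine DT grid, and
#' fills DT gaps with DB — finer resolution and stricter QA win wherever
#' both exist.
#'
#' @param field [grid_field()] of AOD values (unitless, 550 nm).
#' @param qa integer matrix of QA flags 0-3 (0 = bad .. 3 = very good),
#'   congruent with `field$values`; QA must be defined wherever the value
#'   is.
#' @param algorithm `"DT"` or `"DB"`.
#' @param resolution_km nominal resolution; 3 for DT, 10 for DB.
#' @return object of class `aod_granule`.
#' @export
aod_granule <- function(field, qa, algorithm = c("DT", "DB"),
                        resolution_km = NULL) {
  algorithm <- match.arg(algorithm)
  qa <- as.matrix(qa)
  storage.mode(qa) <- "integer"
  if (!identical(dim(qa), dim(field$values))) {
    stop("QA layer and AOD values are not congruent", call. = FALSE)
  }
  if (any(!is.na(field$values) & is.na(qa))) {
    stop("QA flag missing where AOD value is defined", call. = FALSE)
  }
  if (any(qa < 0L | qa > 3L, na.rm = TRUE)) {
    stop("QA flags must be integers 0..3", call. = FALSE)
  }
  if (is.null(resolution_km)) {
    resolution_km <- if (algorithm == "DT") 3 else 10
  }
  structure(list(field = field, qa = qa, algorithm = algorithm,
                 resolution_km = resolution_km),
            class = "aod_granule")
}

#' @export
print.aod_granule <- function(x, ...) {
  cat(sprintf("<aod_granule> %s %g km\n", x$algorithm, x$resolution_km))
  print(x$field)
  invisible(x)
}

#' Mask retrievals below the required quality assurance
#'
#' DT retrievals are kept only at the highest confidence (QA = 3); DB
#' retrievals at QA 2 or 3. Values passing the filter are untouched.
#'
#' @param granule an [aod_granule()].
#' @return the granule with sub-threshold cells set to `NA`.
#' @export
apply_qa_filter <- function(granule) {
  if (is.null(granule$qa)) stop("granule has no QA layer", call. = FALSE)
  keep <- if (granule$algorithm == "DT") granule$qa == 3L
          else granule$qa >= 2L
  v <- granule$field$values
  v[!keep | is.na(keep)] <- NA_real_
  granule$field$values <- v
  granule
}

#' Assign coarse Deep Blue values onto the fine grid
#'
#' Each fine cell takes the value of the 10 km cell **containing its
#' center** (nearest-cell containment, not interpolation, so retrievals
#' are never smeared across surface-type boundaries). Fine cells whose
#' centers fall outside DB coverage are missing.
#'
#' @param db_granule a (typically QA-filtered) DB [aod_granule()].
#' @param fine_spec a [grid_field()] (or any object with `origin`, `cell`
#'   and `values` dimensions) defining the target fine grid.
#' @return a [grid_field()] on the fine grid.
#' @export
regrid_db_to_fine <- function(db_granule, fine_spec) {
  co <- grid_coords(fine_spec)
  db <- db_granule$field
  d <- dim(db$values)
  j <- .axis_index(co$lon, db$origin[1], db$cell[1], d[2])
  i <- .axis_index(co$lat, db$origin[2], db$cell[2], d[1])
  if (all(is.na(i)) || all(is.na(j))) {
    stop("DB granule and fine grid do not overlap", call. = FALSE)
  }
  nlat <- length(co$lat); nlon <- length(co$lon)
  vals <- matrix(NA_real_, nlat, nlon)
  ok_i <- which(!is.na(i)); ok_j <- which(!is.na(j))
  vals[ok_i, ok_j] <- db$values[cbind(rep(i[ok_i], length(ok_j)),
                                      rep(j[ok_j], each = length(ok_i)))]
  grid_field(vals, origin = fine_spec$origin, cell = fine_spec$cell,
             var = db$var, units = db$units, time = db$time)
}

#' Fuse DT and DB AOD on the fine grid
#'
#' Complementary-advantage precedence: the output equals DT wherever DT is
#' valid, else DB, else missing. The fusion never invents values — every
#' output cell is one of its two inputs — and its missing set is exactly
#' the intersection of the input missing sets.
#'
#' @param dt_filtered QA-filtered DT granule (or a bare [grid_field()])
#'   on the fine grid.
#' @param db_on_fine DB values regridded to the fine grid
#'   ([regrid_db_to_fine()]).
#' @return fused [grid_field()] on the fine grid.
#' @export
fuse_dt_db <- function(dt_filtered, db_on_fine) {
  dt <- if (inherits(dt_filtered, "aod_granule")) dt_filtered$field
        else dt_filtered
  if (!identical(dim(dt$values), dim(db_on_fine$values)) ||
      any(abs(dt$origin - db_on_fine$origin) > 1e-9) ||
      any(abs(dt$cell - db_on_fine$cell) > 1e-9)) {
    stop("DT and DB-on-fine grids do not match", call. = FALSE)
  }
  v <- dt$values
  take_db <- is.na(v)
  v[take_db] <- db_on_fine$values[take_db]
  grid_field(v, origin = dt$origin, cell = dt$cell, var = dt$var,
             units = dt$units, time = dt$time)
}
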