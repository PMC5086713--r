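#' Time-zone offset of a longitude
#'
#' Station clocks report Beijing time (UTC+8) but the satellite observes
#' at ~13:30 *local solar* time, and the study domain spans five time
#' zones. Longitudes are mapped to integer UTC offsets +5..+9 by nominal
#' 15-degree solar bands centered on 75/90/105/120/135 E (band edges at
#' 67.5, 82.5, 97.5, 112.5, 127.5, 142.5 E).
#'
#' @param lon longitude, degrees east.
#' @param edges band-edge longitudes (see [run_config()]).
#' @return integer UTC offset(s) in hours.
#' @export
zone_offset <- function(lon, edges = seq(67.5, 142.5, by = 15)) {
  band <- findInterval(lon, edges, rightmost.closed = FALSE)
  if (any(band < 1 | band >= length(edges) | lon == edges[length(edges)])) {
    stop("longitude outside the configured time-zone bands", call. = FALSE)
  }
  as.integer(4L + band)
}

#' Local calendar date of a Beijing-time stamp
#'
#' @param date Beijing calendar date (`Date`).
#' @param hour_beijing Beijing clock hour 0-23.
#' @param offset UTC offset from [zone_offset()].
#' @return `Date` on the station's local clock.
#' @export
local_date <- function(date, hour_beijing, offset) {
  lh <- hour_beijing - (8L - offset)       # local clock hour, may leave 0-23
  as.Date(date) + ifelse(lh < 0, -1L, ifelse(lh > 23, 1L, 0L))
}

#' Average PM2.5 at satellite overpass time
#'
#' Aqua crosses at ~13:30 local solar time, so the ground truth for one
#' station-day is the mean of the 13:00 and 14:00 *local* records. With
#' records stamped in Beijing time those are Beijing hours
#' `13 + 8 - offset` and `14 + 8 - offset`. If only one of the two hours
#' was reported it is used alone (logged by the caller); if neither,
#' the station-day is missing.
#'
#' @param records data.frame of one station-day's records (columns
#'   `hour_beijing`, `pm25`).
#' @param offset UTC offset of the station from [zone_offset()].
#' @return list with `pm25` (numeric or `NA`) and `n_hours` used (0,1,2).
#' @export
overpass_pm25 <- function(records, offset) {
  hours <- c(13L, 14L) + (8L - offset)
  v <- records$pm25[match(hours, records$hour_beijing)]
  v <- v[!is.na(v)]
  list(pm25 = if (length(v)) mean(v) else NA_real_,
       n_hours = length(v))
}

#' Previous-day precipitation at a station
#'
#' The model regresses on total precipitation of the day *before* the
#' estimation day, resolved on the station's local calendar (a station in
#' the UTC+5 band and one in UTC+9 can therefore index different grids
#' near midnight). The value is bilinearly interpolated from the day-1
#' precipitation grid.
#'
#' @param precip_stack named list of precipitation [grid_field()]s, names
#'   being `"%Y-%m-%d"` dates.
#' @param lon,lat station coordinates.
#' @param day estimation day on the station's local calendar (`Date`).
#' @return precipitation in mm, or `NA` if the day-1 grid is absent or
#'   the station lies outside it.
#' @export
prev_day_precip <- function(precip_stack, lon, lat, day) {
  key <- format(as.Date(day) - 1L)
  if (!key %in% names(precip_stack)) return(NA_real_)
  bilinear_at(precip_stack[[key]], lon, lat)
}

#' Assemble collocated model rows for one day
#'
#' Builds the complete-case regression table for one estimation day: for
#' every station it takes the overpass-time PM2.5 (Beijing-to-local clock
#' arithmetic per time-zone band), the fused AOD at the **containing
#' pixel**, bilinearly interpolated meteorology (PBLH, RH, surface
#' temperature, pressure, u/v wind), and the previous local day's
#' precipitation; then applies the physical corrections. Wind speed is
#' the magnitude `sqrt(u^2 + v^2)`. Any station missing any ingredient,
#' or wetter than `rh_cap`, is excluded and counted, never imputed.
#'
#' @param fused fused AOD [grid_field()] for the day (fine grid).
#' @param met named list of meteorology [grid_field()]s with elements
#'   `pblh` (km), `rh` (percent), `st` (K), `ps` (Pa), `u`, `v` (m/s).
#' @param precip_stack named list of daily precipitation grids (mm), see
#'   [prev_day_precip()].
#' @param stations data.frame with `station_id`, `lon`, `lat`.
#' @param records station records data.frame ([read_station_csv()])
#'   restricted to the relevant dates.
#' @param day estimation day (`Date`).
#' @param config a [run_config()].
#' @return data.frame of model rows (one per retained station) with
#'   columns `station_id, lon, lat, day, revised_aod, last_prec, st, ps,
#'   ws, rh, pblh, revised_pm25, pm25`, plus attributes `n_excluded` and
#'   `exclusions` (a named count by reason).
#' @export
build_model_rows <- function(fused, met, precip_stack, stations, records,
                             day, config = run_config()) {
  day <- as.Date(day)
  n <- nrow(stations)
  offset <- zone_offset(stations$lon, config$tz_band_edges)
  excl <- c(no_pm25 = 0L, no_aod = 0L, no_met = 0L, no_precip = 0L,
            high_rh = 0L)

  pm <- rep(NA_real_, n)
  for (s in seq_len(n)) {
    rec <- records[records$station_id == stations$station_id[s] &
                     records$date == day, , drop = FALSE]
    pm[s] <- overpass_pm25(rec, offset[s])$pm25
  }
  aod <- pixel_at(fused, stations$lon, stations$lat)
  pblh <- bilinear_at(met$pblh, stations$lon, stations$lat)
  rh <- bilinear_at(met$rh, stations$lon, stations$lat)
  st <- bilinear_at(met$st, stations$lon, stations$lat)
  ps <- bilinear_at(met$ps, stations$lon, stations$lat)
  u <- bilinear_at(met$u, stations$lon, stations$lat)
  v <- bilinear_at(met$v, stations$lon, stations$lat)
  lp <- vapply(seq_len(n), function(s) {
    prev_day_precip(precip_stack, stations$lon[s], stations$lat[s],
                    local_date(day, 21L - offset[s], offset[s]))
  }, numeric(1))

  met_ok <- is.finite(pblh) & pblh > 0 & is.finite(rh) & is.finite(st) &
    is.finite(ps) & is.finite(u) & is.finite(v)
  high_rh <- met_ok & rh > config$rh_cap
  keep <- is.finite(pm) & is.finite(aod) & met_ok & is.finite(lp) & !high_rh
  excl["no_pm25"] <- sum(!is.finite(pm))
  excl["no_aod"] <- sum(is.finite(pm) & !is.finite(aod))
  excl["no_met"] <- sum(is.finite(pm) & is.finite(aod) & !met_ok)
  excl["no_precip"] <- sum(is.finite(pm) & is.finite(aod) & met_ok &
                             !high_rh & !is.finite(lp))
  excl["high_rh"] <- sum(is.finite(pm) & is.finite(aod) & high_rh)

  if (!any(keep)) {
    stop("no complete station row for ", format(day),
         ": all stations missing at least one ingredient", call. = FALSE)
  }
  rows <- data.frame(
    station_id = stations$station_id[keep],
    lon = stations$lon[keep], lat = stations$lat[keep], day = day,
    revised_aod = revise_aod(aod[keep], pblh[keep]),
    last_prec = lp[keep], st = st[keep], ps = ps[keep],
    ws = sqrt(u[keep]^2 + v[keep]^2), rh = rh[keep], pblh = pblh[keep],
    pm25 = pm[keep], stringsAsFactors = FALSE)
  rows$revised_pm25 <- revise_pm25(rows$pm25, rows$rh, config$rh_cap)
  attr(rows, "n_excluded") <- sum(!keep)
  attr(rows, "exclusions") <- excl
  rows
}
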