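#' Read hourly station PM2.5 records
#'
#' Station records are one row per station-hour with columns
#' `station_id, lon, lat, date, hour_beijing, pm25`. Timestamps are clock
#' time in Beijing time (UTC+8), the convention of the national reporting
#' network, regardless of the station's own time zone. PM2.5 is the dry
#' mass concentration as measured (TEOM-style), in ug/m3.
#'
#' Rows violating the record invariants (negative PM2.5, hour outside
#' 0-23, coordinates outside `domain` when one is given, unparseable
#' date) are rejected with an error naming the offending row numbers;
#' nothing is silently coerced.
#'
#' @param path CSV file path.
#' @param domain optional length-4 numeric
#'   `c(lon_min, lon_max, lat_min, lat_max)`; when given, records outside
#'   it are invalid.
#' @return data.frame with columns `station_id` (character), `lon`, `lat`
#'   (numeric degrees), `date` (`Date`, Beijing calendar date),
#'   `hour_beijing` (integer), `pm25` (numeric ug/m3).
#' @export
read_station_csv <- function(path, domain = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        strip.white = TRUE)
  need <- c("station_id", "lon", "lat", "date", "hour_beijing", "pm25")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("station CSV missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    station_id = df$station_id,
    lon = suppressWarnings(as.numeric(df$lon)),
    lat = suppressWarnings(as.numeric(df$lat)),
    date = as.Date(df$date, optional = TRUE),
    hour_beijing = suppressWarnings(as.integer(df$hour_beijing)),
    pm25 = suppressWarnings(as.numeric(df$pm25)),
    stringsAsFactors = FALSE)
  bad <- !is.finite(out$pm25) | out$pm25 < 0 |
    is.na(out$hour_beijing) | out$hour_beijing < 0 | out$hour_beijing > 23 |
    !is.finite(out$lon) | !is.finite(out$lat) | is.na(out$date)
  if (!is.null(domain)) {
    bad <- bad | out$lon < domain[1] | out$lon > domain[2] |
      out$lat < domain[3] | out$lat > domain[4]
  }
  if (any(bad)) {
    stop("invalid station record(s) at data row(s): ",
         paste(utils::head(which(bad), 20), collapse = ", "),
         if (sum(bad) > 20) sprintf(" (and %d more)", sum(bad) - 20) else "",
         call. = FALSE)
  }
  out
}

#' @rdname read_station_csv
#' @param records data.frame as returned by `read_station_csv`.
#' @export
write_station_csv <- function(records, path) {
  df <- records
  df$lon <- sprintf("%.17g", df$lon)
  df$lat <- sprintf("%.17g", df$lat)
  df$pm25 <- sprintf("%.17g", df$pm25)
  df$date <- format(df$date)
  utils::write.csv(
    df[, c("station_id", "lon", "lat", "date", "hour_beijing", "pm25")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
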