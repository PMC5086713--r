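#' Seasonal mean of a stack of daily fields
#'
#' Per-cell mean over the days on which the cell is valid; cells with
#' fewer than `min_valid_days` valid days are masked, since sparse
#' satellite coverage (bright or snow-covered surfaces) makes a mean of
#' one or two retrievals unrepresentative of a season.
#'
#' @param fields list of [grid_field()]s sharing one grid.
#' @param min_valid_days minimum number of valid days per cell.
#' @return a [grid_field()] of per-cell means.
#' @export
seasonal_mean <- function(fields, min_valid_days = 5L) {
  if (!length(fields)) stop("empty field stack", call. = FALSE)
  ref <- fields[[1]]
  for (f in fields) {
    if (!identical(dim(f$values), dim(ref$values)) ||
        any(abs(f$origin - ref$origin) > 1e-9) ||
        any(abs(f$cell - ref$cell) > 1e-9)) {
      stop("fields in the stack do not share one grid", call. = FALSE)
    }
  }
  d <- dim(ref$values)
  sum_v <- matrix(0, d[1], d[2])
  n_v <- matrix(0L, d[1], d[2])
  for (f in fields) {
    ok <- !is.na(f$values)
    sum_v[ok] <- sum_v[ok] + f$values[ok]
    n_v <- n_v + ok
  }
  out <- sum_v / n_v
  out[n_v < min_valid_days] <- NA_real_
  grid_field(out, ref$origin, ref$cell, var = paste0(ref$var, "_mean"),
             units = ref$units)
}

#' Exceedance of an air-quality standard, in percent
#'
#' `(concentration - standard) / standard * 100`: e.g. a seasonal mean
#' of 60 ug/m3 exceeds the WHO interim target 3 level of 15 ug/m3 by
#' 300 percent. Linear in concentration and invariant under joint
#' rescaling of concentration and standard.
#'
#' @param concentration PM2.5 concentration(s), ug/m3.
#' @param standard threshold, ug/m3, `> 0`; see [who_it_levels].
#' @return exceedance in percent (negative below the standard).
#' @export
who_exceedance_pct <- function(concentration, standard) {
  if (any(standard <= 0)) stop("standard must be > 0", call. = FALSE)
  (concentration - standard) / standard * 100
}

#' WHO interim-target PM2.5 levels (ug/m3)
#'
#' Interim target 1 (35 ug/m3) and interim target 3 (15 ug/m3) annual
#' mean levels for PM2.5.
#' @export
who_it_levels <- c(it1 = 35, it3 = 15)

#' Descriptive statistics with histogram bin counts
#'
#' @param values numeric vector (`NA` dropped), at least 2 finite
#'   values.
#' @param bins number of equal-width histogram bins, or a vector of
#'   break points.
#' @return list with `n, mean, sd, min, max, breaks, counts`; `sd` is
#'   the n-1 sample standard deviation and `counts` always sums to `n`.
#' @export
descriptive_stats <- function(values, bins = 30L) {
  v <- values[is.finite(values)]
  if (length(v) < 2) {
    stop("need at least 2 finite values", call. = FALSE)
  }
  h <- graphics::hist(v, breaks = bins, plot = FALSE)
  list(n = length(v), mean = mean(v), sd = stats::sd(v), min = min(v),
       max = max(v), breaks = h$breaks, counts = h$counts)
}
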