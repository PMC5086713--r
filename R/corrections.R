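#' Physical corrections relating column AOD and dry PM2.5 to
#' near-surface ambient conditions
#'
#' Satellite AOD measures extinction over the whole atmospheric column,
#' while station PM2.5 is measured near the ground after drying the
#' sampled air. Two standard corrections reconcile the scales:
#'
#' * **Vertical correction** — aerosol is assumed well mixed within the
#'   planetary boundary layer, so column AOD divided by boundary-layer
#'   height (km) proxies the near-surface extinction coefficient:
#'   `revised_aod = aod / pblh_km` (units 1/km).
#' * **Hygroscopic correction** — ambient particles swell with relative
#'   humidity; the dry-measured mass is inflated by the growth factor
#'   `(1 - RH/100)^-1`: `revised_pm25 = pm25 / (1 - rh_pct/100)`.
#'
#' `dry_pm25()` is the exact inverse of `revise_pm25()`, used to report
#' model predictions back on the measured (dry) scale. All three are
#' vectorised and exact arithmetic: `dry_pm25(revise_pm25(x, r), r) == x`
#' to machine precision.
#'
#' @param aod column aerosol optical depth at 550 nm, unitless, `>= 0`.
#' @param pblh_km planetary boundary layer height in km, `> 0`.
#' @param pm25 dry PM2.5 mass concentration, ug/m3, `>= 0`.
#' @param revised_pm25 humidity-corrected (ambient) PM2.5, ug/m3.
#' @param rh_pct relative humidity in percent, `0 <= rh_pct <= rh_cap`.
#' @param rh_cap maximum admissible RH (percent, `< 100`); see
#'   [run_config()].
#' @return numeric vector of corrected values.
#' @name corrections
NULL

#' @rdname corrections
#' @export
revise_aod <- function(aod, pblh_km) {
  if (any(!is.finite(pblh_km) | pblh_km <= 0)) {
    stop("pblh_km must be positive", call. = FALSE)
  }
  if (any(!is.finite(aod) | aod < 0)) {
    stop("aod must be non-negative", call. = FALSE)
  }
  aod / pblh_km
}

.check_rh <- function(rh_pct, rh_cap) {
  if (any(!is.finite(rh_pct) | rh_pct < 0 | rh_pct > rh_cap)) {
    stop(sprintf("rh_pct must lie in [0, %g]", rh_cap), call. = FALSE)
  }
}

#' @rdname corrections
#' @export
revise_pm25 <- function(pm25, rh_pct, rh_cap = 95) {
  .check_rh(rh_pct, rh_cap)
  if (any(!is.finite(pm25) | pm25 < 0)) {
    stop("pm25 must be non-negative", call. = FALSE)
  }
  pm25 / (1 - rh_pct / 100)
}

#' @rdname corrections
#' @export
dry_pm25 <- function(revised_pm25, rh_pct, rh_cap = 95) {
  .check_rh(rh_pct, rh_cap)
  revised_pm25 * (1 - rh_pct / 100)
}
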