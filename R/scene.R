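#' Synthetic-scene configuration
#'
#' The generator emulates the study conditions of a national-scale
#' satellite PM2.5 analysis on a 10 x 10 degree window: an unevenly
#' clustered station network, smooth spatially varying regression
#' coefficient surfaces, meteorological fields with log-normal / Weibull
#' marginals (optionally bimodal pressure), and paired Dark Target
#' (0.03 degree, emulating 3 km) / Deep Blue (0.1 degree, emulating
#' 10 km) AOD granules with QA flags and bright-surface missingness.
#' Every artifact is a deterministic function of `(config, seed)`.
#'
#' Magnitudes follow the descriptive statistics of the real study
#' domain: dry PM2.5 averaging ~50 ug/m3, AOD ~0.5, boundary-layer
#' height ~1 km, surface RH ~55 percent, pressure ~960 hPa (with an
#' optional low-pressure plateau mode), and mostly-zero previous-day
#' precipitation.
#'
#' @param domain `c(lon_min, lon_max, lat_min, lat_max)` degrees.
#' @param fine_cell,coarse_cell grid cells (degrees) emulating the 3 km
#'   DT and 10 km DB products (0.03 / 0.1 preserves the resolution
#'   ratio without projection machinery).
#' @param met_cell,precip_cell meteorology and precipitation grid cells.
#' @param n_stations station count.
#' @param clustering fraction of stations drawn around urban cluster
#'   centers (0 = spatially uniform network).
#' @param n_clusters,cluster_sd cluster count and spread (degrees).
#' @param n_days number of consecutive estimation days.
#' @param start_date first estimation day.
#' @param beta_mean,beta_amp length-6 means and perturbation amplitudes
#'   of the coefficient surfaces (intercept, revised AOD, previous-day
#'   precipitation, surface temperature, pressure, wind speed), units
#'   matching the regression term by term.
#' @param corr_length correlation length (degrees) of the coefficient
#'   surfaces; perturbations are superposed sinusoids with wavelengths
#'   at or above this length.
#' @param n_waves sinusoid components per coefficient surface.
#' @param noise_sd observation noise SD on the revised (humidity
#'   corrected) PM2.5 scale, ug/m3.
#' @param jitter_sd hour-to-hour jitter SD of the two overpass-hour
#'   records around the daily value, ug/m3 (dry scale).
#' @param pblh_meanlog,pblh_sdlog log-normal parameters of PBLH (km).
#' @param rh_shape,rh_mean Weibull shape and mean (percent) of surface
#'   RH; values are capped at `rh_cap`.
#' @param st_meanlog,st_sdlog log-normal parameters of surface
#'   temperature (K).
#' @param ps_mean,ps_sd pressure mean/SD (Pa); with
#'   `ps_bimodal = TRUE` a low-pressure plateau mode
#'   (`ps_low_mean`, `ps_low_sd`, weight `ps_low_w`) is mixed in.
#' @param ps_bimodal,ps_low_mean,ps_low_sd,ps_low_w see above.
#' @param wind_mean,wind_sd normal parameters of each wind component
#'   (m/s).
#' @param precip_p0,precip_mean zero-inflation probability and
#'   exponential mean (mm) of daily precipitation.
#' @param aod_meanlog,aod_sdlog log-normal parameters of the latent
#'   near-surface extinction proxy (revised AOD, 1/km) driving the
#'   granules.
#' @param bright_fraction probability that a fine cell is bright surface
#'   (DT retrieval fails there; DB still covers it).
#' @param dt_noise_sd,db_noise_sd retrieval noise SD added to DT values
#'   and to the block-averaged DB values.
#' @param qa_probs_dt,qa_probs_db length-4 probabilities of QA flags
#'   0..3.
#' @param rh_cap maximum admissible RH, percent.
#' @param smooth_waves sinusoid components per smooth Gaussian field
#'   (meteorology); more components give closer-to-normal marginals.
#' @param met_corr_length correlation length (degrees) of the
#'   meteorological fields (synoptic scale).
#' @param aod_corr_length correlation length (degrees) of the latent
#'   extinction field; aerosol plumes decorrelate over ~100 km, far
#'   faster than synoptic meteorology, and this short-scale contrast is
#'   what identifies the local AOD slope.
#' @param noiseless if `TRUE`, zero out observation, jitter and
#'   retrieval noise, the bright-surface mask, and force all QA flags
#'   to 3 — the configuration under which the pipeline must reproduce
#'   the recorded PM2.5 exactly.
#' @return object of class `scene_config` (named list).
#' @export
scene_config <- function(domain = c(95, 105, 27.5, 37.5),
                         fine_cell = 0.03, coarse_cell = 0.1,
                         met_cell = 0.25, precip_cell = 0.5,
                         n_stations = 400L, clustering = 0.5,
                         n_clusters = 6L, cluster_sd = 0.7,
                         n_days = 30L, start_date = "2015-01-01",
                         beta_mean = c(160, 80, -2, -0.5, 5e-4, -1.5),
                         beta_amp = c(25, 20, 1, 0.12, 1.2e-4, 0.6),
                         corr_length = 10, n_waves = 4L,
                         noise_sd = 10, jitter_sd = 1.5,
                         pblh_meanlog = log(0.9), pblh_sdlog = 0.35,
                         rh_shape = 4, rh_mean = 55,
                         st_meanlog = log(288), st_sdlog = 0.012,
                         ps_mean = 96000, ps_sd = 1200,
                         ps_bimodal = FALSE, ps_low_mean = 80000,
                         ps_low_sd = 800, ps_low_w = 0.25,
                         wind_mean = 1.5, wind_sd = 1.2,
                         precip_p0 = 0.8, precip_mean = 4,
                         aod_meanlog = log(0.45), aod_sdlog = 0.5,
                         bright_fraction = 0.15,
                         dt_noise_sd = 0.01, db_noise_sd = 0.02,
                         qa_probs_dt = c(0.05, 0.10, 0.15, 0.70),
                         qa_probs_db = c(0.05, 0.05, 0.20, 0.70),
                         rh_cap = 95, smooth_waves = 12L,
                         met_corr_length = 3, aod_corr_length = 0.7,
                         noiseless = FALSE) {
  if (corr_length <= 0 || met_corr_length <= 0 || aod_corr_length <= 0) {
    stop("correlation lengths must be positive", call. = FALSE)
  }
  if (bright_fraction < 0 || bright_fraction >= 1) {
    stop("bright_fraction must lie in [0, 1)", call. = FALSE)
  }
  ## parameters that would breach hard physical invariants are rejected
  ## here, at configuration time
  if (rh_mean >= rh_cap) stop("rh_mean must be below rh_cap", call. = FALSE)
  if (rh_cap >= 100) stop("rh_cap must be < 100 (hygroscopic correction ",
                          "diverges at saturation)", call. = FALSE)
  cfg <- as.list(environment())
  if (noiseless) {
    cfg$noise_sd <- 0; cfg$jitter_sd <- 0
    cfg$dt_noise_sd <- 0; cfg$db_noise_sd <- 0
    cfg$bright_fraction <- 0
    cfg$qa_probs_dt <- c(0, 0, 0, 1)
    cfg$qa_probs_db <- c(0, 0, 0, 1)
  }
  cfg$start_date <- as.Date(cfg$start_date)
  cfg$n_stations <- as.integer(cfg$n_stations)
  cfg$n_days <- as.integer(cfg$n_days)
  structure(cfg, class = "scene_config")
}

## evaluate an expression under a private RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed %% .Machine$integer.max)
  eval.parent(substitute(expr))
}

## sinusoid component table: n_waves rows of direction, wavelength (>=
## corr_length), phase and weight (|weights| summing to 1)
.wave_table <- function(n_waves, corr_length) {
  theta <- stats::runif(n_waves, 0, 2 * pi)
  data.frame(
    ux = cos(theta), uy = sin(theta),
    wavelength = corr_length * (1 + stats::rexp(n_waves, rate = 2)),
    phase = stats::runif(n_waves, 0, 2 * pi),
    weight = {
      w <- stats::runif(n_waves, 0.5, 1) * sample(c(-1, 1), n_waves,
                                                  replace = TRUE)
      w / sum(abs(w))
    })
}

## evaluate mean + amp * sum_m w_m sin(2 pi (u.x)/lambda + phase)
.eval_waves <- function(tab, mean, amp, lon, lat) {
  out <- rep(mean, length(lon))
  for (m in seq_len(nrow(tab))) {
    out <- out + amp * tab$weight[m] *
      sin(2 * pi * (tab$ux[m] * lon + tab$uy[m] * lat) /
            tab$wavelength[m] + tab$phase[m])
  }
  out
}

## standardized smooth field ~ N(0,1) marginally (sum of K random plane
## waves, variance 1 by construction)
.smooth_gauss_waves <- function(K, corr_length) {
  theta <- stats::runif(K, 0, 2 * pi)
  data.frame(ux = cos(theta), uy = sin(theta),
             wavelength = corr_length * (1 + stats::rexp(K, rate = 2)),
             phase = stats::runif(K, 0, 2 * pi),
             weight = rep(sqrt(2 / K), K))
}

.fine_grid_spec <- function(sc) {
  h <- sc$fine_cell
  list(origin = c(sc$domain[1] + h / 2, sc$domain[3] + h / 2),
       nlon = ceiling((sc$domain[2] - sc$domain[1]) / h),
       nlat = ceiling((sc$domain[4] - sc$domain[3]) / h), cell = h)
}

.grid_spec <- function(sc, h) {
  ## met/precip grids extend half a cell beyond the domain so every
  ## in-domain point is inside the convex hull of cell centers
  list(origin = c(sc$domain[1] - h / 2, sc$domain[3] - h / 2),
       nlon = ceiling((sc$domain[2] - sc$domain[1]) / h) + 2L,
       nlat = ceiling((sc$domain[4] - sc$domain[3]) / h) + 2L, cell = h)
}

.spec_field <- function(spec, values, var, units, time = NULL) {
  grid_field(matrix(values, spec$nlat, spec$nlon), spec$origin,
             spec$cell, var = var, units = units, time = time)
}

.spec_coords <- function(spec) {
  lon <- spec$origin[1] + (seq_len(spec$nlon) - 1) * spec$cell
  lat <- spec$origin[2] + (seq_len(spec$nlat) - 1) * spec$cell
  ## column-major over (lat, lon), matching matrix filling
  list(lon = rep(lon, each = spec$nlat), lat = rep(lat, spec$nlon),
       nlon = spec$nlon, nlat = spec$nlat)
}

#' Generate the true coefficient surfaces
#'
#' Each of the six coefficient surfaces is its configured mean plus a
#' smooth zero-mean perturbation: a superposition of `n_waves` random
#' plane sinusoids with wavelengths at or above the correlation length
#' and absolute weights summing to one, so the perturbation never
#' exceeds the configured amplitude. Sinusoids (rather than sampled
#' Gaussian processes) make the truth exactly reproducible, evaluable
#' at arbitrary coordinates, and give closed-form smoothness bounds.
#'
#' @param sc a [scene_config()].
#' @param seed integer seed.
#' @return object of class `scene_truth`: list with `surfaces` (six
#'   [grid_field()]s on the fine grid), `waves` (component tables),
#'   `beta_at(lon, lat)` (closure returning the n x 6 truth coefficient
#'   matrix at arbitrary points), `noise_sd`, `seed`, `config`.
#' @export
make_coefficient_surfaces <- function(sc, seed) {
  if (sc$corr_length <= 0) stop("corr_length must be > 0", call. = FALSE)
  waves <- .with_seed(seed + 1L, lapply(1:6, function(j) {
    .wave_table(sc$n_waves, sc$corr_length)
  }))
  spec <- .fine_grid_spec(sc)
  co <- .spec_coords(spec)
  names <- c("beta0", "beta1_aod", "beta2_prec", "beta3_st", "beta4_ps",
             "beta5_ws")
  surfaces <- lapply(1:6, function(j) {
    .spec_field(spec,
                .eval_waves(waves[[j]], sc$beta_mean[j], sc$beta_amp[j],
                            co$lon, co$lat),
                var = names[j], units = "1")
  })
  names(surfaces) <- names
  beta_at <- function(lon, lat) {
    vapply(1:6, function(j) {
      .eval_waves(waves[[j]], sc$beta_mean[j], sc$beta_amp[j], lon, lat)
    }, numeric(length(lon)))
  }
  structure(list(surfaces = surfaces, waves = waves, beta_at = beta_at,
                 noise_sd = sc$noise_sd, seed = seed, config = sc),
            class = "scene_truth")
}

#' Generate an unevenly clustered station network
#'
#' With probability `clustering` a station is placed around one of
#' `n_clusters` urban cluster centers (normal spread `cluster_sd`,
#' rejected back into the domain); otherwise uniformly. `clustering = 0`
#' reproduces a spatially uniform network; higher values emulate the
#' dense-urban / sparse-hinterland coverage of real monitoring
#' networks.
#'
#' @param sc a [scene_config()].
#' @param seed integer seed.
#' @return data.frame with `station_id`, `lon`, `lat`.
#' @export
make_station_network <- function(sc, seed) {
  n <- sc$n_stations
  if (n < 1) stop("n_stations must be >= 1", call. = FALSE)
  dens_ceiling <- 250 * (sc$domain[2] - sc$domain[1]) *
    (sc$domain[4] - sc$domain[3])
  if (n > dens_ceiling) {
    stop("station count exceeds the density ceiling of ", dens_ceiling,
         " for this domain", call. = FALSE)
  }
  .with_seed(seed + 2L, {
    centers <- cbind(stats::runif(sc$n_clusters, sc$domain[1], sc$domain[2]),
                     stats::runif(sc$n_clusters, sc$domain[3], sc$domain[4]))
    clustered <- stats::runif(n) < sc$clustering
    lon <- stats::runif(n, sc$domain[1], sc$domain[2])
    lat <- stats::runif(n, sc$domain[3], sc$domain[4])
    idx <- which(clustered)
    if (length(idx)) {
      ci <- sample.int(sc$n_clusters, length(idx), replace = TRUE)
      plon <- stats::rnorm(length(idx), centers[ci, 1], sc$cluster_sd)
      plat <- stats::rnorm(length(idx), centers[ci, 2], sc$cluster_sd)
      for (r in 1:100) {           # resample out-of-domain draws
        bad <- plon < sc$domain[1] | plon > sc$domain[2] |
          plat < sc$domain[3] | plat > sc$domain[4]
        if (!any(bad)) break
        plon[bad] <- stats::rnorm(sum(bad), centers[ci[bad], 1],
                                  sc$cluster_sd)
        plat[bad] <- stats::rnorm(sum(bad), centers[ci[bad], 2],
                                  sc$cluster_sd)
      }
      bad <- plon < sc$domain[1] | plon > sc$domain[2] |
        plat < sc$domain[3] | plat > sc$domain[4]
      plon[bad] <- stats::runif(sum(bad), sc$domain[1], sc$domain[2])
      plat[bad] <- stats::runif(sum(bad), sc$domain[3], sc$domain[4])
      lon[idx] <- plon
      lat[idx] <- plat
    }
    data.frame(station_id = sprintf("S%04d", seq_len(n)), lon = lon,
               lat = lat, stringsAsFactors = FALSE)
  })
}

## inverse CDF of the (optionally bimodal) pressure marginal
.ps_quantile <- function(p, sc) {
  if (!sc$ps_bimodal) return(stats::qnorm(p, sc$ps_mean, sc$ps_sd))
  ## numeric inversion of the two-component normal mixture CDF
  grid <- seq(sc$ps_low_mean - 5 * sc$ps_low_sd,
              sc$ps_mean + 5 * sc$ps_sd, length.out = 2048)
  cdf <- sc$ps_low_w * stats::pnorm(grid, sc$ps_low_mean, sc$ps_low_sd) +
    (1 - sc$ps_low_w) * stats::pnorm(grid, sc$ps_mean, sc$ps_sd)
  stats::approx(cdf, grid, xout = p, rule = 2, ties = "ordered")$y
}

#' Generate one day's meteorological and latent extinction fields
#'
#' Each variable is a smooth standard-normal field (superposed random
#' plane waves) pushed through the quantile function of its configured
#' marginal family: log-normal PBLH (km) and surface temperature (K),
#' Weibull surface RH (percent, capped at `rh_cap`), normal or bimodal
#' mixture pressure (Pa), normal wind components (m/s), zero-inflated
#' exponential daily precipitation (mm), and a log-normal latent
#' near-surface extinction proxy (`rev_aod`, 1/km) on the fine grid
#' from which the AOD granules are built.
#'
#' @param sc a [scene_config()].
#' @param day_index 1-based day number.
#' @param seed integer seed.
#' @return named list of [grid_field()]s: `pblh, rh, st, ps, u, v` on
#'   the meteorology grid, `precip` on the precipitation grid,
#'   `rev_aod` on the fine grid.
#' @export
make_meteorology <- function(sc, day_index, seed) {
  day <- sc$start_date + (day_index - 1L)
  met <- .grid_spec(sc, sc$met_cell)
  pre <- .grid_spec(sc, sc$precip_cell)
  fine <- .fine_grid_spec(sc)
  zfield <- function(spec, sub, corr_length = sc$met_corr_length) {
    tab <- .with_seed(seed + 1000L * day_index + sub,
                      .smooth_gauss_waves(sc$smooth_waves, corr_length))
    co <- .spec_coords(spec)
    .eval_waves(tab, 0, 1, co$lon, co$lat)
  }
  rh_scale <- sc$rh_mean / gamma(1 + 1 / sc$rh_shape)
  pblh <- exp(sc$pblh_meanlog + sc$pblh_sdlog * zfield(met, 1L))
  rh <- pmin(stats::qweibull(stats::pnorm(zfield(met, 2L)), sc$rh_shape,
                             rh_scale), sc$rh_cap)
  st <- exp(sc$st_meanlog + sc$st_sdlog * zfield(met, 3L))
  ps <- .ps_quantile(stats::pnorm(zfield(met, 4L)), sc)
  u <- sc$wind_mean + sc$wind_sd * zfield(met, 5L)
  v <- sc$wind_mean + sc$wind_sd * zfield(met, 6L)
  pz <- stats::pnorm(zfield(pre, 7L))
  precip <- numeric(length(pz))
  wet <- pz >= sc$precip_p0
  precip[wet] <- stats::qexp((pz[wet] - sc$precip_p0) /
                               (1 - sc$precip_p0),
                             rate = 1 / sc$precip_mean)
  rev_aod <- exp(sc$aod_meanlog +
                   sc$aod_sdlog * zfield(fine, 8L, sc$aod_corr_length))
  list(pblh = .spec_field(met, pblh, "pblh", "km", day),
       rh = .spec_field(met, rh, "rh", "%", day),
       st = .spec_field(met, st, "st", "K", day),
       ps = .spec_field(met, ps, "ps", "Pa", day),
       u = .spec_field(met, u, "u", "m/s", day),
       v = .spec_field(met, v, "v", "m/s", day),
       precip = .spec_field(pre, precip, "precip", "mm", day),
       rev_aod = .spec_field(fine, rev_aod, "rev_aod", "1/km", day))
}

#' Column AOD on the fine grid
#'
#' The satellite observes column AOD; the generator works from a latent
#' near-surface extinction proxy (`rev_aod`, 1/km). The column value of
#' a fine cell is its latent value times the boundary-layer height
#' bilinearly interpolated at the cell center — exactly the quantity
#' the vertical correction later divides out.
#'
#' @param rev_aod latent extinction [grid_field()] on the fine grid.
#' @param pblh boundary-layer height [grid_field()] (km).
#' @return column-AOD [grid_field()] on the fine grid.
#' @export
column_aod_field <- function(rev_aod, pblh) {
  co <- grid_coords(rev_aod)
  d <- dim(rev_aod$values)
  lon <- rep(co$lon, each = d[1])
  lat <- rep(co$lat, times = d[2])
  p <- bilinear_at(pblh, lon, lat)
  grid_field(matrix(rev_aod$values * p, d[1], d[2]),
             rev_aod$origin, rev_aod$cell, var = "aod550", units = "1",
             time = rev_aod$time)
}

#' Generate station records and truth model rows for one day
#'
#' Inverts the estimation model: the revised (humidity-corrected) PM2.5
#' at each station is the local linear combination of the regressors
#' under the true coefficient surfaces, plus Gaussian noise on the
#' revised scale; the recorded dry PM2.5 is deflated by
#' `(1 - RH/100)`. Two hourly records per station are written at 13:00
#' and 14:00 *local* time (stamped in Beijing time per the station's
#' zone band), each jittered around the daily value. Regressors are
#' collocated exactly as the pipeline will read them back: AOD from the
#' containing fine pixel divided by bilinear PBLH, meteorology
#' bilinear, wind speed as `sqrt(u^2 + v^2)`, previous-day
#' precipitation bilinear from the day-1 grid.
#'
#' @param truth a `scene_truth` ([make_coefficient_surfaces()]).
#' @param fields one day's fields ([make_meteorology()]).
#' @param prev_precip the previous day's precipitation [grid_field()].
#' @param stations data.frame from [make_station_network()].
#' @param day_index 1-based day number.
#' @param seed integer seed.
#' @return list with `records` (station-record data.frame, two rows per
#'   station) and `truth_rows` (model rows carrying the noiseless
#'   `revised_pm25_true`, the realised `revised_pm25`, and all
#'   regressors).
#' @export
make_observations <- function(truth, fields, prev_precip, stations,
                              day_index, seed) {
  sc <- truth$config
  day <- sc$start_date + (day_index - 1L)
  n <- nrow(stations)
  inside <- stations$lon >= sc$domain[1] & stations$lon <= sc$domain[2] &
    stations$lat >= sc$domain[3] & stations$lat <= sc$domain[4]
  if (!all(inside)) {
    stop("station(s) outside the scene domain: ",
         paste(stations$station_id[!inside], collapse = ", "),
         call. = FALSE)
  }
  pblh <- bilinear_at(fields$pblh, stations$lon, stations$lat)
  rh <- bilinear_at(fields$rh, stations$lon, stations$lat)
  st <- bilinear_at(fields$st, stations$lon, stations$lat)
  ps <- bilinear_at(fields$ps, stations$lon, stations$lat)
  u <- bilinear_at(fields$u, stations$lon, stations$lat)
  v <- bilinear_at(fields$v, stations$lon, stations$lat)
  lp <- bilinear_at(prev_precip, stations$lon, stations$lat)
  if (any(!is.finite(c(pblh, rh, st, ps, u, v, lp)))) {
    stop("station outside a field domain", call. = FALSE)
  }
  aod_col <- column_aod_field(fields$rev_aod, fields$pblh)
  raod <- pixel_at(aod_col, stations$lon, stations$lat) / pblh
  ws <- sqrt(u^2 + v^2)
  beta <- truth$beta_at(stations$lon, stations$lat)
  rev_true <- beta[, 1] + beta[, 2] * raod + beta[, 3] * lp +
    beta[, 4] * st + beta[, 5] * ps + beta[, 6] * ws

  draws <- .with_seed(seed + 5000L + 13L * day_index, {
    list(noise = stats::rnorm(n, 0, sc$noise_sd),
         jitter = matrix(stats::rnorm(2L * n, 0, sc$jitter_sd), n, 2))
  })
  rev_real <- rev_true + draws$noise
  dry_daily <- rev_real * (1 - rh / 100)
  offset <- zone_offset(stations$lon)
  h13 <- 13L + (8L - offset)
  pm_h <- matrix(pmax(0, dry_daily + draws$jitter), n, 2)

  records <- data.frame(
    station_id = rep(stations$station_id, 2),
    lon = rep(stations$lon, 2), lat = rep(stations$lat, 2),
    date = day, hour_beijing = c(h13, h13 + 1L),
    pm25 = c(pm_h[, 1], pm_h[, 2]), stringsAsFactors = FALSE)
  truth_rows <- data.frame(
    station_id = stations$station_id, lon = stations$lon,
    lat = stations$lat, day = day, revised_aod = raod, last_prec = lp,
    st = st, ps = ps, ws = ws, rh = rh, pblh = pblh,
    revised_pm25_true = rev_true, revised_pm25 = rev_real,
    pm25 = dry_daily, stringsAsFactors = FALSE)
  list(records = records, truth_rows = truth_rows)
}

#' Generate the paired DT / DB AOD granules for one day
#'
#' The Dark Target granule carries the fine-grid column AOD plus
#' retrieval noise, with values removed over the bright-surface mask
#' (iid Bernoulli cells, emulating retrieval failure over bright
#' ground). The Deep Blue granule is the block average of the fine
#' column AOD onto the coarse grid (cells whose centers it contains)
#' plus its own retrieval noise, covering bright cells. QA flags are
#' drawn iid from the configured distributions.
#'
#' @param fields one day's fields ([make_meteorology()]).
#' @param sc a [scene_config()].
#' @param day_index 1-based day number.
#' @param seed integer seed.
#' @return list with `dt` and `db` [aod_granule()]s and `bright` (the
#'   logical bright-surface mask on the fine grid).
#' @export
make_aod_granules <- function(fields, sc, day_index, seed) {
  if (sc$bright_fraction >= 1) {
    stop("bright_fraction must be < 1", call. = FALSE)
  }
  aod_col <- column_aod_field(fields$rev_aod, fields$pblh)
  dfine <- dim(aod_col$values)
  ncell <- prod(dfine)
  coarse <- .grid_spec(sc, sc$coarse_cell)

  .with_seed(seed + 9000L + 11L * day_index, {
    bright <- matrix(stats::runif(ncell) < sc$bright_fraction,
                     dfine[1], dfine[2])
    dt_vals <- aod_col$values +
      if (sc$dt_noise_sd > 0) stats::rnorm(ncell, 0, sc$dt_noise_sd) else 0
    dt_vals <- pmax(dt_vals, 0)
    dt_vals[bright] <- NA_real_
    qa_dt <- matrix(sample(0:3, ncell, replace = TRUE,
                           prob = sc$qa_probs_dt), dfine[1], dfine[2])
    dt <- aod_granule(
      grid_field(dt_vals, aod_col$origin, aod_col$cell, var = "aod550",
                 units = "1", time = aod_col$time),
      qa_dt, "DT", 3)

    ## block average: mean of fine cells whose centers fall in each
    ## coarse cell
    co <- grid_coords(aod_col)
    jj <- .axis_index(co$lon, coarse$origin[1], coarse$cell, coarse$nlon)
    ii <- .axis_index(co$lat, coarse$origin[2], coarse$cell, coarse$nlat)
    cellid <- (rep(jj, each = dfine[1]) - 1L) * coarse$nlat +
      rep(ii, times = dfine[2])
    sums <- tapply(as.vector(aod_col$values), cellid, mean)
    db_vals <- matrix(NA_real_, coarse$nlat, coarse$nlon)
    db_vals[as.integer(names(sums))] <- as.numeric(sums)
    nco <- sum(!is.na(db_vals))
    db_vals[!is.na(db_vals)] <- pmax(
      db_vals[!is.na(db_vals)] +
        if (sc$db_noise_sd > 0) stats::rnorm(nco, 0, sc$db_noise_sd) else 0,
      0)
    qa_db <- matrix(sample(0:3, coarse$nlat * coarse$nlon, replace = TRUE,
                           prob = sc$qa_probs_db),
                    coarse$nlat, coarse$nlon)
    qa_db[is.na(db_vals)] <- NA_integer_
    db <- aod_granule(
      grid_field(db_vals, coarse$origin, coarse$cell, var = "aod550",
                 units = "1", time = aod_col$time),
      qa_db, "DB", 10)
    list(dt = dt, db = db, bright = bright)
  })
}

#' Generate a complete synthetic scene
#'
#' Orchestrates the full generator: coefficient surfaces, station
#' network, per-day meteorology, observations and granules, plus a
#' spin-up precipitation grid for the day before the first estimation
#' day. Bit-for-bit reproducible from `(sc, seed)`.
#'
#' @param sc a [scene_config()].
#' @param seed master seed.
#' @return object of class `pm25_scene`: list with `truth`, `stations`,
#'   `records` (all days), `truth_rows` (all days), `met` (per-day field
#'   lists), `granules` (per-day DT/DB), `precip_stack` (named by date,
#'   includes day 0), `config`, `seed`, `days`.
#' @export
simulate_scene <- function(sc = scene_config(), seed = 1L) {
  truth <- make_coefficient_surfaces(sc, seed)
  stations <- make_station_network(sc, seed)
  days <- sc$start_date + seq_len(sc$n_days) - 1L
  ## day-0 precipitation so day 1 has a previous-day grid
  met0 <- make_meteorology(sc, 0L, seed)
  precip_stack <- stats::setNames(list(met0$precip),
                                  format(sc$start_date - 1L))
  met <- vector("list", sc$n_days)
  granules <- vector("list", sc$n_days)
  records <- vector("list", sc$n_days)
  truth_rows <- vector("list", sc$n_days)
  for (d in seq_len(sc$n_days)) {
    met[[d]] <- make_meteorology(sc, d, seed)
    precip_stack[[format(days[d])]] <- met[[d]]$precip
    obs <- make_observations(truth, met[[d]],
                             precip_stack[[format(days[d] - 1L)]],
                             stations, d, seed)
    records[[d]] <- obs$records
    truth_rows[[d]] <- obs$truth_rows
    granules[[d]] <- make_aod_granules(met[[d]], sc, d, seed)
  }
  structure(
    list(truth = truth, stations = stations,
         records = do.call(rbind, records),
         truth_rows = do.call(rbind, truth_rows),
         met = met, granules = granules, precip_stack = precip_stack,
         config = sc, seed = seed, days = days),
    class = "pm25_scene")
}

#' @export
print.pm25_scene <- function(x, ...) {
  cat(sprintf(
    "<pm25_scene> %d stations, %d days from %s, seed %d\n",
    nrow(x$stations), length(x$days), format(x$days[1]), x$seed))
  invisible(x)
}
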