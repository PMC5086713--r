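#' Great-circle distance
#'
#' Haversine distance on a sphere of radius 6371 km. The study domain
#' spans tens of degrees of latitude, so Euclidean distance in degrees
#' would distort the kernel; all GWR weighting uses great-circle km.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees (vectorised).
#' @return distance(s) in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  r <- pi / 180
  dlat <- (lat2 - lat1) * r / 2
  dlon <- (lon2 - lon1) * r / 2
  a <- sin(dlat)^2 + cos(lat1 * r) * cos(lat2 * r) * sin(dlon)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

## n_from x n_to great-circle distance matrix (km)
.dist_km <- function(from, to) {
  outer(seq_len(nrow(from)), seq_len(nrow(to)), function(i, j) {
    haversine_km(from$lon[i], from$lat[i], to$lon[j], to$lat[j])
  })
}

#' Kernel weights
#'
#' Distance-decay weight of an observation at distance `d_km` from the
#' calibration location, for bandwidth `bandwidth_km`. The default
#' bisquare kernel `(1 - (d/b)^2)^2` has compact support — observations
#' at or beyond the bandwidth contribute exactly zero — which suits an
#' adaptively chosen neighbour count on an unevenly dense station
#' network. A Gaussian kernel `exp(-(d/b)^2 / 2)` and a uniform kernel
#' (all weights 1, the global-regression limit) are also available.
#'
#' @param d_km distance(s) in km.
#' @param bandwidth_km kernel bandwidth in km, `> 0`.
#' @return weight(s) in `[0, 1]`.
#' @export
bisquare_weight <- function(d_km, bandwidth_km) {
  if (any(bandwidth_km <= 0)) stop("bandwidth must be > 0", call. = FALSE)
  ifelse(d_km < bandwidth_km, (1 - (d_km / bandwidth_km)^2)^2, 0)
}

.kernel_weight <- function(d_km, bandwidth_km, kernel) {
  switch(kernel,
         bisquare = bisquare_weight(d_km, bandwidth_km),
         gaussian = exp(-0.5 * (d_km / bandwidth_km)^2),
         uniform = rep(1, length(d_km)),
         stop("unknown kernel: ", kernel, call. = FALSE))
}

#' Adaptive bandwidth: distance to the k-th nearest calibration point
#'
#' With an adaptive bandwidth the kernel radius shrinks where stations
#' are dense and grows where they are sparse: at each calibration
#' location the bandwidth is the distance to its k-th nearest
#' calibration point. Under the bisquare kernel the k-th point itself
#' (and any ties with it) receives weight exactly zero.
#'
#' @param distances_km distances from the target location to every
#'   calibration point, km.
#' @param k neighbour count, `min_k <= k <= length(distances_km)`.
#' @param min_k smallest admissible k; when the bandwidth feeds a local
#'   fit this is the six regressors + 2, so the fit stays
#'   overdetermined even though the k-th point itself gets bisquare
#'   weight zero.
#' @return bandwidth in km.
#' @export
adaptive_bandwidth_km <- function(distances_km, k, min_k = 8L) {
  n <- length(distances_km)
  if (k > n) stop("k exceeds the number of calibration points",
                  call. = FALSE)
  if (k < min_k) {
    stop("k below regressors + 2: local fit under-determined",
         call. = FALSE)
  }
  sort(distances_km, partial = k)[k]
}

## Design matrix and response of the local linear model:
## revised_pm25 ~ revised_aod + last_prec + st + ps + ws (+ intercept)
.gwr_terms <- c("revised_aod", "last_prec", "st", "ps", "ws")

.design <- function(rows) {
  X <- cbind(1, rows$revised_aod, rows$last_prec, rows$st, rows$ps,
             rows$ws)
  colnames(X) <- c("intercept", .gwr_terms)
  X
}

#' Locally weighted least squares at one location
#'
#' Solves `min_beta sum_i w_i (y_i - x_i' beta)^2` by weighted QR and
#' reports the local coefficient vector and the local weighted R-squared
#' `1 - sum(w e^2) / sum(w (y - ybar_w)^2)` (with `ybar_w` the weighted
#' mean of the response).
#'
#' @param rows model rows (see [build_model_rows()]).
#' @param weights non-negative observation weights.
#' @param where optional label used in error messages.
#' @return list with `coef` (named length-6 vector) and `r2`.
#' @export
local_wls <- function(rows, weights, where = "target location") {
  pos <- weights > 0
  if (sum(pos) < 7) {
    stop("fewer than 7 positively weighted rows at ", where,
         call. = FALSE)
  }
  X <- .design(rows[pos, , drop = FALSE])
  y <- rows$revised_pm25[pos]
  ## a regressor that is constant across the local support carries no
  ## local information (typically an all-dry precipitation
  ## neighbourhood): drop it and report slope 0; the constant is
  ## absorbed by the intercept. True rank deficiency among varying
  ## columns (e.g. duplicated regressors) remains a hard error.
  varying <- c(TRUE, apply(X[, -1, drop = FALSE], 2,
                           function(x) any(x != x[1])))
  sw <- sqrt(weights[pos])
  fit <- .lm.fit(X[, varying, drop = FALSE] * sw, y * sw)
  if (fit$rank < sum(varying)) {
    stop("singular local fit at ", where,
         ": weighted design matrix is rank deficient", call. = FALSE)
  }
  beta <- numeric(ncol(X))
  names(beta) <- colnames(X)
  beta[varying] <- fit$coefficients
  ## leverage of an arbitrary design point: x' (X'WX)^-1 x computed from
  ## the QR factor (X'WX = R'R up to the pivot permutation); the
  ## prediction guard in predict_gwr() uses it
  p <- sum(varying)
  R <- fit$qr[seq_len(p), seq_len(p), drop = FALSE]
  R[lower.tri(R)] <- 0
  pivot <- fit$pivot
  leverage_at <- function(x_full) {
    xv <- x_full[varying][pivot]
    sum(backsolve(R, xv, transpose = TRUE)^2)
  }
  res <- y - drop(X %*% beta)
  w <- weights[pos]
  ybar <- sum(w * y) / sum(w)
  tss <- sum(w * (y - ybar)^2)
  r2 <- if (tss > 0) 1 - sum(w * res^2) / tss else NA_real_
  list(coef = beta, r2 = r2, leverage_at = leverage_at)
}

## One local calibration: weights at `target` (row of lon/lat) given the
## precomputed distance vector, then WLS.
.calibrate <- function(rows, dists, k, config, where) {
  b <- if (config$kernel == "uniform") Inf
       else adaptive_bandwidth_km(dists, k)
  w <- .kernel_weight(dists, b, config$kernel)
  c(local_wls(rows, w, where = where), list(bandwidth_km = b))
}

#' Leave-one-out CV score of a neighbour count
#'
#' For each calibration row the local model is refitted at that row's
#' location with the row removed, and the squared prediction error
#' accumulated. Used as the bandwidth-selection criterion.
#'
#' @param rows model rows for one day.
#' @param k candidate neighbour count.
#' @param config a [run_config()].
#' @param D optional precomputed distance matrix.
#' @return the LOO residual sum of squares (revised scale); `Inf` if any
#'   local fit fails.
#' @export
loocv_score <- function(rows, k, config = run_config(), D = NULL) {
  n <- nrow(rows)
  if (is.null(D)) D <- .dist_km(rows, rows)
  X <- .design(rows)
  score <- 0
  for (i in seq_len(n)) {
    di <- D[i, -i]
    sub <- rows[-i, , drop = FALSE]
    fit <- tryCatch(
      .calibrate(sub, di, min(k, n - 1L), config,
                 where = sprintf("row %d (LOO)", i)),
      error = function(e) NULL)
    if (is.null(fit)) return(Inf)
    score <- score + (rows$revised_pm25[i] - sum(X[i, ] * fit$coef))^2
  }
  score
}

#' Select the adaptive neighbour count by leave-one-out CV
#'
#' Minimises the LOO residual sum of squares over integer neighbour
#' counts. The search is golden-section on integers (assuming a
#' unimodal score), falling back to exhaustive evaluation once the
#' bracket is narrower than 10; ranges narrower than 10 are searched
#' exhaustively from the start. Ties are broken toward the smallest k
#' (favouring locality).
#'
#' @param rows model rows for one day.
#' @param config a [run_config()]; `config$k_range` bounds the search.
#' @param D optional precomputed distance matrix.
#' @param exhaustive force full evaluation of every candidate (used as a
#'   brute-force cross-check).
#' @return list with `k` (selected count) and `score` (its LOO RSS).
#' @export
select_bandwidth <- function(rows, config = run_config(), D = NULL,
                             exhaustive = FALSE) {
  n <- nrow(rows)
  lo <- config$k_range[1]
  hi <- min(config$k_range[2], n - 1L)
  if (hi < lo) stop("k_range infeasible for ", n, " rows", call. = FALSE)
  if (is.null(D)) D <- .dist_km(rows, rows)
  memo <- new.env(parent = emptyenv())
  sc <- function(k) {
    key <- as.character(k)
    if (is.null(memo[[key]])) memo[[key]] <- loocv_score(rows, k, config, D)
    memo[[key]]
  }
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  if (!exhaustive) {
    while (b - a >= 10) {
      x1 <- as.integer(round(b - phi * (b - a)))
      x2 <- as.integer(round(a + phi * (b - a)))
      if (x1 >= x2) break
      if (sc(x1) <= sc(x2)) b <- x2 else a <- x1
    }
  }
  ks <- seq.int(a, b)
  scores <- vapply(ks, sc, numeric(1))
  if (all(!is.finite(scores))) {
    stop("all candidate bandwidths give singular fits", call. = FALSE)
  }
  best <- ks[which.min(scores)]          # which.min takes the smallest k
  list(k = as.integer(best), score = min(scores))
}

#' Fit a geographically weighted regression for one day
#'
#' Calibrates the local linear model
#' `revised_pm25 = b0 + b1 revised_aod + b2 last_prec + b3 st + b4 ps +
#' b5 ws` at every station location of one estimation day, with
#' distance-decay weights under the configured kernel and an adaptive
#' bandwidth (distance to the k-th nearest station). Coefficients are
#' location-specific: each row of `coef` is the model at that station.
#'
#' @param rows model rows for one day ([build_model_rows()]).
#' @param config a [run_config()].
#' @param k neighbour count; `NULL` selects it by [select_bandwidth()]
#'   (or uses `config$fixed_k` when `bandwidth_mode = "fixed"`).
#' @return object of class `gwr_fit`: list with `locations` (data.frame
#'   `station_id, lon, lat`), `coef` (n x 6 matrix), `local_r2`,
#'   `bandwidth_km` (per-location), `k`, `kernel`, `day`, `n`.
#' @export
fit_gwr <- function(rows, config = run_config(), k = NULL) {
  n <- nrow(rows)
  if (n < config$min_rows) {
    stop(sprintf("only %d rows; %d required for a daily GWR fit", n,
                 config$min_rows), call. = FALSE)
  }
  D <- .dist_km(rows, rows)
  if (is.null(k)) {
    k <- if (config$bandwidth_mode == "fixed") config$fixed_k
         else select_bandwidth(rows, config, D)$k
  }
  k <- min(as.integer(k), n)
  coef <- matrix(NA_real_, n, 6,
                 dimnames = list(NULL, c("intercept", .gwr_terms)))
  r2 <- bw <- rep(NA_real_, n)
  fails <- character(0)
  for (i in seq_len(n)) {
    where <- sprintf("station %s (%.3f E, %.3f N)", rows$station_id[i],
                     rows$lon[i], rows$lat[i])
    fit <- tryCatch(.calibrate(rows, D[i, ], k, config, where),
                    error = function(e) e)
    if (inherits(fit, "error")) { fails <- c(fails, where); next }
    coef[i, ] <- fit$coef
    r2[i] <- fit$r2
    bw[i] <- fit$bandwidth_km
  }
  if (length(fails)) {
    stop("singular local fit(s) at: ", paste(fails, collapse = "; "),
         call. = FALSE)
  }
  structure(
    list(locations = rows[, c("station_id", "lon", "lat")],
         coef = coef, local_r2 = r2, bandwidth_km = bw, k = k,
         kernel = config$kernel, day = rows$day[1], n = n),
    class = "gwr_fit")
}

#' @export
print.gwr_fit <- function(x, ...) {
  cat(sprintf("<gwr_fit> %s: %d locations, kernel %s, adaptive k = %d\n",
              format(x$day), x$n, x$kernel, x$k))
  cat(sprintf("  median local R2 %.3f; median bandwidth %.1f km\n",
              stats::median(x$local_r2), stats::median(x$bandwidth_km)))
  invisible(x)
}

#' Predict revised PM2.5 at arbitrary points
#'
#' At each target point a local model is calibrated from the day's
#' station rows (weights centred on the point, adaptive bandwidth) and
#' evaluated with the point's own regressors. Output is on the revised
#' (humidity-inflated) scale; convert with [dry_pm25()] using the
#' point's RH. Points with any missing regressor, or whose local fit is
#' singular, yield `NA` (no fallback fitting by default).
#'
#' Predictions are also guarded against design-space extrapolation: if
#' the target's leverage `x' (X'WX)^-1 x` exceeds
#' `config$max_leverage` (default 1, i.e. the local prediction would be
#' no more precise than a single raw observation — typically a target
#' whose regressor values lie far outside their local range, such as a
#' wet station in an all-dry neighbourhood), the prediction is
#' unreliable and returned as `NA`. The count of guarded points is
#' attached as attribute `n_unreliable`.
#'
#' @param rows calibration model rows for one day.
#' @param points data.frame with `lon`, `lat` and regressor columns
#'   `revised_aod, last_prec, st, ps, ws`.
#' @param config a [run_config()].
#' @param k neighbour count; `NULL` as in [fit_gwr()].
#' @return numeric vector of predictions (revised scale), `NA` where
#'   undefined.
#' @export
predict_gwr <- function(rows, points, config = run_config(), k = NULL) {
  if (is.null(k)) {
    k <- if (config$bandwidth_mode == "fixed") config$fixed_k
         else select_bandwidth(rows, config)$k
  }
  k <- min(as.integer(k), nrow(rows))
  D <- .dist_km(points, rows)
  Xp <- .design(points)
  out <- rep(NA_real_, nrow(points))
  n_unreliable <- 0L
  for (i in seq_len(nrow(points))) {
    if (any(!is.finite(Xp[i, ]))) next
    fit <- tryCatch(
      .calibrate(rows, D[i, ], k, config,
                 where = sprintf("point (%.3f, %.3f)", points$lon[i],
                                 points$lat[i])),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$leverage_at(Xp[i, ]) > config$max_leverage) {
      n_unreliable <- n_unreliable + 1L
      next
    }
    out[i] <- sum(Xp[i, ] * fit$coef)
  }
  attr(out, "n_unreliable") <- n_unreliable
  out
}
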