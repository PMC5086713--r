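#' Meteorological season of a date
#'
#' Seasons follow the conjunctive astronomical/climatic convention:
#' spring = March-May, summer = June-August, autumn =
#' September-November, winter = December-February.
#'
#' @param date a `Date` (vectorised).
#' @return character vector in
#'   `c("spring", "summer", "autumn", "winter")`.
#' @export
season_of <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  c("winter", "winter", "spring", "spring", "spring", "summer", "summer",
    "summer", "autumn", "autumn", "autumn", "winter")[m]
}

#' Random k-fold partition
#'
#' Assigns each of `n` rows to one of `k` folds uniformly at random;
#' fold sizes differ by at most one and the labelling is reproducible
#' from the seed (drawn from an isolated RNG state, so callers' RNG is
#' untouched).
#'
#' @param n row count, `>= k`.
#' @param k fold count, `>= 2`.
#' @param seed integer seed.
#' @return integer vector of fold labels `1..k`, length `n`.
#' @export
make_folds <- function(n, k, seed) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (n < k) stop("fewer rows than folds", call. = FALSE)
  labels <- rep_len(seq_len(k), n)
  perm <- local({
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    sample.int(n)
  })
  labels[order(perm)]
}

#' Agreement metrics between measured and estimated PM2.5
#'
#' R-squared is the squared Pearson correlation (the convention matching
#' a scatter-plot regression line of estimated against measured);
#' `r2_ss`, the sum-of-squares definition `1 - RSS/TSS`, is reported as
#' a secondary column since the two differ when the fit is biased.
#' The slope and intercept come from the ordinary least-squares line
#' `estimated = slope * measured + intercept`.
#'
#' @param measured,estimated numeric vectors of equal length `>= 3`;
#'   `measured` must have positive variance.
#' @return named list: `n, r2, r2_ss, rmse, mae, slope, intercept`.
#' @export
pm25_metrics <- function(measured, estimated) {
  if (length(measured) != length(estimated)) {
    stop("length mismatch", call. = FALSE)
  }
  ok <- is.finite(measured) & is.finite(estimated)
  x <- measured[ok]; y <- estimated[ok]
  if (length(x) < 3) stop("need at least 3 finite pairs", call. = FALSE)
  if (stats::var(x) == 0) {
    stop("measured values have zero variance", call. = FALSE)
  }
  e <- y - x
  fit <- stats::lm.fit(cbind(1, x), y)$coefficients
  list(n = length(x),
       r2 = stats::cor(x, y)^2,
       r2_ss = 1 - sum(e^2) / sum((x - mean(x))^2),
       rmse = sqrt(mean(e^2)),
       mae = mean(abs(e)),
       slope = unname(fit[2]),
       intercept = unname(fit[1]))
}

#' Seasonal k-fold cross-validation of the daily GWR models
#'
#' Rows are partitioned into `config$folds` random folds within each
#' season (record-level folding). For every fold, each day's GWR is
#' refitted on that day's rows from the other folds and the held-out
#' rows are predicted at their own locations; predictions are
#' back-transformed to the dry (measured) scale with [dry_pm25()] and
#' pooled per season, where the agreement metrics are computed against
#' the measured PM2.5. Every row is validated exactly once.
#'
#' One adaptive neighbour count is selected per season by LOO CV on a
#' small sample of days (`config$bw_sample_days`, median of the per-day
#' selections) and held fixed across folds, mirroring the usual
#' single-bandwidth GWR practice while keeping the day-wise model.
#'
#' Days whose training set falls below `config$min_rows` after fold
#' masking are skipped and their held-out rows counted in `n_skipped`;
#' held-out rows whose prediction trips the extrapolation guard of
#' [predict_gwr()] are counted in `n_unreliable` and excluded from the
#' pooled metrics.
#'
#' @param rows model rows spanning one or more seasons (must carry a
#'   `day` column).
#' @param config a [run_config()].
#' @param seed fold-assignment seed; defaults to `config$seed`.
#' @return object of class `cv_report`: data.frame with one row per
#'   season (`season, n, r2, r2_ss, rmse, mae, slope, intercept`), with
#'   attributes `fold_seed`, `n_skipped`, `k_by_season` and `folds`
#'   (the per-row fold labels, ordered as `rows`).
#' @export
crossval <- function(rows, config = run_config(), seed = config$seed) {
  rows$season <- season_of(rows$day)
  seasons <- unique(rows$season)
  fold_lab <- integer(nrow(rows))
  for (s in seasons) {
    idx <- which(rows$season == s)
    fold_lab[idx] <- make_folds(length(idx), config$folds,
                                seed + match(s, seasons))
  }
  pred_dry <- rep(NA_real_, nrow(rows))
  n_skipped <- 0L
  n_unreliable <- 0L
  k_by_season <- integer(0)

  for (s in seasons) {
    sidx <- which(rows$season == s)
    days <- sort(unique(rows$day[sidx]))
    ## one neighbour count per season, from a spread of sampled days
    sample_days <- days[unique(round(seq(1, length(days),
                                         length.out = min(config$bw_sample_days,
                                                          length(days)))))]
    ks <- vapply(sample_days, function(d) {
      dr <- rows[rows$day == d & rows$season == s, , drop = FALSE]
      if (nrow(dr) <= config$k_range[1]) return(NA_integer_)
      select_bandwidth(dr, config)$k
    }, integer(1))
    k_season <- if (config$bandwidth_mode == "fixed") config$fixed_k
                else as.integer(round(stats::median(ks, na.rm = TRUE)))
    k_by_season[s] <- k_season

    for (f in seq_len(config$folds)) {
      for (d in days) {
        didx <- which(rows$day == d & rows$season == s)
        test <- didx[fold_lab[didx] == f]
        if (!length(test)) next
        train <- didx[fold_lab[didx] != f]
        if (length(train) < config$min_rows) {
          n_skipped <- n_skipped + length(test)
          next
        }
        p <- predict_gwr(rows[train, , drop = FALSE],
                         rows[test, , drop = FALSE], config, k = k_season)
        n_unreliable <- n_unreliable + attr(p, "n_unreliable")
        pred_dry[test] <- dry_pm25(as.numeric(p), rows$rh[test],
                                   config$rh_cap)
      }
    }
  }

  per_season <- lapply(sort(seasons), function(s) {
    idx <- which(rows$season == s & is.finite(pred_dry))
    m <- pm25_metrics(rows$pm25[idx], pred_dry[idx])
    data.frame(season = s, n = m$n, r2 = m$r2, r2_ss = m$r2_ss,
               rmse = m$rmse, mae = m$mae, slope = m$slope,
               intercept = m$intercept, stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, per_season)
  class(rep) <- c("cv_report", "data.frame")
  attr(rep, "fold_seed") <- seed
  attr(rep, "n_skipped") <- n_skipped
  attr(rep, "n_unreliable") <- n_unreliable
  attr(rep, "k_by_season") <- k_by_season
  attr(rep, "folds") <- fold_lab
  attr(rep, "pred_dry") <- pred_dry
  rep
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-season cross-validation (%d rows skipped)\n",
              nrow(x), attr(x, "n_skipped")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
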