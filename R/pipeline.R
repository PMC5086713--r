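#' Run the estimation pipeline over a synthetic scene
#'
#' Applies the full chain — QA filtering, DB regridding, DT/DB fusion,
#' overpass collocation, physical corrections — to every day of a
#' generated scene and stacks the resulting model rows. This is the
#' entry point the cross-validation and parameter-recovery diagnostics
#' build on, and (on a noiseless scene) the closure check that the
#' generator and the estimator share one model.
#'
#' @param scene a `pm25_scene` from [simulate_scene()].
#' @param config a [run_config()]; its domain should match the scene's.
#' @return data.frame of model rows for all days, with attribute
#'   `n_excluded` (total rows dropped across days).
#' @export
scene_model_rows <- function(scene, config = run_config(
                               domain = scene$config$domain)) {
  rows <- vector("list", length(scene$days))
  n_excluded <- 0L
  for (d in seq_along(scene$days)) {
    day <- scene$days[d]
    g <- scene$granules[[d]]
    dt_f <- apply_qa_filter(g$dt)
    db_f <- apply_qa_filter(g$db)
    db_fine <- regrid_db_to_fine(db_f, dt_f$field)
    fused <- fuse_dt_db(dt_f, db_fine)
    day_records <- scene$records[scene$records$date == day, , drop = FALSE]
    r <- build_model_rows(fused, scene$met[[d]], scene$precip_stack,
                          scene$stations, day_records, day, config)
    n_excluded <- n_excluded + attr(r, "n_excluded")
    rows[[d]] <- r
  }
  out <- do.call(rbind, rows)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Daily GWR fits for every day of a row set
#'
#' Fits one GWR per estimation day (coefficients vary by location *and*
#' day). A single adaptive neighbour count is selected per season on a
#' sample of days, as in [crossval()].
#'
#' @param rows model rows spanning one or more days.
#' @param config a [run_config()].
#' @param k neighbour count; `NULL` selects per season.
#' @return named list of [fit_gwr()] objects, one per day.
#' @export
fit_gwr_daily <- function(rows, config = run_config(), k = NULL) {
  days <- sort(unique(rows$day))
  if (is.null(k)) {
    sample_days <- days[unique(round(seq(1, length(days),
                                         length.out = min(config$bw_sample_days,
                                                          length(days)))))]
    ks <- vapply(sample_days, function(d) {
      select_bandwidth(rows[rows$day == d, , drop = FALSE], config)$k
    }, integer(1))
    k <- as.integer(round(stats::median(ks)))
  }
  fits <- lapply(days, function(d) {
    fit_gwr(rows[rows$day == d, , drop = FALSE], config, k = k)
  })
  names(fits) <- format(days)
  fits
}
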