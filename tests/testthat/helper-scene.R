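# Shared fixtures, built in code. The tiny scene keeps unit tests fast;
# anything statistical about the full study conditions lives in the
# acceptance suite.

tiny_scene_config <- function(...) {
  args <- utils::modifyList(
    list(domain = c(100, 104, 30, 34), fine_cell = 0.08,
         coarse_cell = 0.24, met_cell = 0.5, precip_cell = 1,
         n_stations = 80L, n_days = 2L, n_clusters = 3L,
         cluster_sd = 0.5),
    list(...))
  do.call(scene_config, args)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

tiny_scene <- function() {
  cached("tiny_scene", simulate_scene(tiny_scene_config(), 7L))
}

tiny_rows <- function() {
  cached("tiny_rows", scene_model_rows(tiny_scene()))
}

tiny_config <- function(...) {
  run_config(domain = c(100, 104, 30, 34), ...)
}

# iid synthetic model rows with spatially constant true coefficients --
# the regression-identification fixture (no scene machinery involved)
flat_rows <- function(n, seed, beta = c(50, 80, -2, -0.5, 5e-4, -1.5),
                      noise_sd = 0) {
  set.seed(seed)
  rows <- data.frame(
    station_id = sprintf("F%03d", seq_len(n)),
    lon = runif(n, 100, 104), lat = runif(n, 30, 34),
    day = as.Date("2015-01-01"),
    revised_aod = exp(rnorm(n, log(0.45), 0.5)),
    last_prec = ifelse(runif(n) < 0.5, 0, rexp(n, 1 / 4)),
    st = rnorm(n, 288, 4), ps = rnorm(n, 96000, 1200),
    ws = abs(rnorm(n, 2, 1)), rh = runif(n, 20, 80),
    pblh = exp(rnorm(n, 0, 0.3)), stringsAsFactors = FALSE)
  X <- cbind(1, rows$revised_aod, rows$last_prec, rows$st, rows$ps,
             rows$ws)
  rows$revised_pm25 <- drop(X %*% beta) + rnorm(n, 0, noise_sd)
  rows$pm25 <- rows$revised_pm25 * (1 - rows$rh / 100)
  rows
}

# closed-form weighted least squares via normal equations: the
# independent oracle for every local fit
ols_oracle <- function(rows, weights = rep(1, nrow(rows))) {
  X <- cbind(1, rows$revised_aod, rows$last_prec, rows$st, rows$ps,
             rows$ws)
  y <- rows$revised_pm25
  W <- diag(weights)
  drop(solve(t(X) %*% W %*% X, t(X) %*% W %*% y))
}
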