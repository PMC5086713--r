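test_that("haversine distance matches the closed form and geosphere", {
  expect_identical(haversine_km(116.4, 39.9, 116.4, 39.9), 0)
  # one degree of meridian arc: 2 pi R / 360
  expect_equal(haversine_km(0, 0, 0, 1), 2 * pi * 6371 / 360,
               tolerance = 1e-5)
  set.seed(3)
  p <- cbind(runif(20, 70, 140), runif(20, 5, 55))
  q <- cbind(runif(20, 70, 140), runif(20, 5, 55))
  expect_equal(haversine_km(p[, 1], p[, 2], q[, 1], q[, 2]),
               haversine_km(q[, 1], q[, 2], p[, 1], p[, 2]))
  ref <- geosphere::distHaversine(p, q, r = 6371) # independent oracle
  expect_equal(haversine_km(p[, 1], p[, 2], q[, 1], q[, 2]), ref,
               tolerance = 1e-9)
})

test_that("bisquare kernel has the right shape and compact support", {
  expect_identical(bisquare_weight(0, 10), 1)
  expect_equal(bisquare_weight(5, 10), 0.5625)
  expect_identical(bisquare_weight(10, 10), 0)
  expect_identical(bisquare_weight(15, 10), 0)
  expect_error(bisquare_weight(1, 0), "bandwidth")
})

test_that("adaptive bandwidth is the k-th nearest distance", {
  expect_identical(adaptive_bandwidth_km(c(1, 2, 3, 4), 3, min_k = 1), 3)
  expect_identical(adaptive_bandwidth_km(c(4, 1, 3, 2), 4, min_k = 1), 4)
  expect_identical(adaptive_bandwidth_km(c(1, 2, 2, 5), 3, min_k = 1), 2)
  expect_error(adaptive_bandwidth_km(1:20, 3), "under-determined")
  expect_error(adaptive_bandwidth_km(1:5, 6, min_k = 1), "exceeds")
})

test_that("uniform-weight local fit matches the normal-equation oracle", {
  rows <- flat_rows(100, seed = 11, noise_sd = 8)
  fit <- local_wls(rows, rep(1, 100))
  expect_equal(unname(fit$coef), ols_oracle(rows), tolerance = 1e-8)
  # and with arbitrary positive weights against the weighted oracle
  set.seed(12)
  w <- runif(100, 0.1, 2)
  fitw <- local_wls(rows, w)
  expect_equal(unname(fitw$coef), ols_oracle(rows, w), tolerance = 1e-8)
})

test_that("an exactly linear response gives zero residuals and R2 = 1", {
  rows <- flat_rows(60, seed = 4, noise_sd = 0)
  set.seed(5)
  w <- runif(60, 0.05, 1)
  fit <- local_wls(rows, w)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  X <- cbind(1, rows$revised_aod, rows$last_prec, rows$st, rows$ps,
             rows$ws)
  expect_lt(max(abs(rows$revised_pm25 - drop(X %*% fit$coef))), 1e-8)
})

test_that("degenerate local designs are handled as specified", {
  rows <- flat_rows(50, seed = 6, noise_sd = 1)
  # duplicated regressor columns: hard singular error
  dup <- rows; dup$last_prec <- dup$revised_aod
  expect_error(local_wls(dup, rep(1, 50)), "singular")
  # a locally constant regressor is dropped with slope zero
  const <- rows; const$last_prec <- 0
  fit <- local_wls(const, rep(1, 50))
  expect_identical(unname(fit$coef["last_prec"]), 0)
  # remaining coefficients match a 5-regressor oracle
  X5 <- cbind(1, const$revised_aod, const$st, const$ps, const$ws)
  b5 <- drop(solve(t(X5) %*% X5, t(X5) %*% const$revised_pm25))
  expect_equal(unname(fit$coef[c("intercept", "revised_aod", "st", "ps",
                                 "ws")]), b5, tolerance = 1e-8)
  # too few positive weights
  expect_error(local_wls(rows, c(rep(1, 6), rep(0, 44))), "fewer than 7")
})

test_that("golden-section bandwidth search agrees with exhaustive search", {
  s <- tiny_scene()
  rows <- tiny_rows()
  d1 <- rows[rows$day == s$days[1], ][1:60, ]
  cfg <- tiny_config(k_range = c(8L, 50L))
  gold <- select_bandwidth(d1, cfg)
  brute <- select_bandwidth(d1, cfg, exhaustive = TRUE)
  expect_identical(gold$k, brute$k)
  expect_equal(gold$score, brute$score)
  # singleton range returns its only candidate
  expect_identical(select_bandwidth(d1, tiny_config(k_range = c(8L, 8L)))$k,
                   8L)
})

test_that("flat truth with low noise prefers wide bandwidths", {
  rows <- flat_rows(80, seed = 31, noise_sd = 2)
  cfg <- tiny_config(k_range = c(8L, 60L))
  sel <- select_bandwidth(rows, cfg)
  expect_gte(sel$k, 8L + as.integer(0.75 * (60 - 8)))  # top quartile
})

test_that("uniform kernel reduces every location to the global OLS fit", {
  rows <- flat_rows(100, seed = 21, noise_sd = 10)
  cfg <- tiny_config(kernel = "uniform")
  fit <- fit_gwr(rows, cfg, k = 30L)
  target <- ols_oracle(rows)
  for (i in c(1, 25, 100)) {
    expect_equal(unname(fit$coef[i, ]), target, tolerance = 1e-8)
  }
})

test_that("row order and row duplication do not change the fit", {
  s <- tiny_scene()
  rows <- tiny_rows()
  d1 <- rows[rows$day == s$days[1], ]
  cfg <- tiny_config()
  f1 <- fit_gwr(d1, cfg, k = 20L)
  set.seed(9)
  perm <- sample.int(nrow(d1))
  f2 <- fit_gwr(d1[perm, ], cfg, k = 20L)
  back <- match(f1$locations$station_id, f2$locations$station_id)
  expect_equal(f1$coef, f2$coef[back, ], tolerance = 1e-9)
  expect_equal(f1$local_r2, f2$local_r2[back], tolerance = 1e-9)
  # duplicating all rows rescales every local weight vector and changes
  # nothing (k doubles so the neighbour set is identical)
  dup <- rbind(d1, d1)
  f3 <- fit_gwr(dup, cfg, k = 40L)
  m <- match(f1$locations$station_id, f3$locations$station_id)
  expect_equal(f1$coef, f3$coef[m, ], tolerance = 1e-8)
})

test_that("fit floor and local R2 bounds hold", {
  rows <- flat_rows(10, seed = 2)
  expect_error(fit_gwr(rows, tiny_config()), "required")
  s <- tiny_scene()
  d1 <- tiny_rows()[tiny_rows()$day == s$days[1], ]
  f <- fit_gwr(d1, tiny_config(), k = 25L)
  expect_true(all(f$local_r2 <= 1 + 1e-12))
  expect_identical(dim(f$coef), c(nrow(d1), 6L))
  expect_true(all(f$bandwidth_km > 0))
})

test_that("beyond-bandwidth observations have exactly zero influence", {
  rows <- flat_rows(60, seed = 41, noise_sd = 5)
  cfg <- tiny_config()
  D <- outer(seq_len(60), seq_len(60), function(i, j)
    haversine_km(rows$lon[i], rows$lat[i], rows$lon[j], rows$lat[j]))
  b <- adaptive_bandwidth_km(D[1, ], 20)
  w <- bisquare_weight(D[1, ], b)
  fit1 <- local_wls(rows, w)
  # corrupt every zero-weight row; the fit must not move
  rows2 <- rows
  rows2$revised_pm25[w == 0] <- rows2$revised_pm25[w == 0] + 1000
  fit2 <- local_wls(rows2, w)
  expect_identical(fit1$coef, fit2$coef)
})

test_that("prediction interpolates exactly under constant coefficients", {
  # constant-coefficient noiseless scene: local fits recover the global
  # truth and predictions are exact everywhere
  sc <- tiny_scene_config(noiseless = TRUE, beta_amp = rep(0, 6))
  s <- simulate_scene(sc, 17L)
  rows <- scene_model_rows(s)
  d1 <- rows[rows$day == s$days[1], ]
  cfg <- tiny_config()
  p <- predict_gwr(d1, d1, cfg, k = 20L)
  expect_equal(as.numeric(p), d1$revised_pm25, tolerance = 1e-8)
})

test_that("including a target's own row pulls the prediction toward it", {
  s <- tiny_scene()
  rows <- tiny_rows()
  d1 <- rows[rows$day == s$days[1], ]
  cfg <- tiny_config()
  i <- 5L
  with_i <- predict_gwr(d1, d1[i, ], cfg, k = 20L)
  without_i <- predict_gwr(d1[-i, ], d1[i, ], cfg, k = 20L)
  y <- d1$revised_pm25[i]
  expect_true(is.finite(without_i))
  expect_lte(abs(with_i - y), abs(without_i - y) + 1e-9)
})

test_that("points with missing regressors predict as missing", {
  s <- tiny_scene()
  d1 <- tiny_rows()[tiny_rows()$day == s$days[1], ]
  pt <- d1[1, ]
  pt$revised_aod <- NA_real_
  expect_identical(as.numeric(predict_gwr(d1, pt, tiny_config(), k = 20L)),
                   NA_real_)
})
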