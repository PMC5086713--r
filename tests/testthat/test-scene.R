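test_that("coefficient surfaces are mean plus bounded smooth perturbation", {
  sc <- tiny_scene_config()
  flat <- tiny_scene_config(beta_amp = rep(0, 6))
  truth0 <- make_coefficient_surfaces(flat, 3L)
  for (j in 1:6) {
    expect_true(all(truth0$surfaces[[j]]$values == flat$beta_mean[j]))
  }

  t1 <- make_coefficient_surfaces(sc, 3L)
  t2 <- make_coefficient_surfaces(sc, 3L)
  expect_identical(t1$surfaces, t2$surfaces)     # reproducible
  t3 <- make_coefficient_surfaces(sc, 4L)
  expect_false(identical(t1$surfaces, t3$surfaces))

  # perturbation never exceeds the amplitude (weights sum to 1 in
  # absolute value)
  for (j in 1:6) {
    dev <- abs(t1$surfaces[[j]]$values - sc$beta_mean[j])
    expect_lte(max(dev), sc$beta_amp[j] + 1e-12)
  }
})

test_that("surface roughness respects the wave-table Laplacian bound", {
  # for a plane wave sin(k . r), the cell value minus its 4-neighbour
  # mean is sin(k . r) * (1 - (cos(kx h) + cos(ky h)) / 2); the bound
  # below is computed from the realised component table, not fitted
  sc <- tiny_scene_config()
  truth <- make_coefficient_surfaces(sc, 3L)
  h <- sc$fine_cell
  for (j in 1:6) {
    tab <- truth$waves[[j]]
    kx <- 2 * pi * tab$ux / tab$wavelength
    ky <- 2 * pi * tab$uy / tab$wavelength
    bound <- sc$beta_amp[j] *
      sum(abs(tab$weight) * (1 - (cos(kx * h) + cos(ky * h)) / 2))
    v <- truth$surfaces[[j]]$values
    inner_i <- 2:(nrow(v) - 1); inner_j <- 2:(ncol(v) - 1)
    mean4 <- (v[inner_i - 1, inner_j] + v[inner_i + 1, inner_j] +
                v[inner_i, inner_j - 1] + v[inner_i, inner_j + 1]) / 4
    dev <- abs(v[inner_i, inner_j] - mean4)
    expect_lte(max(dev), bound + 1e-12)
  }
})

test_that("station network honours count, domain and clustering", {
  sc <- tiny_scene_config(n_stations = 50L)
  st <- make_station_network(sc, 5L)
  expect_identical(nrow(st), 50L)
  expect_true(all(st$lon >= sc$domain[1] & st$lon <= sc$domain[2] &
                    st$lat >= sc$domain[3] & st$lat <= sc$domain[4]))
  expect_error(
    make_station_network(tiny_scene_config(n_stations = 10^6L), 5L),
    "density ceiling")

  # clustering = 0: occupancy of a 4x4 grid is not rejected as uniform
  scu <- tiny_scene_config(n_stations = 2000L, clustering = 0)
  stu <- make_station_network(scu, 5L)
  occ_u <- table(cut(stu$lon, seq(100, 104, 1)),
                 cut(stu$lat, seq(30, 34, 1)))
  p <- suppressWarnings(stats::chisq.test(as.vector(occ_u)))$p.value
  expect_gt(p, 0.01)

  # strong clustering concentrates occupancy (same n, same seed)
  scc <- tiny_scene_config(n_stations = 2000L, clustering = 0.9)
  stc <- make_station_network(scc, 5L)
  occ_c <- table(cut(stc$lon, seq(100, 104, 1)),
                 cut(stc$lat, seq(30, 34, 1)))
  expect_gt(stats::var(as.vector(occ_c)), stats::var(as.vector(occ_u)))
})

test_that("meteorological marginals match their configured families", {
  # degenerate log-normal: PBLH identically exp(meanlog)
  scd <- tiny_scene_config(pblh_meanlog = 0, pblh_sdlog = 0)
  fd <- make_meteorology(scd, 1L, 9L)
  expect_true(all(fd$pblh$values == 1))

  sc <- tiny_scene_config()
  fields <- lapply(1:20, function(d) make_meteorology(sc, d, 9L))
  expect_true(all(vapply(fields, function(f) all(f$pblh$values > 0),
                         logical(1))))
  expect_true(all(vapply(fields, function(f)
    all(f$rh$values >= 0 & f$rh$values <= sc$rh_cap), logical(1))))
  # day fields are independent draws: mean of the per-day RH means
  # should sit within 3 standard errors of the configured mean
  day_means <- vapply(fields, function(f) mean(f$rh$values), numeric(1))
  se <- stats::sd(day_means) / sqrt(length(day_means))
  expect_lt(abs(mean(day_means) - sc$rh_mean), 3 * se + 1)
  # precipitation is zero-inflated
  wet_frac <- mean(vapply(fields, function(f)
    mean(f$precip$values > 0), numeric(1)))
  expect_lt(wet_frac, 0.5)
})

test_that("bimodal pressure option yields two separated modes", {
  sc <- tiny_scene_config(ps_bimodal = TRUE, met_cell = 0.25)
  ps <- unlist(lapply(1:10, function(d)
    as.vector(make_meteorology(sc, d, 9L)$ps$values)))
  km <- stats::kmeans(ps, centers = c(80000, 96000))
  expect_gt(min(km$size) / length(ps), 0.1)   # both modes populated
  gap <- abs(diff(km$centers))
  pooled_sd <- sqrt(mean(c(stats::var(ps[km$cluster == 1]),
                           stats::var(ps[km$cluster == 2]))))
  expect_gt(gap, 4 * pooled_sd)               # well separated
})

test_that("noiseless observations equal the closed-form model composition", {
  sc <- tiny_scene_config(noiseless = TRUE)
  s <- simulate_scene(sc, 7L)
  tr <- s$truth_rows
  expect_equal(tr$revised_pm25, tr$revised_pm25_true, tolerance = 1e-12)
  # recompute the regression identity from the stored regressors
  beta <- s$truth$beta_at(tr$lon, tr$lat)
  rhs <- beta[, 1] + beta[, 2] * tr$revised_aod + beta[, 3] * tr$last_prec +
    beta[, 4] * tr$st + beta[, 5] * tr$ps + beta[, 6] * tr$ws
  expect_equal(tr$revised_pm25, rhs, tolerance = 1e-10)
  # recorded hourly values equal the dry daily value when jitter is 0
  d1 <- s$days[1]
  r13 <- s$records[s$records$date == d1 &
                     s$records$hour_beijing %in% (21L - 7L), ]
  expect_gt(nrow(r13), 0)
  m <- match(r13$station_id, tr$station_id[tr$day == d1])
  expect_equal(r13$pm25, tr$pm25[tr$day == d1][m], tolerance = 1e-12)
})

test_that("observation noise is mean-zero on the revised scale", {
  sc <- tiny_scene_config(n_stations = 400L, n_days = 6L)
  s <- simulate_scene(sc, 13L)
  delta <- s$truth_rows$revised_pm25 - s$truth_rows$revised_pm25_true
  n <- length(delta)
  expect_gt(n, 2000)
  expect_lt(abs(mean(delta)), 3 * sc$noise_sd / sqrt(n))
})

test_that("granules encode mask, QA and block-averaged DB as configured", {
  # clean configuration: DT pixel equals column AOD = revised AOD x PBLH
  sc <- tiny_scene_config(noiseless = TRUE)
  f <- make_meteorology(sc, 1L, 7L)
  g <- make_aod_granules(f, sc, 1L, 7L)
  col <- column_aod_field(f$rev_aod, f$pblh)
  expect_equal(g$dt$field$values, col$values, tolerance = 1e-12)
  expect_true(all(g$dt$qa == 3L))

  # bright-surface missingness at the configured rate (binomial SE)
  scb <- scene_config(domain = c(100, 104, 30, 34), fine_cell = 0.04,
                      coarse_cell = 0.2, met_cell = 0.5, precip_cell = 1,
                      n_stations = 10L, n_days = 1L,
                      bright_fraction = 0.3)
  fb <- make_meteorology(scb, 1L, 7L)
  gb <- make_aod_granules(fb, scb, 1L, 7L)
  ncell <- length(gb$dt$field$values)
  expect_gte(ncell, 1e4)
  miss <- mean(is.na(gb$dt$field$values))
  expect_lt(abs(miss - 0.3), 0.02)
  # bright cells: DT missing, DB (coarse, containing cell) defined
  expect_true(all(is.na(gb$dt$field$values[gb$bright])))
  co <- grid_coords(gb$dt$field)
  idx <- which(gb$bright, arr.ind = TRUE)[1:50, ]
  dbv <- pixel_at(gb$db$field, co$lon[idx[, 2]], co$lat[idx[, 1]])
  expect_true(all(is.finite(dbv)))

  # DB is the block average of fine column AOD (zero retrieval noise)
  colb <- column_aod_field(fb$rev_aod, fb$pblh)
  scb0 <- scb; scb0$db_noise_sd <- 0
  gb0 <- make_aod_granules(fb, scb0, 1L, 7L)
  cof <- grid_coords(colb)
  # check one interior coarse cell by direct averaging; the coarse grid
  # has origin (99.9, 29.9) and 0.2 degree cells, so (101.05, 31.05)
  # falls in the cell spanning [101.0, 101.2) x [31.0, 31.2)
  target_lon <- 101.05; target_lat <- 31.05
  in_lon <- which(cof$lon >= 101.0 & cof$lon < 101.2)
  in_lat <- which(cof$lat >= 31.0 & cof$lat < 31.2)
  expect_equal(pixel_at(gb0$db$field, target_lon, target_lat),
               mean(colb$values[in_lat, in_lon]), tolerance = 1e-12)
})

test_that("a scene is bit-for-bit reproducible from (config, seed)", {
  sc <- tiny_scene_config(n_stations = 30L, n_days = 1L)
  s1 <- simulate_scene(sc, 21L)
  s2 <- simulate_scene(sc, 21L)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth_rows, s2$truth_rows)
  expect_identical(s1$granules[[1]]$dt$field$values,
                   s2$granules[[1]]$dt$field$values)
  expect_identical(s1$stations, s2$stations)
})
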