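test_that("time-zone bands map longitudes to UTC offsets +5..+9", {
  expect_identical(zone_offset(116.4), 8L)
  expect_identical(zone_offset(87.6), 6L)
  expect_identical(zone_offset(131.0), 9L)
  expect_identical(zone_offset(c(75, 90, 105, 120, 135)), 5:9)
  expect_identical(zone_offset(67.5), 5L)        # west edge inclusive
  expect_error(zone_offset(60), "outside")
  expect_error(zone_offset(150), "outside")
  # shifting a longitude by one band shifts the offset by exactly one
  lon <- c(70, 87.6, 100, 116.4, 130)
  expect_identical(zone_offset(lon[-5] + 15), zone_offset(lon[-5]) + 1L)
})

test_that("overpass averaging follows the local 13:00/14:00 clock", {
  rec <- data.frame(hour_beijing = c(13L, 14L), pm25 = c(40, 60))
  expect_equal(overpass_pm25(rec, 8L)$pm25, 50)
  # a UTC+6 station reports its local 13:00/14:00 at Beijing 15:00/16:00
  rec6 <- data.frame(hour_beijing = c(15L, 16L), pm25 = c(30, 50))
  expect_equal(overpass_pm25(rec6, 6L)$pm25, 40)
  # at Beijing clock 13/14 the same records are *not* the overpass pair
  expect_identical(overpass_pm25(rec, 6L)$pm25, NA_real_)
  # single-hour fallback
  one <- data.frame(hour_beijing = 13L, pm25 = 40)
  r <- overpass_pm25(one, 8L)
  expect_equal(r$pm25, 40)
  expect_identical(r$n_hours, 1L)
  expect_identical(overpass_pm25(one[0, ], 8L)$pm25, NA_real_)
})

test_that("local calendar dates roll over by zone near midnight", {
  d <- as.Date("2015-06-10")
  expect_identical(local_date(d, 13L, 8L), d)
  expect_identical(local_date(d, 2L, 5L), d - 1)   # Beijing 02:00 is
                                                   # 23:00 local UTC+5
  expect_identical(local_date(d, 23L, 9L), d + 1)  # UTC+9 already next day
})

test_that("previous-day precipitation selects the local day-1 grid", {
  g1 <- grid_field(matrix(0, 4, 4), c(100, 30), 1, var = "precip",
                   units = "mm")
  g2 <- grid_field(matrix(5, 4, 4), c(100, 30), 1, var = "precip",
                   units = "mm")
  stack <- list("2015-06-09" = g1, "2015-06-10" = g2)
  expect_equal(prev_day_precip(stack, 101.5, 31.5, as.Date("2015-06-10")),
               0)
  expect_equal(prev_day_precip(stack, 101.5, 31.5, as.Date("2015-06-11")),
               5)
  expect_identical(
    prev_day_precip(stack, 101.5, 31.5, as.Date("2015-06-09")), NA_real_)
  # two stations observing at the same Beijing instant near local
  # midnight resolve to different day-1 grids across zone bands
  beijing_date <- as.Date("2015-06-10"); beijing_hour <- 2L
  d_west <- local_date(beijing_date, beijing_hour, 5L)  # 23:00 on the 9th
  d_east <- local_date(beijing_date, beijing_hour, 9L)  # 03:00 on the 10th
  expect_equal(prev_day_precip(stack, 101.5, 31.5, d_west), NA_real_)
  expect_equal(prev_day_precip(stack, 101.5, 31.5, d_east), 0)
})

test_that("model rows are complete-case with exclusions counted", {
  s <- tiny_scene()
  rows <- tiny_rows()
  ## no missing or non-finite regressor anywhere
  num <- rows[, c("revised_aod", "last_prec", "st", "ps", "ws", "rh",
                  "pblh", "revised_pm25", "pm25")]
  expect_true(all(vapply(num, function(x) all(is.finite(x)), logical(1))))
  expect_true(all(rows$rh <= 95))
  expect_true(all(rows$pblh > 0))
  expect_identical(nrow(rows) + attr(rows, "n_excluded"),
                   nrow(s$stations) * length(s$days))
})

test_that("a fully clean scene yields one row per station per day", {
  sc <- tiny_scene_config(noiseless = TRUE)
  s <- simulate_scene(sc, 7L)
  rows <- scene_model_rows(s)
  expect_identical(nrow(rows), nrow(s$stations) * length(s$days))
  expect_identical(attr(rows, "n_excluded"), 0L)
})

test_that("a station whose fused pixel is masked is excluded and counted", {
  sc <- tiny_scene_config(noiseless = TRUE, n_days = 1L)
  s <- simulate_scene(sc, 7L)
  day <- s$days[1]
  g <- s$granules[[1]]
  dtf <- apply_qa_filter(g$dt)
  fused <- fuse_dt_db(dtf, regrid_db_to_fine(apply_qa_filter(g$db),
                                             dtf$field))
  ## mask the pixel containing station 1 in both products, i.e. the
  ## fused field
  st1 <- s$stations[1, ]
  co <- grid_coords(fused)
  j <- which.min(abs(co$lon - st1$lon)); i <- which.min(abs(co$lat - st1$lat))
  fused$values[i, j] <- NA
  cfg <- tiny_config()
  rows <- build_model_rows(fused, s$met[[1]], s$precip_stack, s$stations,
                           s$records[s$records$date == day, ], day, cfg)
  expect_identical(nrow(rows), nrow(s$stations) - 1L)
  expect_false(st1$station_id %in% rows$station_id)
  expect_identical(attr(rows, "n_excluded"), 1L)
  expect_identical(unname(attr(rows, "exclusions")["no_aod"]), 1L)
})

test_that("noiseless rows reproduce the truth regression exactly", {
  sc <- tiny_scene_config(noiseless = TRUE)
  s <- simulate_scene(sc, 7L)
  rows <- scene_model_rows(s)
  beta <- s$truth$beta_at(rows$lon, rows$lat)
  rhs <- beta[, 1] + beta[, 2] * rows$revised_aod +
    beta[, 3] * rows$last_prec + beta[, 4] * rows$st +
    beta[, 5] * rows$ps + beta[, 6] * rows$ws
  expect_equal(rows$revised_pm25, rhs, tolerance = 1e-8)
})
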