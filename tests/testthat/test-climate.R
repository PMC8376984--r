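toy_weather <- function(tmin, tmax, precip, start = "2020-01-01") {
  data.frame(date = as.Date(start) + seq_along(tmin) - 1,
             tmin = tmin, tmax = tmax, precip = precip)
}

test_that("phase windows are validated and half-open", {
  expect_error(phase_windows("2020-01-05", "2020-01-01", "2020-02-01",
                             "2020-03-01"), "strictly increasing")
  # a distinctive flowering-day value must not leak into the vegetative phase
  w <- toy_weather(tmin = c(10, 10, 10, -5, 10, 10, 10, 10),
                   tmax = rep(20, 8), precip = rep(0, 8))
  p <- phase_windows("2020-01-01", "2020-01-04", "2020-01-06", "2020-01-08")
  ci <- climate_indices(w, p)
  expect_equal(ci$minNT_veg, 10)
  expect_equal(ci$minNT_rep, -5)
})

test_that("constant temperature collapses the night statistics", {
  w <- toy_weather(rep(10, 10), rep(18, 10), rep(0, 10))
  p <- phase_windows("2020-01-01", "2020-01-04", "2020-01-07", "2020-01-10")
  ci <- climate_indices(w, p)
  expect_equal(ci$minNT_veg, 10)
  expect_equal(ci$maxNT_veg, 10)
  expect_equal(ci$meanNT_veg, 10)
  expect_equal(ci$DTR_full, 8)
})

test_that("GDD and rainfall indices match hand computation", {
  w <- toy_weather(tmin = c(8, 9, 7, 10, 6, 8, 8, 8),
                   tmax = c(18, 20, 17, 21, 19, 18, 18, 18),
                   precip = c(0, 0, 5, 0, 0, 2, 0, 0))
  p <- phase_windows("2020-01-01", "2020-01-06", "2020-01-07", "2020-01-08")
  ci <- climate_indices(w, p)
  expect_equal(ci$GDD_veg, 13 + 14.5 + 12 + 15.5 + 12.5)  # 67.5
  expect_equal(ci$max_dry_run_veg, 2)
  expect_equal(ci$rain_days_veg, 1)
  expect_equal(ci$rain_total_veg, 5)
  expect_equal(ci$rain_max_1d_veg, 5)
  expect_equal(ci$rain_max_5d_veg, 5)
})

test_that("temperature shift moves NT/DT indices by c and GDD by c * length", {
  base <- toy_weather(tmin = rnorm(12, 10), tmax = rnorm(12, 20) + 5,
                      precip = runif(12, 0, 3))
  p <- phase_windows("2020-01-01", "2020-01-05", "2020-01-09", "2020-01-13")
  a <- climate_indices(base, p)
  shifted <- base; shifted$tmin <- base$tmin + 2; shifted$tmax <- base$tmax + 2
  b <- climate_indices(shifted, p)
  expect_equal(b$minNT_veg, a$minNT_veg + 2)
  expect_equal(b$meanDT_full, a$meanDT_full + 2)
  expect_equal(b$GDD_full, a$GDD_full + 2 * 12)
  expect_equal(b$DTR_full, a$DTR_full)
  # ordering invariant per phase
  for (ph in c("veg", "rep", "gf", "full")) {
    expect_lte(a[[paste0("minNT_", ph)]], a[[paste0("meanNT_", ph)]])
    expect_lte(a[[paste0("meanNT_", ph)]], a[[paste0("maxNT_", ph)]])
  }
})

test_that("coverage gaps are reported with the missing dates", {
  w <- toy_weather(rep(10, 5), rep(20, 5), rep(0, 5))
  p <- phase_windows("2020-01-01", "2020-01-04", "2020-01-06", "2020-01-09")
  expect_error(climate_indices(w, p), "missing date")
  bad <- w; bad$tmin[2] <- 30
  p2 <- phase_windows("2020-01-01", "2020-01-03", "2020-01-04", "2020-01-05")
  expect_error(climate_indices(bad, p2), "tmin")
})

test_that("sowing windows are quantile-interval midpoints", {
  d <- as.Date("2020-01-01") + c(0, 10, 20, 30, 40, 50)
  expect_equal(sowing_windows(d, 3),
               as.Date(round(quantile(as.numeric(d), c(1, 3, 5) / 6,
                                      type = 7, names = FALSE)),
                       origin = "1970-01-01"))
  same <- rep(as.Date("2020-06-01"), 5)
  expect_equal(sowing_windows(same, 3), rep(as.Date("2020-06-01"), 3))
  big <- as.Date("2020-01-01") + withr::with_seed(1, sample(0:89, 5000, TRUE))
  got <- as.integer(sowing_windows(big, 3) - as.Date("2020-01-01")) + 1
  expect_equal(got, c(15, 45, 75), tolerance = 0.15)
  expect_error(sowing_windows(as.Date(character(0))), "non-empty")
})
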