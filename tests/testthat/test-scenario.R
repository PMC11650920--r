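test_that("GPP-latitude regression reproduces its printed line", {
  expect_equal(suppressWarnings(gpp_from_latitude(0)), 88.0)
  expect_equal(gpp_from_latitude(50), 38.13 * 50 + 88.0)
  expect_equal(gpp_from_latitude(60), 2375.8)
  expect_error(gpp_from_latitude(NaN), "finite")
  expect_warning(gpp_from_latitude(10), "18-78")
})

test_that("primary consumer production follows its printed line", {
  expect_equal(pcp_from_gpp(0), 9.04)
  expect_equal(pcp_from_gpp(1994.5), 0.02 * 1994.5 + 9.04)
  expect_equal(pcp_from_gpp(2375.8), 56.556)
  expect_error(pcp_from_gpp(-1), "nonnegative")
})

test_that("latitude-to-food chain is affine (brute-force oracle)", {
  f <- function(x) pcp_from_gpp(suppressWarnings(gpp_from_latitude(x)))
  for (a in c(20, 35.5, 47)) {
    for (b in c(18.2, 25, 30.9)) {
      # slope part adds: f(a) + f(b) - f(0) should equal f(a + b)
      expect_equal(f(a) + f(b) - f(0), f(a + b), tolerance = 1e-12)
    }
  }
})

test_that("areal production converts to per-patch food", {
  geom <- system_geometry()
  expect_equal(food_per_patch(0, geom), 0)
  # 20 m2 over 50 vegetated patches, mg -> g
  expect_equal(food_per_patch(48.93, geom), 48.93 * 20 / 1000 / 50)
  expect_error(food_per_patch(-1, geom), "nonnegative")
  geom0 <- system_geometry(vegetated_ratio = 0)
  expect_error(food_per_patch(10, geom0), "vegetated")
})

test_that("warming offsets and food factor match the biomass regression", {
  expect_equal(warming_log10_offset(0), 1.090)
  expect_equal(warming_log10_offset(1.4), 1.090 + 0.138 * 1.4)
  expect_error(warming_log10_offset(-1), "nonnegative")
  expect_equal(warming_food_factor(0), 1)
  expect_equal(apply_warming_food_increase(0.0196, 1.4),
               0.0196 * 10^(0.138 * 1.4))
  expect_equal(apply_warming_food_increase(0.0226, 4.4),
               0.0226 * 10^0.6072)
  expect_error(apply_warming_food_increase(0, 1.4), "positive")
})

test_that("scenarios satisfy their invariants", {
  sc <- build_scenario(55, 0, seasonal_shape = rep(1, 12))
  expect_equal(round(sc$monthly_food_per_patch, 4), rep(0.0211, 12))
  expect_equal(mean(sc$monthly_food_per_patch), sc$annual_mean_food,
               tolerance = 1e-9)
  expect_equal(sc$monthly_temperature, default_monthly_temperatures(55))

  warm <- build_scenario(55, 2.7)
  base <- build_scenario(55, 0)
  expect_equal(warm$monthly_temperature, base$monthly_temperature + 2.7)
  expect_equal(warm$annual_mean_food,
               base$annual_mean_food * warming_food_factor(2.7))

  # seasonal shape is scale-invariant
  shape <- default_food_shape()
  sc1 <- build_scenario(50, 1.4, seasonal_shape = shape)
  sc2 <- build_scenario(50, 1.4, seasonal_shape = 2 * shape)
  expect_equal(sc1$monthly_food_per_patch, sc2$monthly_food_per_patch)

  expect_error(build_scenario(55, 0, seasonal_shape = c(rep(1, 11), -1)),
               "positive")
})

test_that("rescaled random shapes hit their target annual mean", {
  set.seed(101)
  for (i in 1:1000) {
    shape <- stats::runif(12, 0.05, 3)
    lat <- stats::runif(1, 50, 60)
    dt <- sample(c(0, 1.4, 2.7, 4.4), 1)
    sc <- build_scenario(lat, dt, seasonal_shape = shape)
    expect_equal(mean(sc$monthly_food_per_patch), sc$annual_mean_food,
                 tolerance = 1e-9)
    expect_true(all(sc$monthly_food_per_patch >= 0))
  }
})

test_that("monthly driver tables round-trip through delimited text", {
  sc <- build_scenario(60, 4.4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_monthly_drivers(sc, path)
  d <- read_monthly_drivers(path)
  expect_equal(d$temperature_c, sc$monthly_temperature)
  expect_equal(d$food_g_patch_day, sc$monthly_food_per_patch)

  sc2 <- scenario_from_drivers(d, lat = 60, delta_t = 0)
  # drivers carry the warmed shape; rebuilt scenario keeps its pattern
  expect_equal(sc2$monthly_food_per_patch / mean(sc2$monthly_food_per_patch),
               sc$monthly_food_per_patch / mean(sc$monthly_food_per_patch))
})

test_that("regression_spec validates and predicts", {
  expect_error(regression_spec(Inf, 0), "finite")
  r <- macroinvertebrate_temperature_regression()
  expect_equal(predict_regression(r, 5), 0.138 * 5 + 1.090)
  expect_equal(predict_regression(r, 5, back_transform = TRUE),
               10^(0.138 * 5 + 1.090))
})

test_that("constant scenarios hold drivers flat", {
  sc <- constant_scenario(0.01, 12)
  expect_equal(sc$monthly_food_per_patch, rep(0.01, 12))
  expect_equal(sc$monthly_temperature, rep(12, 12))
})
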