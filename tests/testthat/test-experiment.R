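test_that("census tables follow the design algebra", {
  cfg <- experiment_config(latitudes = 55, delta_ts = 0, warmup_years = 0,
                           treatment_years = 3, n_replicates = 2,
                           n_init = 20L, base_seed = 9)
  cen <- run_experiment(cfg)
  expect_equal(nrow(cen), 1 * 1 * 2 * 3)
  expect_equal(sort(unique(cen$year)), 1:3)
  cfg2 <- experiment_config(latitudes = c(50, 60), delta_ts = c(0, 4.4),
                            warmup_years = 0, treatment_years = 2,
                            n_replicates = 2, n_init = 20L, base_seed = 9)
  cen2 <- run_experiment(cfg2)
  expect_equal(nrow(cen2), 2 * 2 * 2 * 2)
  # the full study design would give 3 x 4 x 15 x 10 = 1800 rows
  full <- experiment_config()
  expect_equal(length(full$latitudes) * length(full$delta_ts) *
                 full$n_replicates * full$treatment_years, 1800)
  expect_error(experiment_config(delta_ts = c(1.4, 2.7)), "include 0")
})

test_that("experiments are reproducible under the base seed", {
  cfg <- experiment_config(latitudes = 60, delta_ts = c(0, 1.4),
                           warmup_years = 1, treatment_years = 2,
                           n_replicates = 2, n_init = 30L, base_seed = 4)
  a <- run_experiment(cfg)
  b <- run_experiment(cfg)
  expect_identical(a, b)
})

test_that("percent change is the signed relative difference", {
  expect_equal(percent_change(10, 10), 0)
  expect_equal(percent_change(10, 20.8), 108)
  expect_equal(percent_change(10, 9.2), -8)
  expect_error(percent_change(0, 5), "nonpositive")
})

test_that("effect detection applies the threshold to decade means", {
  base <- expand.grid(replicate = 1:3, year = 1:10)
  ctrl <- data.frame(latitude = 55, delta_t = 0, replicate = base$replicate,
                     year = base$year, density = 2, biomass = 10)
  scale_by <- function(f) {
    d <- ctrl; d$delta_t <- 1.4; d$density <- d$density * f
    d$biomass <- d$biomass * f; d
  }
  same <- detect_effect(ctrl, scale_by(1), "density")
  expect_equal(same$percent_change, 0)
  expect_false(same$detectable)
  up6 <- detect_effect(ctrl, scale_by(1.06), "density")
  expect_true(up6$detectable)
  expect_equal(up6$percent_change, 6, tolerance = 1e-9)
  up4 <- detect_effect(ctrl, scale_by(1.04), "density")
  expect_false(up4$detectable)
  down6 <- detect_effect(ctrl, scale_by(0.94), "biomass")
  expect_true(down6$detectable)
  other <- ctrl; other$latitude <- 60
  expect_error(detect_effect(ctrl, other), "same latitude")
  expect_error(detect_effect(ctrl[0, ], scale_by(1.06)), "non-empty")
})

test_that("final-census summaries match hand-computed means", {
  fix <- expand.grid(latitude = 55, delta_t = c(0, 4.4), replicate = 1:3,
                     year = 1:2)
  fix$abundance <- 40
  fix$density <- ifelse(fix$delta_t == 0, 2, 3) + fix$replicate / 10
  fix$biomass <- 2 * fix$density
  fix$mean_metabolic_rate <- 50
  fix$extinct <- FALSE
  s <- summarize_final_census(fix)
  expect_equal(nrow(s), 2L)
  expect_equal(s$density_mean[s$delta_t == 0], mean(2 + (1:3) / 10))
  expect_equal(s$density_sd[s$delta_t == 4.4], stats::sd(3 + (1:3) / 10))
  expect_equal(s$density_percent_change[s$delta_t == 4.4],
               percent_change(mean(2 + (1:3) / 10), mean(3 + (1:3) / 10)))
  # single replicate: zero SDs
  one <- fix[fix$replicate == 1, ]
  s1 <- summarize_final_census(one)
  expect_true(all(s1$density_sd == 0))
  # extinction: all-zero group flagged, percent change NA-safe
  dead <- fix
  dead$density[dead$delta_t == 4.4] <- 0
  dead$biomass[dead$delta_t == 4.4] <- 0
  dead$abundance[dead$delta_t == 4.4] <- 0
  dead$extinct <- dead$delta_t == 4.4
  s2 <- summarize_final_census(dead)
  expect_equal(s2$extinct_replicates[s2$delta_t == 4.4], 3L)
  expect_equal(s2$density_mean[s2$delta_t == 4.4], 0)
  # no control rows: warning, percent-change columns absent
  expect_warning(s3 <- summarize_final_census(fix[fix$delta_t == 4.4, ]),
                 "control")
  expect_false("density_percent_change" %in% names(s3))
})
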