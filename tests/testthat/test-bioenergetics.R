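p <- bioenergetics_params()

test_that("temperature scaling honours Q10 and the thermal window", {
  tref <- p$reference_temperature
  tw <- p$thermal_window
  expect_equal(temperature_scaling(tref, 2, tref, tw), 1)
  expect_equal(temperature_scaling(tref + 5, 2, tref, tw), 2^0.5)
  expect_equal(temperature_scaling(tw[3], 2, tref, tw), 0)
  expect_equal(temperature_scaling(tw[1], 2, tref, tw), 0)
  expect_equal(temperature_scaling(tw[1] - 3, 2, tref, tw, taper = FALSE), 0)
  # untapered variant rises monotonically up to CT_max
  temps <- seq(tw[1] + 0.5, tw[3] - 0.5, by = 0.5)
  expect_true(all(diff(temperature_scaling(temps, 2, tref, tw,
                                           taper = FALSE)) > 0))
  # tapered variant is continuous across CT_opt
  eps <- 1e-8
  expect_equal(temperature_scaling(tw[2] - eps, 2, tref, tw),
               temperature_scaling(tw[2] + eps, 2, tref, tw),
               tolerance = 1e-6)
})

test_that("ingestion and maintenance follow allometric power laws", {
  tref <- p$reference_temperature
  expect_equal(max_ingestion(2, tref, p) / max_ingestion(1, tref, p),
               2^p$ingestion_mass_exponent)
  # a 10 degree rise lands above CT_opt: Q10 doubling times the taper
  fade <- (p$thermal_window[3] - (tref + 10)) /
    (p$thermal_window[3] - p$thermal_window[2])
  expect_equal(max_ingestion(1, tref + 10, p) / max_ingestion(1, tref, p),
               p$q10_ingestion * fade)
  # below CT_opt the ratio is the pure Q10 factor
  expect_equal(max_ingestion(1, tref + 5, p) / max_ingestion(1, tref, p),
               p$q10_ingestion^0.5)
  expect_equal(max_ingestion(1, p$thermal_window[3], p), 0)
  expect_error(max_ingestion(0, tref, p), "positive mass")

  expect_equal(maintenance_cost(1, tref, p), p$maintenance_coeff)
  expect_equal(maintenance_cost(1, tref + 10, p),
               p$maintenance_coeff * p$q10_metabolism)
  expect_equal(maintenance_cost(2, tref, p) / maintenance_cost(1, tref, p),
               2^p$metabolic_mass_exponent)
})

test_that("patch food is shared in proportion to demand when limited", {
  expect_equal(share_patch_food(0.01, 1), 0.01)
  # two identical fish, half the joint demand available: 25% each
  expect_equal(share_patch_food(c(0.1, 0.1), 0.1), c(0.05, 0.05))
  expect_equal(share_patch_food(c(0.1, 0.3), 0.2), c(0.05, 0.15))
  expect_equal(share_patch_food(c(0.1, 0.1), 0), c(0, 0))
  intakes <- share_patch_food(c(0.2, 0.05, 0.15), 0.1)
  expect_lte(sum(intakes), 0.1 + 1e-12)
  expect_true(all(intakes <= c(0.2, 0.05, 0.15)))
})

test_that("assimilation is linear in intake, efficiency and energy density", {
  expect_equal(assimilate(0, p), 0)
  q <- bioenergetics_params(food_energy_density = 3000,
                            assimilation_efficiency = 0.7)
  expect_equal(assimilate(0.01, q), 21)
  q1 <- bioenergetics_params(assimilation_efficiency = 1,
                             food_energy_density = 3000)
  expect_equal(assimilate(0.01, q1), 30)
})

test_that("growth is additive in energy and round-trips length-mass", {
  g1 <- grow(1, 100, p)
  g2 <- grow(grow(1, 50, p)$mass, 50, p)
  expect_equal(g1$mass, g2$mass)
  expect_equal(grow(1, 0, p)$mass, 1)
  expect_equal(mass_from_length(length_from_mass(1.234, p), p), 1.234,
               tolerance = 1e-9)
  expect_equal(g1$length, length_from_mass(g1$mass, p))
})

test_that("energy allocation balances exactly in simple cases", {
  tref <- p$reference_temperature
  m <- maintenance_cost(1, tref, p)
  # assimilation exactly covers maintenance: nothing else happens
  a <- allocate_energy(1, 100, 0, m, tref, p)
  expect_equal(a$reproduction, 0)
  expect_equal(a$growth, 0)
  expect_equal(a$storage_delta, 0)
  expect_false(a$starved)
  # nothing assimilated, ample reserves: maintenance drawn from storage
  a2 <- allocate_energy(1, 1000, 0, 0, tref, p)
  expect_equal(a2$storage_delta, -m)
  expect_equal(a2$maintenance, m)
  expect_false(a2$starved)
  # reserves short of maintenance: deficit recorded, fish flagged
  a3 <- allocate_energy(1, 10, 0, 0, tref, p)
  expect_true(a3$starved)
  expect_equal(a3$deficit, m - 10)
  expect_equal(a3$maintenance, 10)
  expect_equal(a3$storage_delta, -10)
})

test_that("surplus beyond all caps is discarded but the ledger balances", {
  tref <- p$reference_temperature
  res0 <- reserve_capacity(1, p)  # start at capacity
  a <- allocate_energy(1, res0, 0, 1e6, tref, p)
  expect_gt(a$overflow, 0)
  expect_equal(a$assimilated,
               a$maintenance + a$reproduction + a$growth +
                 a$storage_delta + a$overflow,
               tolerance = 1e-9)
  # growth respects the asymptotic size
  expect_lte(a$mass, mass_from_length(p$max_length, p) + 1e-12)
})

test_that("allocation ledger identity holds over random states", {
  set.seed(77)
  for (i in 1:200) {
    n <- sample(1:8, 1)
    mass <- stats::runif(n, 0.01, 2.2)
    reserves <- stats::runif(n) * reserve_capacity(mass, p)
    gonad <- stats::runif(n, 0, 500)
    assim <- stats::runif(n, 0, 400)
    temp <- stats::runif(1, 1, 28)
    a <- allocate_energy(mass, reserves, gonad, assim, temp, p,
                         repro_active = stats::runif(n) < 0.5)
    expect_equal(a$assimilated,
                 a$maintenance + a$reproduction + a$growth +
                   a$storage_delta + a$overflow,
                 tolerance = 1e-9)
    expect_true(all(a$reserves >= -1e-12))
    expect_true(all(a$reserves <= reserve_capacity(a$mass, p) + 1e-9))
    expect_true(all(a$mass >= mass))
  }
})
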