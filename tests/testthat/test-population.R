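p <- bioenergetics_params()

make_pop <- function(n, landscape, stage = 4L, mass = 1, sex = NULL) {
  pop <- sticklesim:::new_population(n)
  pop$id <- seq_len(n)
  pop$sex <- if (is.null(sex)) rep(c(1L, 2L), length.out = n) else
    rep(sex, length.out = n)
  pop$age <- rep(400, n)
  pop$stage <- rep(stage, n)
  pop$mass <- rep(mass, n)
  pop$length <- length_from_mass(pop$mass, p)
  pop$reserves <- 0.5 * reserve_capacity(pop$mass, p)
  pop$patch <- rep(landscape$vegetated_idx[1], n)
  pop$days_since_spawn <- rep(p$clutch_interval, n)
  pop
}

test_that("population initialisation is reproducible and well-formed", {
  ls <- init_landscape(seed = 1)
  set.seed(5); a <- init_population(40, ls, p)
  set.seed(5); b <- init_population(40, ls, p)
  expect_identical(a, b)
  expect_true(all(a$mass > 0))
  expect_true(all(a$patch %in% ls$vegetated_idx))
  expect_true(all(a$stage %in% c(3L, 4L)))
  expect_equal(mass_from_length(a$length, p), a$mass, tolerance = 0.01)
  expect_equal(sticklesim:::pop_size(init_population(0, ls, p)), 0L)
})

test_that("equal-food movement balances occupancy across patches", {
  geom <- system_geometry(area = 2, n_patches = 50L, vegetated_ratio = 0.2,
                          grid_dim = c(10L, 5L))
  set.seed(3)
  ls <- renew_food(init_landscape(geom), 0.02)
  pop <- make_pop(33, ls)
  pop <- move_ifd(pop, ls)
  occ <- tabulate(match(pop$patch, ls$vegetated_idx), 10)
  expect_lte(diff(range(occ)), 1)
  expect_equal(sum(occ), 33)
})

test_that("two-patch movement reproduces input matching (closed form)", {
  geom <- system_geometry(area = 1, n_patches = 2L, vegetated_ratio = 1,
                          grid_dim = c(2L, 1L))
  for (split in list(c(1, 1), c(2, 1), c(3, 1))) {
    set.seed(11)
    ls <- init_landscape(geom)
    ls$food <- split / sum(split) * 0.5
    pop <- make_pop(100, ls)
    pop <- move_ifd(pop, ls)
    occ <- tabulate(match(pop$patch, ls$vegetated_idx), 2)
    expected <- ifd_expected_occupancy(100, ls$food)
    expect_lte(max(abs(occ - expected)), 1)
  }
})

test_that("all mobile fish pile onto a single food-bearing patch", {
  geom <- system_geometry(area = 1, n_patches = 4L, vegetated_ratio = 0.5,
                          grid_dim = c(2L, 2L))
  set.seed(4)
  ls <- init_landscape(geom)
  ls$food[ls$vegetated_idx] <- c(0.5, 0)
  pop <- make_pop(10, ls)
  pop <- move_ifd(pop, ls)
  expect_true(all(pop$patch == ls$vegetated_idx[1]))
})

test_that("territorial males are capped by vegetated patch count", {
  geom <- system_geometry(area = 1, n_patches = 10L, vegetated_ratio = 0.2,
                          grid_dim = c(5L, 2L))
  set.seed(21)
  ls <- init_landscape(geom)
  pop <- make_pop(7, ls, sex = 1L)  # 7 adult males, 2 nest sites
  day <- p$breeding_season[1]
  out <- attempt_breeding(pop, ls, day, p)
  expect_equal(sum(out$pop$territorial), 2L)
  expect_equal(out$eggs_laid, 0L)  # no females
  # out of season nothing happens and territories clear
  out2 <- attempt_breeding(out$pop, ls, p$breeding_season[2] + 1, p)
  expect_equal(sum(out2$pop$territorial), 0L)
  # no vegetated patches, no spawnings
  bare <- init_landscape(system_geometry(area = 1, n_patches = 10L,
                                         vegetated_ratio = 0,
                                         grid_dim = c(5L, 2L)))
  out3 <- attempt_breeding(make_pop(4, ls), bare, day, p)
  expect_equal(out3$n_spawns, 0L)
})

test_that("spawning pays the clutch cost and lays eggs on the nest", {
  set.seed(31)
  ls <- init_landscape(seed = 31)
  pop <- make_pop(2, ls, sex = c(1L, 2L))
  pop$gonad[2] <- 1e4  # ample gonad
  day <- p$breeding_season[1]
  out <- attempt_breeding(pop, ls, day, p)
  expect_equal(out$n_spawns, 1L)
  eggs_expected <- round(p$fecundity_coeff * 1)
  expect_equal(out$eggs_laid, eggs_expected)
  npop <- out$pop
  expect_equal(sticklesim:::pop_size(npop), 2L + eggs_expected)
  laid <- npop$stage == sticklesim:::STAGE_EGG
  expect_true(all(npop$patch[laid] == npop$patch[npop$territorial][1]))
  cost <- eggs_expected * p$egg_mass * p$tissue_energy_density
  expect_equal(npop$gonad[2], 1e4 - cost)
  expect_equal(npop$days_since_spawn[2], 0)
  # same seed, same schedule
  set.seed(31)
  ls2 <- init_landscape(seed = 31)
  pop2 <- make_pop(2, ls2, sex = c(1L, 2L)); pop2$gonad[2] <- 1e4
  out2 <- attempt_breeding(pop2, ls2, day, p)
  expect_identical(out2$pop$patch, out$pop$patch)
})

test_that("development completes after the temperature-scaled duration", {
  ls <- init_landscape(seed = 2)
  tref <- p$reference_temperature
  egg <- sticklesim:::new_population(1L)
  egg$id <- 1L; egg$sex <- 1L; egg$stage <- 1L; egg$mass <- p$egg_mass
  egg$patch <- ls$vegetated_idx[1]
  # at the reference temperature an egg hatches after exactly its base duration
  pop <- egg
  for (d in seq_len(p$egg_duration_days - 1)) pop <- develop_offspring(pop, tref, p)
  expect_equal(pop$stage, 1L)
  pop <- develop_offspring(pop, tref, p)
  expect_equal(pop$stage, 2L)
  # 10 degrees warmer with Q10 2 above CT_opt is not doubled; test below CT_opt
  q <- bioenergetics_params(thermal_window = c(0, 28, 32))
  pop2 <- egg
  ndays <- ceiling(p$egg_duration_days / 2)
  for (d in seq_len(ndays)) pop2 <- develop_offspring(pop2, tref + 10, q)
  expect_equal(pop2$stage, 2L)
  # no development at or below CT_min
  pop3 <- develop_offspring(egg, p$thermal_window[1], p)
  expect_equal(pop3$develop, 0)
  # metamorphosis draws a positive juvenile mass
  set.seed(9)
  larva <- egg; larva$stage <- 2L
  for (d in seq_len(p$larva_duration_days)) larva <- develop_offspring(larva, tref, p)
  expect_equal(larva$stage, 3L)
  expect_gt(larva$mass, 0)
})

test_that("mortality honours its deterministic and stochastic rules", {
  ls <- init_landscape(seed = 2)
  pop <- make_pop(30, ls)
  # no background mortality, no density penalty: everyone survives
  m0 <- mortality_params(m_egg = 0, m_larva = 0, m_juvenile = 0,
                         m_adult = 0, gamma = 0, max_age_days = Inf)
  set.seed(1)
  expect_equal(sticklesim:::pop_size(apply_mortality(pop, m0, 20)), 30L)
  # starved fish die regardless of draws
  pop$starved[1:5] <- TRUE
  set.seed(1)
  expect_equal(sticklesim:::pop_size(apply_mortality(pop, m0, 20)), 25L)
  # fish over the maximum age die
  m_age <- mortality_params(m_egg = 0, m_larva = 0, m_juvenile = 0,
                            m_adult = 0, gamma = 0)
  pop2 <- make_pop(10, ls)
  pop2$age[1:3] <- 4000
  set.seed(1)
  expect_equal(sticklesim:::pop_size(apply_mortality(pop2, m_age, 20)), 7L)
})

test_that("survivor counts match the closed-form mean (Monte Carlo)", {
  ls <- init_landscape(seed = 2)
  n <- 100L
  mort <- mortality_params(m_adult = 0.02, gamma = 0.01, max_age_days = Inf)
  area <- 20
  p_surv <- (1 - 0.02) / (1 + 0.01 * n / area)
  set.seed(123)
  survivors <- replicate(200, {
    pop <- make_pop(n, ls)
    sticklesim:::pop_size(apply_mortality(pop, mort, area))
  })
  se <- sqrt(n * p_surv * (1 - p_surv)) / sqrt(200)
  expect_lt(abs(mean(survivors) - n * p_surv), 3 * se)
})
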