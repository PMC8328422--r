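test_that("temperature series honour mean, SD, seed and degenerate SD", {
  params <- generative_params()
  t1 <- generate_temperature(2003:2015, params, seed = 1)
  t2 <- generate_temperature(2003:2015, params, seed = 1)
  expect_identical(t1, t2)
  expect_false(identical(
    t1$temperature_c,
    generate_temperature(2003:2015, params, seed = 2)$temperature_c))

  # long series: sample mean/SD close to the configured 12.0 +/- 0.7 (sea)
  long <- generate_temperature(1:4000, params, seed = 3)
  sea <- long$temperature_c[long$environment == "sea"]
  expect_equal(mean(sea), 12.0, tolerance = 0.01)
  expect_equal(sd(sea), 0.7, tolerance = 0.05)

  flat <- generative_params(temperature_sd = c(sea = 0, freshwater = 0))
  tc <- generate_temperature(2003:2015, flat, seed = 4)
  expect_equal(unique(tc$temperature_c[tc$environment == "freshwater"]),
               9.1)
})

test_that("year effects carry the planted temperature correlation", {
  params <- generative_params()
  years <- 1:10000
  temp <- generate_temperature(years, params, seed = 5)
  eff <- generate_year_effects(years, params, temp, seed = 6)

  wild_sea <- eff[eff$group == "wild" & eff$environment == "sea", ]
  sea_t <- temp$temperature_c[temp$environment == "sea"]
  expect_equal(cor(wild_sea$effect, sea_t), 0.41, tolerance = 0.03)
  expect_equal(sd(wild_sea$effect), params$sigma_year, tolerance = 0.01)
  expect_equal(mean(wild_sea$effect), 0, tolerance = 0.01)

  # rho = 1 makes effects an affine function of temperature
  perfect <- generative_params(
    rho = tibble::tibble(group = "wild", environment = "sea", rho = 1))
  e1 <- generate_year_effects(2003:2015, perfect, temp, seed = 7)
  fitl <- lm(e1$effect ~ sea_t[match(e1$year, years)])
  expect_lt(max(abs(residuals(fitl))), 1e-10)

  # rho = 0 decouples
  null <- generative_params(
    rho = tibble::tibble(group = "wild", environment = "sea", rho = 0))
  e0 <- generate_year_effects(years, null, temp, seed = 8)
  expect_lt(abs(cor(e0$effect, sea_t)), 0.05)
})

test_that("cohort generation is seed-deterministic and seed-sensitive", {
  cfg <- cohort_config(n_fish = 60)
  params <- generative_params()
  a <- generate_cohort(cfg, params, seed = 10)
  b <- generate_cohort(cfg, params, seed = 10)
  expect_identical(a$dataset$increments, b$dataset$increments)
  c <- generate_cohort(cfg, params, seed = 11)
  expect_false(identical(a$dataset$increments$width_um,
                         c$dataset$increments$width_um))
})

test_that("zero variances collapse same-cell widths to a point mass", {
  params <- generative_params(sigma_obs = 1e-12, sigma_fish = 1e-12,
                              sigma_year = 1e-12)
  sim <- generate_cohort(cohort_config(n_fish = 120), params, seed = 12)
  inc <- prepare_dataset(sim$dataset)$increments
  grp <- sim$dataset$fish$group[match(inc$fish_id,
                                      sim$dataset$fish$fish_id)]
  spread <- tapply(log(inc$width_um), paste(grp, inc$age_class),
                   function(v) diff(range(v)))
  expect_lt(max(spread), 1e-8)
})

test_that("generated medians match the generative fixed effects", {
  sim <- generate_cohort(cohort_config(n_fish = 3000),
                         generative_params(), seed = 13)
  inc <- prepare_dataset(sim$dataset)$increments
  grp <- sim$dataset$fish$group[match(inc$fish_id,
                                      sim$dataset$fish$fish_id)]
  med <- function(g, ac) median(inc$width_um[grp == g &
                                               inc$age_class == ac])
  expect_equal(med("hatchery", "FW1"), exp(6.70), tolerance = 0.03)
  expect_equal(med("hatchery", "SW1"), exp(6.70 + 0.61), tolerance = 0.03)
  expect_equal(med("wild", "SW1"), exp(6.70 + 0.61 - 0.39 + 0.53),
               tolerance = 0.03)
})

test_that("cohort composition follows the configured probabilities", {
  sim <- generate_cohort(cohort_config(n_fish = 4000),
                         generative_params(), seed = 14)
  fish <- sim$dataset$fish
  ages <- parse_age_code(fish$age_code)
  expect_equal(mean(ages$fw_age == 1), 0.899, tolerance = 0.02)
  expect_equal(mean(ages$sw_age == 1), 0.630, tolerance = 0.03)
  expect_equal(mean(fish$group == "wild"), 449 / 1596, tolerance = 0.03)
  expect_equal(mean(fish$repeat_spawner), 0.107, tolerance = 0.02)
  # every generated dataset satisfies the structural invariants
  expect_silent(validate_trout_dataset(sim$dataset))
})
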