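test_that("monthly aggregation averages the requested window", {
  monthly <- tidyr::expand_grid(environment = "sea", year = 2004:2005,
                                month = 1:12)
  monthly$temperature_c <- rep(c(rep(8, 6), rep(14, 6)), 2)
  ann <- aggregate_monthly(monthly, months = 1:12)
  expect_equal(ann$temperature_c, c(11, 11))
  jul_dec <- aggregate_monthly(monthly, months = 7:12)
  expect_equal(jul_dec$temperature_c, c(14, 14))

  gap <- monthly[!(monthly$year == 2005 & monthly$month == 11), ]
  expect_warning(out <- aggregate_monthly(gap, months = 7:12), "missing")
  expect_true(is.na(out$temperature_c[out$year == 2005]))
  expect_false(out$complete[out$year == 2005])
  expect_error(aggregate_monthly(monthly, months = integer(0)), "empty")
})

test_that("degenerate posteriors reduce the Monte Carlo test to plain
           Pearson correlation", {
  years <- 2003:2015
  chron_mean <- sin(seq_along(years))
  draws <- matrix(chron_mean, 500, length(years), byrow = TRUE)
  colnames(draws) <- years
  temp <- tibble::tibble(year = years,
                         temperature_c = chron_mean * 0.5 + rnorm(13, 0, .2))
  mc <- monte_carlo_correlation(draws, temp, n_draws = 400, seed = 1)
  r_naive <- cor(chron_mean, temp$temperature_c)
  expect_equal(unique(mc$r), r_naive)
  expect_equal(mc$mean_r, r_naive)
  expect_equal(unname(diff(mc$ci)), 0)
})

test_that("mean correlation approaches 1 as posterior noise vanishes when
           temperature equals the chronology", {
  years <- 2003:2015
  base <- scale(cos(seq_along(years)))[, 1]
  temp <- tibble::tibble(year = years, temperature_c = base)
  r_at_noise <- vapply(c(1, 0.3, 0.01), function(s) {
    set.seed(10)
    draws <- matrix(rep(base, each = 300), 300) +
      matrix(rnorm(300 * 13, 0, s), 300)
    colnames(draws) <- years
    monte_carlo_correlation(draws, temp, n_draws = 300, seed = 2)$mean_r
  }, numeric(1))
  expect_true(all(diff(r_at_noise) > 0))
  expect_gt(r_at_noise[3], 0.99)
})

test_that("planted temperature coupling is recovered over a long span and
           subsampling is seed-deterministic", {
  params <- generative_params(
    rho = tibble::tibble(group = "wild", environment = "sea", rho = 0.41))
  years <- 1:600
  temp <- generate_temperature(years, params, seed = 3)
  eff <- generate_year_effects(years, params, temp, seed = 4)
  truth <- eff$effect
  set.seed(5)
  draws <- matrix(rep(truth, each = 400), 400) +
    matrix(rnorm(400 * length(truth), 0, 0.01), 400)
  colnames(draws) <- years
  sea <- temp[temp$environment == "sea", ]
  mc1 <- monte_carlo_correlation(draws, sea, n_draws = 200, seed = 6)
  # sampling error of r over 600 years is about 1/sqrt(600) ~ 0.04
  expect_lt(abs(mc1$mean_r - 0.41), 0.09)
  mc2 <- monte_carlo_correlation(draws, sea, n_draws = 200, seed = 6)
  expect_identical(mc1$r, mc2$r)
})

test_that("short overlaps and flat temperature series are rejected", {
  draws <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, 2004:2005))
  temp <- tibble::tibble(year = 2004:2005, temperature_c = c(10, 11))
  expect_error(monte_carlo_correlation(draws, temp), "3 overlapping")
  draws3 <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, 2004:2006))
  flat <- tibble::tibble(year = 2004:2006, temperature_c = rep(10, 3))
  expect_error(monte_carlo_correlation(draws3, flat), "zero variance")
})

test_that("propagating posterior uncertainty is more conservative than
           the naive two-step test under a null coupling", {
  # mini-model per replicate: true year effects independent of temperature;
  # "posterior" draws from a conjugate normal-normal update of noisily
  # observed cell means. The regime of interest is the one biochronologies
  # live in: per-year posterior uncertainty comparable to or larger than
  # the between-year spread, which is when point-summary ("naive") testing
  # overstates the evidence.
  set.seed(77)
  n_years <- 13
  n_rep <- 150
  obs_sd <- 0.12
  naive_reject <- logical(n_rep)
  mc_reject <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    truth <- rnorm(n_years, 0, 0.065)
    obs <- truth + rnorm(n_years, 0, obs_sd)
    post_prec <- 1 / 0.065^2 + 1 / obs_sd^2
    post_mean <- (obs / obs_sd^2) / post_prec
    draws <- matrix(rep(post_mean, each = 300), 300) +
      matrix(rnorm(300 * n_years, 0, sqrt(1 / post_prec)), 300)
    colnames(draws) <- 2003:2015
    temp <- tibble::tibble(year = 2003:2015, temperature_c = rnorm(n_years))
    naive_reject[i] <- cor.test(post_mean,
                                temp$temperature_c)$p.value < 0.05
    mc <- monte_carlo_correlation(draws, temp, n_draws = 300, seed = i)
    mc_reject[i] <- mc$important
  }
  expect_lt(mean(mc_reject), mean(naive_reject) + 1e-9)
  expect_lte(mean(mc_reject), 0.05)
})

test_that("the per-stratum report carries intervals and importance flags", {
  years <- 2003:2015
  mk <- function(r_target, seed) {
    set.seed(seed)
    base <- rnorm(13)
    temp <- tibble::tibble(year = years, temperature_c = base)
    draws <- matrix(rep(base * r_target, each = 100), 100) +
      matrix(rnorm(1300, 0, 1 - abs(r_target) + 0.05), 100)
    colnames(draws) <- years
    monte_carlo_correlation(draws, temp, n_draws = 100, seed = seed)
  }
  res <- list("wild:sea" = mk(0.95, 1), "hatchery:sea" = mk(0.3, 2),
              "wild:freshwater" = mk(0.2, 3),
              "hatchery:freshwater" = mk(0, 4))
  tab <- correlation_report(res)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$group[1], "wild")
  expect_equal(tab$environment[1], "sea")
  # a tight positive stratum is important; intervals straddling 0 are not
  expect_true(tab$important[tab$label == "wild:sea"])
  has_zero <- tab$ci_low < 0 & tab$ci_high > 0
  expect_equal(tab$important, !has_zero)
  p <- plot_correlations(res)
  expect_s3_class(p, "ggplot")
})
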