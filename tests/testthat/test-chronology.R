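fx <- small_prepared_cohort(n_fish = 400, seed = 77)
fit <- suppressWarnings(
  fit_growth_model(fx$ds, growth_model_spec(), draws = 600, burnin = 200,
                   seed = 5))

test_that("chronology summaries are consistent with the draw matrix", {
  chron <- extract_chronology(fit)
  draws <- attr(chron, "draws")
  expect_equal(nrow(chron), ncol(draws))
  expect_equal(chron$mean, unname(colMeans(draws)))
  expect_equal(chron$q2.5,
               unname(apply(draws, 2, quantile, 0.025)))
  # approximately Gaussian posteriors: mean tracks median
  med <- apply(draws, 2, median)
  expect_lt(max(abs(chron$mean - med)), 0.02)
  # one entry per observed group x environment x year cell
  expect_false(any(duplicated(chron[, c("group", "environment", "year")])))
})

test_that("extracted chronologies recover planted year effects", {
  chron <- extract_chronology(fit)
  eff <- fx$sim$year_effects
  key <- paste(eff$group, eff$environment, eff$year)
  planted <- eff$effect[match(paste(chron$group, chron$environment,
                                    chron$year), key)]
  # weight to well-observed cells: correlation over all cells
  expect_gt(cor(chron$mean, planted), 0.8)
})

test_that("variance partition reproduces the analytic shares", {
  # identity on posterior-mean SDs: sigma_k^2 over the three-way total
  vp <- variance_partition(c(obs = 0.155, fish = 0.058, year = 0.065))
  expect_equal(round(vp$percent[vp$component == "year"]), 13)
  expect_equal(round(vp$percent[vp$component == "fish"]), 11)
  expect_equal(sum(vp$percent), 100)

  eq <- variance_partition(c(obs = 0.3, fish = 0.3, year = 0.3))
  expect_equal(eq$percent, rep(100 / 3, 3))

  solo <- variance_partition(c(obs = 0.2, fish = 0, year = 0))
  expect_equal(solo$percent, c(100, 0, 0))

  # shares invariant to joint rescaling of the response
  sc <- variance_partition(c(obs = 0.155, fish = 0.058, year = 0.065) * 7)
  expect_equal(sc$percent, vp$percent)
})

test_that("plasticity F test equals the hand-computed variance ratio", {
  h <- c(-0.1, 0.0, 0.1)
  w <- c(-0.4, 0.1, 0.3)
  pt <- fish_plasticity_test(c(h, w), c(rep("hatchery", 3), rep("wild", 3)))
  expect_equal(pt$f, var(h) / var(w))
  expect_equal(pt$df, c(2L, 2L))
  p_hand <- 2 * min(pf(var(h) / var(w), 2, 2),
                    1 - pf(var(h) / var(w), 2, 2))
  expect_equal(pt$p_value, p_hand)
})

test_that("swapping group labels inverts the F statistic and the dfs", {
  set.seed(31)
  x <- rnorm(50)
  g <- rep(c("hatchery", "wild"), 25)
  a <- fish_plasticity_test(x, g)
  b <- fish_plasticity_test(x, ifelse(g == "wild", "hatchery", "wild"))
  expect_equal(b$f, 1 / a$f)
  expect_equal(b$df, rev(a$df))
  expect_equal(b$p_value, a$p_value)
})

test_that("null intercept distributions give F near 1, unequal spread the
           planted ratio", {
  set.seed(41)
  f_null <- replicate(200, {
    x <- rnorm(60)
    fish_plasticity_test(x, rep(c("hatchery", "wild"), 30))$p_value
  })
  # p-values roughly uniform under the null
  expect_gt(ks.test(f_null, "punif")$p.value, 0.01)

  s <- 0.06
  x <- c(rnorm(1147, 0, sqrt(0.41) * s), rnorm(449, 0, s))
  pt <- fish_plasticity_test(x, c(rep("hatchery", 1147),
                                  rep("wild", 449)))
  expect_equal(pt$df, c(1146L, 448L))
  expect_equal(pt$f, 0.41, tolerance = 0.2)
  expect_lt(pt$p_value, 0.001)
})

test_that("groups with fewer than two fish are rejected", {
  expect_error(fish_plasticity_test(c(0.1, 0.2, 0.3),
                                    c("wild", "wild", "hatchery")),
               "at least 2")
})
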