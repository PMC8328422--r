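fx <- small_prepared_cohort(n_fish = 80, seed = 21)

test_that("frozen-variance posterior means match the mixed-model
           equations solution", {
  ds <- fx$ds
  spec <- growth_model_spec(prior_obs = prior_fixed(0.155),
                            prior_fish = prior_fixed(0.058),
                            prior_year = prior_fixed(0.065))
  dn <- build_design(ds, spec)
  oracle <- mme_oracle(dn, 0.155, 0.058, 0.065)
  fit <- suppressWarnings(
    fit_growth_model(dn, draws = 4000, burnin = 50, seed = 2))
  est <- colMeans(cbind(fit$beta, fit$u_fish, fit$u_year))
  # with variances fixed the draws are iid normal around the MME solution;
  # agreement is limited only by Monte Carlo error
  mc_se <- apply(cbind(fit$beta, fit$u_fish, fit$u_year), 2, sd) /
    sqrt(4000)
  expect_lt(max(abs(est - oracle) / (mc_se + 1e-12)), 5)
  expect_lt(max(abs(est - oracle)), 0.02)
  # SD draws stay exactly at their frozen values
  expect_equal(unique(fit$sigma[, "obs"]), 0.155)
  expect_equal(unique(fit$sigma[, "fish"]), 0.058)
})

test_that("identical seed and configuration reproduce draws bit for bit", {
  ds <- fx$ds
  f1 <- suppressWarnings(fit_growth_model(ds, growth_model_spec(),
                                          draws = 150, burnin = 50,
                                          seed = 33))
  f2 <- suppressWarnings(fit_growth_model(ds, growth_model_spec(),
                                          draws = 150, burnin = 50,
                                          seed = 33))
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$sigma, f2$sigma)
  f3 <- suppressWarnings(fit_growth_model(ds, growth_model_spec(),
                                          draws = 150, burnin = 50,
                                          seed = 34))
  expect_false(identical(f1$beta, f3$beta))
})

test_that("rescaling all widths shifts only the intercept, by log(c)", {
  ds <- fx$ds
  scaled <- ds
  scaled$increments$width_um <- ds$increments$width_um * 10
  f1 <- suppressWarnings(fit_growth_model(ds, growth_model_spec(),
                                          draws = 400, burnin = 150,
                                          seed = 8))
  f2 <- suppressWarnings(fit_growth_model(scaled, growth_model_spec(),
                                          draws = 400, burnin = 150,
                                          seed = 8))
  b1 <- colMeans(f1$beta)
  b2 <- colMeans(f2$beta)
  expect_equal(b2[["(Intercept)"]] - b1[["(Intercept)"]], log(10),
               tolerance = 0.01)
  expect_lt(max(abs(b2[-1] - b1[-1])), 0.05)
  expect_equal(mean(f2$sigma[, "obs"]), mean(f1$sigma[, "obs"]),
               tolerance = 0.01)
})

test_that("a random term with no levels collapses to prior-only draws", {
  ds <- fx$ds
  spec <- growth_model_spec(fish_intercept = FALSE)
  fit <- suppressWarnings(fit_growth_model(ds, spec, draws = 800,
                                           burnin = 100, seed = 4))
  expect_equal(ncol(fit$u_fish), 0)
  # sigma_fish is then sampled from its PC prior: Exp(rate 4.605)
  expect_equal(mean(fit$sigma[, "fish"]), 1 / 4.6052, tolerance = 0.05)
})

test_that("credible intervals cover the generative fixed effects at
           roughly the nominal rate", {
  params <- generative_params()
  truth <- params$beta
  # identifiable cells only; SW3-by-wild is often empty at this size
  check <- setdiff(names(truth), c("age_classSW3",
                                   "age_classSW3:groupwild"))
  hits <- 0; total <- 0; fits <- 0
  for (rep in 1:20) {
    sim <- generate_cohort(cohort_config(n_fish = 120), params,
                           seed = 100 + rep)
    ds <- prepare_dataset(sim$dataset)
    # a few SW3 fish may all share one group, making the SW3 contrasts
    # collinear; such degenerate replicates are skipped
    fit <- tryCatch(
      suppressWarnings(
        fit_growth_model(ds, growth_model_spec(), draws = 400,
                         burnin = 150, seed = 200 + rep)),
      error = function(e) NULL)
    if (is.null(fit)) next
    fits <- fits + 1
    q <- apply(fit$beta, 2, quantile, c(0.025, 0.975))
    for (nm in intersect(check, colnames(fit$beta))) {
      total <- total + 1
      if (truth[[nm]] >= q[1, nm] && truth[[nm]] <= q[2, nm]) {
        hits <- hits + 1
      }
    }
  }
  expect_gte(fits, 15)
  coverage <- hits / total
  # binomial 99% band around 0.95 for ~160 checks
  expect_gte(coverage, 0.89)
  expect_lte(coverage, 1.0)
})
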