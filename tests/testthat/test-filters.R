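test_that("rare-life-history exclusion removes exactly the listed codes", {
  # field-sample composition: 1,603 fish of which 3 x 2.0+, 3 x 2.3+,
  # 1 x 3.1+ carry rare histories
  codes <- c(rep("1.1+", 1400), rep("1.2+", 196),
             rep("2.0+", 3), rep("2.3+", 3), "3.1+")
  ds <- skeleton_dataset(codes)
  out <- exclude_rare_life_histories(ds)
  expect_equal(nrow(out$fish), 1596)
  expect_equal(out$provenance$rows_removed, 7L)

  unchanged <- exclude_rare_life_histories(ds, character(0))
  expect_equal(nrow(unchanged$fish), 1603)

  small <- skeleton_dataset(c(rep("2.0+", 4), rep("1.1+", 6)))
  out2 <- exclude_rare_life_histories(small)
  expect_equal(nrow(out2$fish), 6)
  expect_equal(out2$provenance$rows_removed, 4L)
})

test_that("marginal and spawning zones are removed with logged fractions", {
  n <- 1000
  ids <- sprintf("F%04d", seq_len(n))
  fish <- tibble::tibble(
    fish_id = ids, group = "wild", sex = "female", capture_year = 2010L,
    age_code = "1.1+", fork_length_cm = 60, scale_radius_um = 3300,
    circulus_count = 100L, repeat_spawner = FALSE)
  inc <- tibble::tibble(
    fish_id = ids, increment_index = 1L, age_class = "SW1",
    width_um = 1500,
    is_marginal = c(rep(TRUE, 287), rep(FALSE, 713)),
    is_spawning_zone = c(rep(FALSE, 287), rep(TRUE, 30), rep(FALSE, 683)))
  ds <- trout_dataset(fish, inc)
  out <- filter_increments(ds)
  expect_equal(nrow(out$increments), 683)
  prov <- out$provenance
  expect_equal(prov$fraction_of_increments[prov$rule == "marginal_zone"],
               0.287)
  expect_equal(prov$fraction_of_increments[prov$rule == "spawning_zone"],
               0.030)
})

test_that("zone filtering keeps completed non-spawning zones only", {
  ds <- tiny_dataset()
  out <- filter_increments(ds)
  a <- out$increments[out$increments$fish_id == "A", ]
  expect_equal(a$age_class, c("FW1", "SW1"))
  # spawning-eroded zone of a repeat spawner is dropped too
  ds2 <- ds
  ds2$increments$is_spawning_zone[6] <- TRUE  # fish B, SW2
  b <- filter_increments(ds2)$increments
  expect_equal(b$age_class[b$fish_id == "B"], c("FW1", "SW1"))
})

test_that("filtering is idempotent and provenance conserves row counts", {
  sim <- generate_cohort(cohort_config(n_fish = 80), generative_params(),
                         seed = 11)
  once <- filter_increments(sim$dataset)
  twice <- filter_increments(once)
  expect_equal(twice$increments, once$increments)
  expect_equal(nrow(sim$dataset$increments),
               nrow(once$increments) + sum(once$provenance$rows_removed))
})

test_that("growth years anchor the last completed annulus before capture", {
  ds <- tiny_dataset()
  out <- assign_growth_years(ds)
  a <- out$increments[out$increments$fish_id == "A", ]
  expect_equal(a$growth_year, c(2005L, 2006L, 2007L))  # FW1, SW1, marginal

  # 2.2+ caught 2007 reaches back to 2003; 1.1+ caught 2016 ends at 2015
  sk <- skeleton_dataset("2.2+", capture_year = 2007L)
  sk$increments <- tibble::tibble(
    fish_id = "S0001", increment_index = 1:5,
    age_class = c("FW1", "FW2", "SW1", "SW2", "SW3"),
    width_um = c(450, 600, 1700, 1400, 700),
    is_marginal = c(rep(FALSE, 4), TRUE),
    is_spawning_zone = rep(FALSE, 5))
  sk$increments$environment <- age_class_environment(sk$increments$age_class)
  expect_equal(assign_growth_years(sk)$increments$growth_year[1], 2003L)

  late <- tiny_dataset()
  late$fish$capture_year <- c(2016L, 2016L)
  gy <- assign_growth_years(late)$increments
  expect_equal(gy$growth_year[gy$fish_id == "A" & gy$age_class == "SW1"],
               2015L)
})

test_that("completed-zone years of a study-window cohort span 2003-2015", {
  sim <- generate_cohort(cohort_config(n_fish = 600), generative_params(),
                         seed = 5)
  ds <- prepare_dataset(sim$dataset)
  expect_gte(min(ds$increments$growth_year), 2003)
  expect_lte(max(ds$increments$growth_year), 2015)
})

test_that("non-contiguous increment indices are rejected", {
  ds <- tiny_dataset()
  ds$increments$increment_index[2] <- 5L
  expect_error(assign_growth_years(ds), "non-contiguous")
})
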