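# Fixtures built in code; no data files.

# Minimal hand-written dataset: two fish, fully controlled zones.
tiny_dataset <- function() {
  fish <- tibble::tibble(
    fish_id = c("A", "B"),
    group = c("hatchery", "wild"),
    sex = c("female", "male"),
    capture_year = c(2007L, 2010L),
    age_code = c("1.1+", "1.2+"),
    fork_length_cm = c(55, 62),
    scale_radius_um = c(3100, 3600),
    circulus_count = c(95L, 104L),
    repeat_spawner = c(FALSE, FALSE))
  increments <- tibble::tibble(
    fish_id = c("A", "A", "A", "B", "B", "B", "B"),
    increment_index = c(1L, 2L, 3L, 1L, 2L, 3L, 4L),
    age_class = c("FW1", "SW1", "SW2", "FW1", "SW1", "SW2", "SW3"),
    width_um = c(800, 1500, 700, 450, 1700, 1400, 600),
    is_marginal = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE),
    is_spawning_zone = rep(FALSE, 7))
  trout_dataset(fish, increments)
}

# One-line-per-fish skeleton dataset with given age codes (for filter-count
# worked examples); every fish gets a single FW1 zone.
skeleton_dataset <- function(age_codes, capture_year = 2010L) {
  n <- length(age_codes)
  ids <- sprintf("S%04d", seq_len(n))
  fish <- tibble::tibble(
    fish_id = ids, group = rep("wild", n), sex = rep("female", n),
    capture_year = rep(capture_year, n), age_code = age_codes,
    fork_length_cm = rep(60, n), scale_radius_um = rep(3300, n),
    circulus_count = rep(100L, n), repeat_spawner = rep(FALSE, n))
  increments <- tibble::tibble(
    fish_id = ids, increment_index = rep(1L, n),
    age_class = rep("FW1", n), width_um = rep(800, n),
    is_marginal = rep(FALSE, n), is_spawning_zone = rep(FALSE, n))
  trout_dataset(fish, increments)
}

# Small simulated cohort, filtered and ready for fitting.
small_prepared_cohort <- function(n_fish = 150, seed = 42,
                                  params = generative_params()) {
  sim <- generate_cohort(cohort_config(n_fish = n_fish), params, seed)
  list(sim = sim, ds = prepare_dataset(sim$dataset))
}

# Dense-algebra oracle for the mixed-model normal equations: posterior /
# BLUP mean of (beta, u) with all variance components frozen. Independent
# of the sampler: base-R linear algebra on the densified design.
mme_oracle <- function(design, sigma_obs, sigma_fish, sigma_year,
                       fixed_effect_sd = 100) {
  W <- as.matrix(design$W)
  prec <- c(rep(1 / fixed_effect_sd^2, design$p),
            rep(1 / sigma_fish^2, design$nf),
            rep(1 / sigma_year^2, design$ny))
  A <- crossprod(W) / sigma_obs^2 + diag(prec)
  b <- crossprod(W, design$y) / sigma_obs^2
  drop(solve(A, b))
}

draw_sigma_for_test <- function(SS, k, prior) {
  scalechron:::draw_sigma(0.5, SS, k, prior)
}

# Subset a chronology to one stratum, keeping the draw matrix aligned.
chronology_stratum <- function(chron, group, environment) {
  keep <- chron$group == group & chron$environment == environment
  sub <- chron[keep, ]
  attr(sub, "draws") <- attr(chron, "draws")[, keep, drop = FALSE]
  class(sub) <- class(chron)
  sub
}
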