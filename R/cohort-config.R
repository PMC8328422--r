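#' Configuration of a synthetic sea-trout cohort
#'
#' Defaults reproduce the composition of a southern-Baltic sea-trout
#' spawning-run sample: 1,596 fish caught 2007-2016, 89.9% FW1 smolts,
#' sea ages 63.0/35.1/1.9% (SW1/SW2/SW3), 10.7% repeat spawners, 1,249:347
#' female:male, and a hatchery:wild split of 1,147:449.
#'
#' @param n_fish number of fish.
#' @param p_wild proportion of wild (non-fin-clipped) fish.
#' @param p_fw1 proportion of fish smolting after one freshwater winter
#'   (the remainder smolt after two).
#' @param sea_age_probs named probabilities for 1-3 completed sea winters;
#'   must sum to 1.
#' @param p_repeat_spawner overall proportion of repeat spawners (fish that
#'   spawned in an earlier season; only possible with at least two sea
#'   winters, so the conditional rate is rescaled accordingly).
#' @param capture_years integer vector of capture years.
#' @param p_female proportion of females.
#' @param n_rare number of rare-life-history fish (codes 2.0+, 2.3+, 3.1+)
#'   appended on top of `n_fish`; default 0. Set to `c(3, 3, 1)` to emulate
#'   a raw field sample before rare-history exclusion.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_fish = 1596,
                          p_wild = 449 / 1596,
                          p_fw1 = 0.899,
                          sea_age_probs = c(SW1 = 0.630, SW2 = 0.351,
                                            SW3 = 0.019),
                          p_repeat_spawner = 0.107,
                          capture_years = 2007:2016,
                          p_female = 1249 / 1596,
                          n_rare = c(`2.0+` = 0, `2.3+` = 0, `3.1+` = 0)) {
  stopifnot(n_fish >= 1, p_wild >= 0, p_wild <= 1,
            p_fw1 >= 0, p_fw1 <= 1, length(sea_age_probs) == 3,
            all(sea_age_probs >= 0),
            p_repeat_spawner >= 0, p_repeat_spawner <= 1,
            length(capture_years) >= 1, p_female >= 0, p_female <= 1)
  if (abs(sum(sea_age_probs) - 1) > 1e-8) {
    stop("sea_age_probs must sum to 1", call. = FALSE)
  }
  structure(list(n_fish = as.integer(n_fish), p_wild = p_wild,
                 p_fw1 = p_fw1, sea_age_probs = sea_age_probs,
                 p_repeat_spawner = p_repeat_spawner,
                 capture_years = as.integer(capture_years),
                 p_female = p_female, n_rare = n_rare),
            class = "cohort_config")
}

#' Generative parameters of the log-normal growth model
#'
#' Fixed effects are on the natural-log micrometre scale with the hatchery
#' FW1 cell as the reference: a hatchery fish's first freshwater zone has
#' median width `exp(intercept)` (about 812 um at the default 6.70) and a
#' wild FW1-smolt's first sea zone `exp(6.70 + 0.61 - 0.39 + 0.53)`
#' (about 1,722 um). Random variation enters as a per-fish intercept
#' (`sigma_fish`), a group-by-environment-by-year intercept (`sigma_year`)
#' and residual observation noise (`sigma_obs`), all on the log scale.
#' Year effects can be coupled to the environment's temperature series with
#' stratum-specific correlations `rho`.
#'
#' @param beta named numeric vector of the ten fixed effects (intercept;
#'   FW2, SW1, SW2, SW3 age contrasts; wild-group contrast; the four
#'   age-by-group interactions).
#' @param sigma_obs,sigma_fish,sigma_year standard deviations (log scale).
#' @param rho tibble of year-effect/temperature correlations with columns
#'   `group`, `environment`, `rho`; defaults follow the correlation
#'   magnitudes typical of this system (sea growth more strongly coupled
#'   than freshwater, wild more than hatchery).
#' @param temperature_mean,temperature_sd named vectors (per environment) of
#'   yearly temperature means and SDs, degrees C. Sea values describe
#'   July-December surface means; freshwater values annual means.
#' @param marginal_fraction range of the uniform fraction of a full year's
#'   growth simulated for the (discarded) marginal plus-growth zone.
#' @param spawning_erosion range of the uniform width-retention factor for
#'   zones eroded by a spawning mark.
#' @return A list of class `generative_params`.
#' @export
generative_params <- function(
    beta = c(`(Intercept)` = 6.70,
             age_classFW2 = -0.23, age_classSW1 = 0.61,
             age_classSW2 = 0.58, age_classSW3 = 0.23,
             groupwild = -0.39,
             `age_classFW2:groupwild` = 0.32,
             `age_classSW1:groupwild` = 0.53,
             `age_classSW2:groupwild` = 0.35,
             `age_classSW3:groupwild` = 0.24),
    sigma_obs = 0.155, sigma_fish = 0.058, sigma_year = 0.065,
    rho = tibble::tibble(
      group = c("wild", "hatchery", "wild", "hatchery"),
      environment = c("sea", "sea", "freshwater", "freshwater"),
      rho = c(0.41, 0.29, 0.21, 0.05)),
    temperature_mean = c(sea = 12.0, freshwater = 9.1),
    temperature_sd = c(sea = 0.7, freshwater = 0.5),
    marginal_fraction = c(0.2, 0.8),
    spawning_erosion = c(0.5, 0.9)) {
  stopifnot(length(beta) == 10, !is.null(names(beta)),
            sigma_obs >= 0, sigma_fish >= 0, sigma_year >= 0,
            all(abs(rho$rho) <= 1),
            all(temperature_sd >= 0))
  structure(list(beta = beta, sigma_obs = sigma_obs,
                 sigma_fish = sigma_fish, sigma_year = sigma_year,
                 rho = rho, temperature_mean = temperature_mean,
                 temperature_sd = temperature_sd,
                 marginal_fraction = marginal_fraction,
                 spawning_erosion = spawning_erosion),
            class = "generative_params")
}
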