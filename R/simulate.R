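#' Simulate yearly temperature series
#'
#' Draws one value per year and environment from a normal distribution with
#' the configured long-term mean and SD, optionally with AR(1) dependence
#' (the marginal variance is held at `temperature_sd^2` regardless of the
#' autocorrelation coefficient). Two calls with the same seed are identical.
#'
#' @param years integer vector of years to cover.
#' @param params a [generative_params()].
#' @param seed integer seed.
#' @param ar1 AR(1) coefficient in `[0, 1)`; 0 (default) gives independent
#'   yearly draws.
#' @return tibble with columns `environment`, `year`, `temperature_c`.
#' @export
generate_temperature <- function(years, params, seed, ar1 = 0) {
  stopifnot(length(years) >= 1, ar1 >= 0, ar1 < 1)
  years <- sort(unique(as.integer(years)))
  set.seed(as.integer(seed))
  out <- lapply(names(params$temperature_mean), function(env) {
    m <- params$temperature_mean[[env]]
    s <- params$temperature_sd[[env]]
    z <- stats::rnorm(length(years))
    if (ar1 > 0 && length(years) > 1) {
      for (i in 2:length(z)) {
        z[i] <- ar1 * z[i - 1] + sqrt(1 - ar1^2) * z[i]
      }
    }
    tibble::tibble(environment = env, year = years,
                   temperature_c = m + s * z)
  })
  dplyr::bind_rows(out)
}

#' Simulate temperature-coupled year effects
#'
#' For each group-by-environment stratum, year effects are built as
#' `sigma_year * (rho * z_temp + sqrt(1 - rho^2) * z_noise)`, where `z_temp`
#' is the stratum environment's standardized temperature series and
#' `z_noise` independent standard normal noise, so the effects are zero-mean
#' with SD `sigma_year` and population correlation `rho` with temperature.
#'
#' @inheritParams generate_temperature
#' @param temperature tibble from [generate_temperature()] (or a real series
#'   read with [read_temperature_csv()]) covering `years`.
#' @return tibble with columns `group`, `environment`, `year`, `effect`.
#' @export
generate_year_effects <- function(years, params, temperature, seed) {
  years <- sort(unique(as.integer(years)))
  set.seed(as.integer(seed))
  out <- lapply(seq_len(nrow(params$rho)), function(i) {
    g <- params$rho$group[i]
    env <- params$rho$environment[i]
    r <- params$rho$rho[i]
    temp <- temperature[temperature$environment == env, ]
    temp <- temp[match(years, temp$year), ]
    if (any(is.na(temp$temperature_c))) {
      stop("temperature series for ", env, " does not cover all years",
           call. = FALSE)
    }
    ts <- temp$temperature_c
    z_temp <- if (stats::sd(ts) > 0) (ts - mean(ts)) / stats::sd(ts) else
      rep(0, length(ts))
    z_noise <- stats::rnorm(length(years))
    tibble::tibble(group = g, environment = env, year = years,
                   effect = params$sigma_year *
                     (r * z_temp + sqrt(1 - r^2) * z_noise))
  })
  dplyr::bind_rows(out)
}

#' Simulate a scale-increment cohort
#'
#' Generates a full pre-filtering dataset: each fish receives a life history
#' (smolt age, completed sea winters, capture year, sex, group), a fish-level
#' log-scale intercept `~ Normal(0, sigma_fish)`, and one growth zone per
#' life year with `log(width) = beta %*% x + year effect + fish effect +
#' Normal(0, sigma_obs)`. A marginal plus-growth zone (a configurable uniform
#' fraction of a full year's growth) is appended to every fish, and repeat
#' spawners carry one spawning-eroded sea zone; both are flagged so the
#' standard filters remove them. Scale radius is the sum of all zone widths;
#' fork length and circulus count are derived from it through the
#' calibration-truth relationships `FL = 17.128 + 0.013 * radius` (cm) and a
#' linear circulus-radius relation, plus noise.
#'
#' @param config a [cohort_config()].
#' @param params a [generative_params()].
#' @param seed integer seed.
#' @param temperature,year_effects optional pre-generated series; when `NULL`
#'   they are generated internally (seeds derived from `seed`) over the year
#'   span the capture window implies.
#' @return A list: `dataset` (a [trout_dataset()] with `growth_year`
#'   assigned, marginal and spawning zones still present), `temperature`,
#'   `year_effects`, and `truth` (the parameters used).
#' @export
generate_cohort <- function(config, params, seed, temperature = NULL,
                            year_effects = NULL) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(params, "generative_params"))
  # year span implied by the capture window: deepest life history is
  # fw 3 + sw 3 (rare codes included), marginal zones take the capture year
  years <- (min(config$capture_years) - 6):max(config$capture_years)
  if (is.null(temperature)) {
    temperature <- generate_temperature(years, params,
                                        seed = derive_seed(seed, 1))
  }
  if (is.null(year_effects)) {
    year_effects <- generate_year_effects(years, params, temperature,
                                          seed = derive_seed(seed, 2))
  }
  set.seed(as.integer(seed))

  n <- config$n_fish
  fw <- ifelse(stats::runif(n) < config$p_fw1, 1L, 2L)
  sw <- sample(1:3, n, replace = TRUE, prob = config$sea_age_probs)
  # rare life histories appended explicitly, if requested
  rare <- config$n_rare
  if (sum(rare) > 0) {
    codes <- rep(names(rare), rare)
    ages <- parse_age_code(codes)
    fw <- c(fw, ages$fw_age)
    sw <- c(sw, ages$sw_age)
    n <- n + sum(rare)
  }
  group <- ifelse(stats::runif(n) < config$p_wild, "wild", "hatchery")
  sex <- ifelse(stats::runif(n) < config$p_female, "female", "male")
  capture_year <- sample(config$capture_years, n, replace = TRUE)
  # repeat spawning requires >= 2 sea winters; rescale the conditional rate
  # so the overall proportion matches the configured one
  p_sw2 <- sum(config$sea_age_probs[c("SW2", "SW3")])
  p_rs <- min(1, config$p_repeat_spawner / p_sw2)
  repeat_spawner <- sw >= 2 & stats::runif(n) < p_rs
  fish_id <- sprintf("F%04d", seq_len(n))
  u_fish <- stats::rnorm(n, 0, params$sigma_fish)

  fish <- tibble::tibble(
    fish_id = fish_id, group = group, sex = sex,
    capture_year = as.integer(capture_year),
    age_code = paste0(fw, ".", sw, "+"),
    fork_length_cm = NA_real_, scale_radius_um = NA_real_,
    circulus_count = NA_integer_, repeat_spawner = repeat_spawner)

  inc <- vector("list", n)
  for (i in seq_len(n)) {
    classes <- age_class_sequence(fw[i], sw[i])
    m <- length(classes)
    # completed zone k closed in capture_year - 1 - (m - k)
    gy <- capture_year[i] - 1 - (m - seq_len(m))
    eta <- fixed_effect_predictor(classes, group[i], params$beta) + u_fish[i]
    env <- age_class_environment(classes)
    ye <- year_effect_lookup(year_effects, group[i], env, gy)
    width <- exp(eta + ye + stats::rnorm(m, 0, params$sigma_obs))
    spawning <- rep(FALSE, m)
    if (repeat_spawner[i]) {
      # one sea zone after the first spawning migration carries the mark
      cand <- which(env == "sea")[-1]
      zone <- if (length(cand) == 1) cand else sample(cand, 1)
      spawning[zone] <- TRUE
      width[zone] <- width[zone] *
        stats::runif(1, params$spawning_erosion[1],
                     params$spawning_erosion[2])
    }
    # marginal plus-growth zone at the scale edge, capture-year growth
    marg_class <- paste0("SW", min(sw[i] + 1, 3))
    if (sw[i] == 0) marg_class <- "SW1"
    marg_eta <- fixed_effect_predictor(marg_class, group[i], params$beta) +
      u_fish[i]
    marg_width <- exp(marg_eta) *
      stats::runif(1, params$marginal_fraction[1],
                   params$marginal_fraction[2])
    inc[[i]] <- tibble::tibble(
      fish_id = fish_id[i],
      increment_index = seq_len(m + 1),
      age_class = c(classes, marg_class),
      environment = c(env, "sea"),
      width_um = c(width, marg_width),
      growth_year = as.integer(c(gy, capture_year[i])),
      is_marginal = c(rep(FALSE, m), TRUE),
      is_spawning_zone = c(spawning, FALSE))
  }
  increments <- dplyr::bind_rows(inc)

  # somatic measurements derived from total scale growth
  radius <- vapply(split(increments$width_um, increments$fish_id), sum,
                   numeric(1))[fish_id]
  fish$scale_radius_um <- radius
  fish$fork_length_cm <- 17.128 + 0.013 * radius + stats::rnorm(n, 0, 3.66)
  fish$circulus_count <- pmax(
    10L, as.integer(round(27.4 + 0.022 * radius + stats::rnorm(n, 0, 6.3))))

  ds <- trout_dataset(fish, increments)
  list(dataset = ds, temperature = temperature,
       year_effects = year_effects,
       truth = list(params = params, u_fish = stats::setNames(u_fish,
                                                              fish_id)))
}

#' Simulate a complete study: cohort plus temperature series
#'
#' Thin wrapper over [generate_temperature()], [generate_year_effects()] and
#' [generate_cohort()] using seeds derived from one master seed.
#'
#' @inheritParams generate_cohort
#' @return As [generate_cohort()].
#' @export
simulate_study <- function(config = cohort_config(),
                           params = generative_params(), seed = 1) {
  generate_cohort(config, params, seed)
}

fixed_effect_predictor <- function(age_class, group, beta) {
  eta <- rep(beta[["(Intercept)"]], length(age_class))
  for (j in seq_along(age_class)) {
    ac <- age_class[j]
    if (ac != "FW1") {
      eta[j] <- eta[j] + beta[[paste0("age_class", ac)]]
    }
    if (group == "wild") {
      eta[j] <- eta[j] + beta[["groupwild"]]
      if (ac != "FW1") {
        eta[j] <- eta[j] + beta[[paste0("age_class", ac, ":groupwild")]]
      }
    }
  }
  eta
}

year_effect_lookup <- function(year_effects, group, environment, year) {
  key <- paste(year_effects$group, year_effects$environment,
               year_effects$year)
  idx <- match(paste(group, environment, year), key)
  if (any(is.na(idx))) {
    stop("year effects do not cover year(s) ",
         paste(unique(year[is.na(idx)]), collapse = ", "),
         " for ", group, "/", paste(unique(environment[is.na(idx)]),
                                    collapse = ","), call. = FALSE)
  }
  year_effects$effect[idx]
}
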