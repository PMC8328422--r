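#' Deviance information criterion of a fitted growth model
#'
#' Uses the deviance conditional on the latent effects:
#' `D(theta) = -2 log N(y | X beta + Z u, sigma_obs^2 I)`. Then
#' `pD = mean(D) - D(posterior means)` and `DIC = mean(D) + pD`. The
#' conditional (rather than marginal) likelihood focus matches the usual
#' convention for hierarchical-model DIC reported by INLA-style software;
#' pD then counts effective numbers of latent parameters.
#'
#' @param samples a `growth_posterior` from [fit_growth_model()].
#' @param design optional `growth_design`; defaults to the one stored in
#'   `samples`.
#' @return list with elements `dic`, `pD`, `mean_deviance`.
#' @export
dic <- function(samples, design = samples$design) {
  stopifnot(inherits(samples, "growth_posterior"))
  S <- nrow(samples$sigma)
  if (S < 10) stop("too few posterior draws for DIC", call. = FALSE)
  y <- design$y
  n <- design$n
  theta <- cbind(samples$beta, samples$u_fish, samples$u_year)
  eta <- as.matrix(design$W %*% t(theta))          # n x S
  sobs <- samples$sigma[, "obs"]
  ss <- colSums((y - eta)^2)
  D <- n * log(2 * pi * sobs^2) + ss / sobs^2
  eta_bar <- rowMeans(eta)
  s_bar <- mean(sobs)
  D_hat <- n * log(2 * pi * s_bar^2) + sum((y - eta_bar)^2) / s_bar^2
  mean_D <- mean(D)
  pD <- mean_D - D_hat
  list(dic = mean_D + pD, pD = pD, mean_deviance = mean_D)
}

#' Compare model terms by DIC
#'
#' Refits the model with each candidate term dropped and flags the term as
#' supported when dropping it raises the DIC by more than `threshold`
#' (default 2). All fits share the same seed policy so comparisons are
#' reproducible.
#'
#' @param ds a filtered [trout_dataset()].
#' @param base_spec the full [growth_model_spec()].
#' @param candidate_terms character vector among `"sex"`, `"interaction"`
#'   (the age-by-group interaction), `"fish"` and `"year"` (the random
#'   terms).
#' @param threshold DIC-difference support threshold.
#' @param ... passed to [fit_growth_model()] (draws, burnin, seed, ...).
#' @return tibble with columns `term`, `dic_full`, `dic_reduced`,
#'   `delta_dic`, `pD_full`, `pD_reduced`, `supported`.
#' @export
compare_terms <- function(ds, base_spec = growth_model_spec(sex = TRUE),
                          candidate_terms = c("sex", "interaction"),
                          threshold = 2, ...) {
  stopifnot(inherits(ds, "trout_dataset"))
  drop_term <- function(spec, term) {
    switch(term,
      sex = { spec$sex <- FALSE; spec },
      interaction = { spec$interaction <- FALSE; spec },
      fish = { spec$fish_intercept <- FALSE; spec },
      year = { spec$year_intercept <- FALSE; spec },
      stop("term ", sQuote(term), " is not droppable", call. = FALSE))
  }
  present <- function(spec, term) {
    switch(term, sex = spec$sex, interaction = spec$interaction,
           fish = spec$fish_intercept, year = spec$year_intercept)
  }
  full_fit <- fit_growth_model(ds, base_spec, ...)
  full_dic <- dic(full_fit)
  rows <- lapply(candidate_terms, function(term) {
    if (!present(base_spec, term)) {
      stop("term ", sQuote(term), " is absent from base_spec", call. = FALSE)
    }
    red <- tryCatch(
      fit_growth_model(ds, drop_term(base_spec, term), ...),
      error = function(e) stop("fit without term ", sQuote(term),
                               " failed: ", conditionMessage(e),
                               call. = FALSE))
    red_dic <- dic(red)
    tibble::tibble(term = term,
                   dic_full = full_dic$dic, dic_reduced = red_dic$dic,
                   delta_dic = red_dic$dic - full_dic$dic,
                   pD_full = full_dic$pD, pD_reduced = red_dic$pD,
                   supported = (red_dic$dic - full_dic$dic) > threshold)
  })
  dplyr::bind_rows(rows)
}

#' Prior sensitivity of posterior summaries
#'
#' Refits the model with each requested SD-prior family applied to all three
#' variance components and tabulates the posterior means of the fixed
#' effects and SDs, plus the maximum absolute pairwise difference per
#' parameter across families. With adequate data the fixed-effect summaries
#' should be essentially prior-invariant; on very small datasets the SD
#' posteriors legitimately differ (the prior dominates).
#'
#' @param ds a filtered [trout_dataset()].
#' @param spec a [growth_model_spec()] supplying everything but the priors.
#' @param families named list of [sd_priors] objects, e.g.
#'   `list(pc = prior_pc(), half_cauchy = prior_half_cauchy(),
#'   inv_gamma = prior_inv_gamma())`.
#' @param ... passed to [fit_growth_model()].
#' @return tibble with columns `family`, `parameter`, `mean`, `sd`; the
#'   attribute `max_abs_diff` holds a per-parameter tibble of the largest
#'   pairwise difference in posterior means.
#' @export
prior_sensitivity <- function(ds, spec = growth_model_spec(),
                              families = list(
                                pc = prior_pc(),
                                half_cauchy = prior_half_cauchy(),
                                inv_gamma = prior_inv_gamma()), ...) {
  stopifnot(length(families) >= 1)
  rows <- lapply(names(families), function(nm) {
    sp <- spec
    sp$prior_obs <- families[[nm]]
    sp$prior_fish <- families[[nm]]
    sp$prior_year <- families[[nm]]
    fit <- fit_growth_model(ds, sp, ...)
    s <- summary(fit)
    tibble::tibble(family = nm, parameter = s$parameter, mean = s$mean,
                   sd = s$sd)
  })
  out <- dplyr::bind_rows(rows)
  spread <- out |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(max_abs_diff = max(.data$mean) - min(.data$mean),
                     .groups = "drop")
  attr(out, "max_abs_diff") <- spread
  out
}
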