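#' Specify the growth model structure
#'
#' Defines the fixed and random structure of the Gaussian mixed model for
#' log increment width: age class (FW1 reference) and fish group (hatchery
#' reference) as fixed effects with an optional age-by-group interaction and
#' optional sex term; a random intercept per fish and a random intercept per
#' group-by-environment-by-year cell; and one SD prior per variance
#' component. Fixed effects get independent zero-mean normal priors with a
#' large SD (default 100 on the log scale).
#'
#' @param interaction include the age-by-group interaction (default `TRUE`).
#' @param sex include a sex fixed effect (default `FALSE`; support for it is
#'   typically tested with [compare_terms()] and the term dropped).
#' @param fish_intercept,year_intercept include the random terms.
#' @param prior_obs,prior_fish,prior_year SD priors (see [sd_priors]); PC
#'   priors with `U = 1`, `alpha = 0.01` by default.
#' @param fixed_effect_sd SD of the normal prior on fixed effects.
#' @return A list of class `growth_model_spec`.
#' @export
growth_model_spec <- function(interaction = TRUE, sex = FALSE,
                              fish_intercept = TRUE, year_intercept = TRUE,
                              prior_obs = prior_pc(),
                              prior_fish = prior_pc(),
                              prior_year = prior_pc(),
                              fixed_effect_sd = 100) {
  stopifnot(inherits(prior_obs, "sd_prior"),
            inherits(prior_fish, "sd_prior"),
            inherits(prior_year, "sd_prior"), fixed_effect_sd > 0)
  structure(list(interaction = interaction, sex = sex,
                 fish_intercept = fish_intercept,
                 year_intercept = year_intercept,
                 prior_obs = prior_obs, prior_fish = prior_fish,
                 prior_year = prior_year,
                 fixed_effect_sd = fixed_effect_sd),
            class = "growth_model_spec")
}

AGE_CLASS_LEVELS <- c("FW1", "FW2", "SW1", "SW2", "SW3")

#' Build the model design from a filtered dataset
#'
#' Constructs the response (natural-log increment width), the fixed-effect
#' design matrix (treatment coding, FW1 and hatchery as references), and the
#' random-effect index maps: every increment points to one fish and one
#' group-by-environment-by-year cell. Unused age classes are dropped from
#' the coding, so small datasets stay full rank.
#'
#' @param ds a filtered [trout_dataset()] with `growth_year` assigned (see
#'   [prepare_dataset()]).
#' @param spec a [growth_model_spec()].
#' @return A list of class `growth_design`: `y`, `X`, `fish_index`,
#'   `fish_levels`, `fish_groups`, `year_index`, `year_cells` (tibble with
#'   `group`, `environment`, `year`), and the sparse combined matrix `W`.
#' @export
build_design <- function(ds, spec = growth_model_spec()) {
  inc <- ds$increments
  if (nrow(inc) == 0) stop("no increments in dataset", call. = FALSE)
  if (any(inc$is_marginal) || any(inc$is_spawning_zone)) {
    stop("dataset still contains marginal or spawning zones; ",
         "run filter_increments() first", call. = FALSE)
  }
  if (!"growth_year" %in% names(inc)) {
    stop("increments lack growth_year; run assign_growth_years() first",
         call. = FALSE)
  }
  bad <- !inc$age_class %in% AGE_CLASS_LEVELS
  if (any(bad)) {
    stop("unknown age_class: ",
         paste(unique(inc$age_class[bad]), collapse = ", "), call. = FALSE)
  }
  if (any(inc$width_um <= 0)) stop("non-positive width", call. = FALSE)

  fi <- match(inc$fish_id, ds$fish$fish_id)
  dat <- data.frame(
    age_class = factor(inc$age_class,
                       levels = intersect(AGE_CLASS_LEVELS,
                                          unique(inc$age_class))),
    group = factor(ds$fish$group[fi], levels = c("hatchery", "wild")),
    sex = factor(ds$fish$sex[fi]))
  form <- if (spec$interaction) ~ age_class * group else ~ age_class + group
  if (spec$sex && nlevels(droplevels(dat$sex)) > 1) {
    form <- stats::update(form, ~ . + sex)
  }
  X <- stats::model.matrix(form, dat)
  y <- log(inc$width_um)

  fish_levels <- unique(inc$fish_id)
  fish_index <- match(inc$fish_id, fish_levels)
  fish_groups <- ds$fish$group[match(fish_levels, ds$fish$fish_id)]

  cell_key <- paste(dat$group, inc$environment, inc$growth_year, sep = ":")
  cell_levels <- unique(cell_key)
  year_index <- match(cell_key, cell_levels)
  parts <- strsplit(cell_levels, ":", fixed = TRUE)
  year_cells <- tibble::tibble(
    group = vapply(parts, `[`, "", 1),
    environment = vapply(parts, `[`, "", 2),
    year = as.integer(vapply(parts, `[`, "", 3)))

  n <- length(y)
  nf <- if (spec$fish_intercept) length(fish_levels) else 0L
  ny <- if (spec$year_intercept) nrow(year_cells) else 0L
  p <- ncol(X)
  blocks <- list(Matrix::Matrix(X, sparse = TRUE))
  if (nf > 0) {
    blocks <- c(blocks, Matrix::sparseMatrix(i = seq_len(n), j = fish_index,
                                             x = 1, dims = c(n, nf)))
  }
  if (ny > 0) {
    blocks <- c(blocks, Matrix::sparseMatrix(i = seq_len(n), j = year_index,
                                             x = 1, dims = c(n, ny)))
  }
  W <- do.call(cbind, blocks)

  structure(list(y = y, X = X, W = W, n = n, p = p, nf = nf, ny = ny,
                 fish_index = fish_index, fish_levels = fish_levels,
                 fish_groups = fish_groups, year_index = year_index,
                 year_cells = year_cells, spec = spec),
            class = "growth_design")
}
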