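#' Extract growth biochronologies from the posterior
#'
#' Summarises the group-by-environment-by-year random intercepts into growth
#' chronologies: per cell, the posterior mean, SD and quantiles of the year
#' effect, which represent the systematic deviation of that stratum-year's
#' growth from the stratum average. The full draw matrix is kept attached
#' so downstream Monte Carlo procedures can propagate posterior uncertainty
#' rather than working from the point summaries.
#'
#' @param samples a `growth_posterior`, or a draws-by-cells matrix whose
#'   column names are `"group:environment:year"` labels (the serialized
#'   form written by the analysis pipeline).
#' @param design optional `growth_design`; defaults to the one in `samples`.
#' @return A tibble of class `chronology` with columns `group`,
#'   `environment`, `year`, `mean`, `sd`, `q2.5`, `q97.5`; the draw matrix
#'   (draws x cells) is in `attr(, "draws")`.
#' @export
extract_chronology <- function(samples, design = samples$design) {
  if (is.matrix(samples)) {
    parts <- strsplit(colnames(samples), ":", fixed = TRUE)
    stopifnot(all(lengths(parts) == 3))
    cells <- tibble::tibble(
      group = vapply(parts, `[`, "", 1),
      environment = vapply(parts, `[`, "", 2),
      year = as.integer(vapply(parts, `[`, "", 3)))
    u <- samples
  } else {
    stopifnot(inherits(samples, "growth_posterior"))
    if (is.null(samples$u_year) || ncol(samples$u_year) == 0) {
      stop("posterior contains no year random effects", call. = FALSE)
    }
    u <- samples$u_year
    cells <- design$year_cells
  }
  out <- tibble::tibble(
    group = cells$group, environment = cells$environment,
    year = cells$year,
    mean = unname(colMeans(u)),
    sd = unname(apply(u, 2, stats::sd)),
    q2.5 = unname(apply(u, 2, stats::quantile, 0.025)),
    q97.5 = unname(apply(u, 2, stats::quantile, 0.975)))
  ord <- order(out$group, out$environment, out$year)
  out <- out[ord, ]
  attr(out, "draws") <- u[, ord, drop = FALSE]
  class(out) <- c("chronology", class(out))
  out
}

#' Partition growth variance among its random sources
#'
#' Expresses each variance component (observation-level, fish-level,
#' year-level) as a percentage of their total, using the posterior means of
#' the SDs: `100 * sigma_k^2 / (sigma_obs^2 + sigma_fish^2 + sigma_year^2)`.
#' The shares are invariant to rescaling the response, since all three SDs
#' scale jointly.
#'
#' @param samples a `growth_posterior`, or a named numeric vector of SDs
#'   (`obs`, `fish`, `year`) for direct use.
#' @return tibble with columns `component`, `sd`, `percent`.
#' @export
variance_partition <- function(samples) {
  sds <- if (inherits(samples, "growth_posterior")) {
    colMeans(samples$sigma)
  } else {
    stopifnot(is.numeric(samples),
              all(c("obs", "fish", "year") %in% names(samples)))
    samples[c("obs", "fish", "year")]
  }
  v <- sds^2
  tibble::tibble(component = c("observation", "fish", "year"),
                 sd = as.numeric(sds),
                 percent = as.numeric(100 * v / sum(v)))
}

#' Wild-vs-hatchery plasticity variance-ratio test
#'
#' Compares the dispersion of individual growth levels between fish groups:
#' the variance of per-fish intercept summaries in the hatchery group over
#' that in the wild group, referred to an F distribution with
#' `(n_hatchery - 1, n_wild - 1)` degrees of freedom. A ratio below 1 means
#' hatchery-reared fish express a narrower range of individual average
#' growth than wild fish. The test runs on posterior means of the fish
#' intercepts (point summaries), so — unlike the Monte Carlo correlation
#' machinery — it does not propagate posterior uncertainty; this mildly
#' anticonservative convention is the standard two-step practice.
#'
#' @param x either a `growth_posterior` (per-fish posterior-mean intercepts
#'   and stored groups are used) or a numeric vector of per-fish intercept
#'   summaries.
#' @param groups character vector (`"wild"`/`"hatchery"`) parallel to the
#'   intercepts; ignored when `x` is a `growth_posterior`.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return list of class `plasticity_test`: `f` (hatchery/wild variance
#'   ratio), `df` (numerator, denominator), `p_value`, per-group `n` and
#'   `variance`, and `alternative`.
#' @export
fish_plasticity_test <- function(x, groups = NULL,
                                 alternative = c("two.sided", "less",
                                                 "greater")) {
  alternative <- match.arg(alternative)
  if (inherits(x, "growth_posterior")) {
    if (is.null(x$u_fish) || ncol(x$u_fish) == 0) {
      stop("posterior contains no fish random effects", call. = FALSE)
    }
    groups <- x$design$fish_groups
    x <- colMeans(x$u_fish)
  }
  stopifnot(length(x) == length(groups),
            all(groups %in% c("wild", "hatchery")))
  xh <- x[groups == "hatchery"]
  xw <- x[groups == "wild"]
  if (length(xh) < 2 || length(xw) < 2) {
    stop("each group needs at least 2 fish", call. = FALSE)
  }
  vh <- stats::var(xh)
  vw <- stats::var(xw)
  f <- vh / vw
  df1 <- length(xh) - 1L
  df2 <- length(xw) - 1L
  p_lower <- stats::pf(f, df1, df2)
  p <- switch(alternative,
              two.sided = 2 * min(p_lower, 1 - p_lower),
              less = p_lower,
              greater = 1 - p_lower)
  structure(list(f = f, df = c(df1, df2), p_value = min(p, 1),
                 n = c(hatchery = length(xh), wild = length(xw)),
                 variance = c(hatchery = vh, wild = vw),
                 alternative = alternative),
            class = "plasticity_test")
}

#' @export
print.plasticity_test <- function(x, ...) {
  cat(sprintf(paste0("Variance-ratio (hatchery/wild) test: F = %.3f ",
                     "(df = %d, %d), p = %.3g [%s]\n"),
              x$f, x$df[1], x$df[2], x$p_value, x$alternative))
  invisible(x)
}
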