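#' Validate scale measurements as somatic-growth proxies
#'
#' Ordinary least squares of fork length on scale radius (or circulus
#' count), allowing a group offset and a predictor-by-group interaction, to
#' check that scale growth tracks somatic growth equally in wild and
#' hatchery-reared fish. Also reports the reduced no-group model, whose
#' slope and intercept are the usual calibration line.
#'
#' @param fish fish tibble (from a [trout_dataset()]) with
#'   `fork_length_cm`, `group`, and the predictor column
#'   (`scale_radius_um` or `circulus_count`).
#' @param predictor `"radius"` or `"circuli"`.
#' @return list of class `calibration_fit`: `predictor`, `coefficients`
#'   (tibble: term, estimate, ci_low, ci_high, p_value), `r_squared`, `n`,
#'   `reduced` (coefficients and R-squared of the no-group model), and the
#'   underlying `lm` objects in `fit` and `fit_reduced`.
#' @export
fit_calibration <- function(fish, predictor = c("radius", "circuli")) {
  predictor <- match.arg(predictor)
  col <- switch(predictor, radius = "scale_radius_um",
                circuli = "circulus_count")
  stopifnot(all(c("fork_length_cm", "group", col) %in% names(fish)))
  d <- data.frame(fl = fish$fork_length_cm,
                  x = as.numeric(fish[[col]]),
                  group = factor(fish$group, levels = c("hatchery", "wild")))
  d <- d[stats::complete.cases(d), ]
  if (any(d$x <= 0)) stop("non-positive predictor values", call. = FALSE)
  if (nrow(d) < 5) stop("too few fish for calibration", call. = FALSE)
  fit <- stats::lm(fl ~ x * group, data = d)
  if (any(!is.finite(stats::coef(fit)))) {
    stop("degenerate (collinear) calibration design", call. = FALSE)
  }
  fit_red <- stats::lm(fl ~ x, data = d)
  coefs <- function(m) {
    s <- summary(m)$coefficients
    ci <- stats::confint(m)
    tibble::tibble(term = rownames(s), estimate = unname(s[, 1]),
                   ci_low = unname(ci[, 1]), ci_high = unname(ci[, 2]),
                   p_value = unname(s[, 4]))
  }
  structure(list(predictor = predictor,
                 coefficients = coefs(fit),
                 r_squared = summary(fit)$r.squared,
                 n = nrow(d),
                 reduced = list(coefficients = coefs(fit_red),
                                r_squared = summary(fit_red)$r.squared),
                 fit = fit, fit_reduced = fit_red),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("<calibration_fit> fork length ~ ", x$predictor, " * group, n = ",
      x$n, ", R^2 = ", round(x$r_squared, 3), "\n", sep = "")
  print(x$coefficients)
  b <- x$reduced$coefficients$estimate
  cat(sprintf("reduced model: FL = %.3f + %.4g * %s (R^2 = %.3f)\n",
              b[1], b[2], x$predictor, x$reduced$r_squared))
  invisible(x)
}

#' Compare radius and circulus count as growth proxies
#'
#' Fits both calibrations and reports which predictor explains more
#' fork-length variance.
#'
#' @inheritParams fit_calibration
#' @return tibble with one row per predictor: `predictor`, `r_squared`,
#'   `n`, `preferred`.
#' @export
compare_calibrations <- function(fish) {
  fits <- list(radius = fit_calibration(fish, "radius"),
               circuli = fit_calibration(fish, "circuli"))
  r2 <- vapply(fits, function(f) f$r_squared, 0)
  tibble::tibble(predictor = names(fits), r_squared = as.numeric(r2),
                 n = vapply(fits, function(f) f$n, 0L),
                 preferred = r2 == max(r2))
}
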