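#' Aggregate a monthly temperature table to yearly means
#'
#' Averages monthly values over a month window per year, e.g. July-December
#' for sea surface conditions or the full year for freshwater. Years with
#' any month of the window missing are flagged and returned with `NA`, with
#' a warning, so downstream correlation code can drop them explicitly.
#'
#' @param monthly tibble with columns `environment`, `year`, `month`
#'   (1-12), `temperature_c`.
#' @param months integer vector of months to average (default `7:12`).
#' @param years years to cover; default all years present.
#' @return tibble with columns `environment`, `year`, `temperature_c`,
#'   `complete`.
#' @export
aggregate_monthly <- function(monthly, months = 7:12, years = NULL) {
  if (length(months) == 0) stop("empty month window", call. = FALSE)
  stopifnot(all(months %in% 1:12),
            all(c("environment", "year", "month", "temperature_c") %in%
                  names(monthly)))
  if (is.null(years)) years <- sort(unique(monthly$year))
  sub <- monthly[monthly$month %in% months & monthly$year %in% years, ]
  out <- sub |>
    dplyr::group_by(.data$environment, .data$year) |>
    dplyr::summarise(
      temperature_c = mean(.data$temperature_c),
      complete = dplyr::n() == length(months), .groups = "drop") |>
    tidyr::complete(.data$environment, year = years,
                    fill = list(complete = FALSE))
  out$temperature_c[!out$complete] <- NA_real_
  if (any(!out$complete)) {
    warning(sum(!out$complete), " year/environment cell(s) with missing ",
            "months flagged incomplete", call. = FALSE)
  }
  out
}

#' Monte Carlo correlation between a growth chronology and temperature
#'
#' For each retained posterior draw of one stratum's year-effect vector,
#' computes the Pearson (or Spearman) correlation with the temperature
#' series over the overlapping years, together with the least-squares line
#' for plotting. Summaries are the mean correlation and the 2.5/97.5%
#' quantiles across draws; the relationship is flagged `important` when
#' that interval excludes zero. With a degenerate posterior (all draws
#' equal) the procedure reduces exactly to the classical correlation of the
#' point chronology — the naive two-step test is the zero-uncertainty
#' special case.
#'
#' @param chron_draws draws x years matrix of year effects for one stratum
#'   (columns named by year), or a `chronology` subset to a single stratum
#'   (its attached draw matrix is used).
#' @param temperature tibble with `year` and `temperature_c` for the
#'   stratum's environment.
#' @param n_draws number of posterior draws to use (default 1000);
#'   subsampled without replacement with `seed` when fewer are requested
#'   than available.
#' @param seed integer seed for the subsampling.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list of class `mc_correlation`: `r` (per-draw correlations),
#'   `mean_r`, `ci` (2.5/97.5%), `important`, `lines` (per-draw intercept
#'   and slope), `mean_line`, `years`, `n_draws`, `method`.
#' @export
monte_carlo_correlation <- function(chron_draws, temperature,
                                    n_draws = 1000, seed = 1,
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (inherits(chron_draws, "chronology")) {
    if (length(unique(paste(chron_draws$group,
                            chron_draws$environment))) != 1) {
      stop("chronology spans several strata; subset to one group/",
           "environment first", call. = FALSE)
    }
    draws <- attr(chron_draws, "draws")
    colnames(draws) <- as.character(chron_draws$year)
    chron_draws <- draws
  }
  stopifnot(is.matrix(chron_draws), !is.null(colnames(chron_draws)))
  yrs <- as.integer(colnames(chron_draws))
  temperature <- temperature[!is.na(temperature$temperature_c), ]
  common <- intersect(yrs, temperature$year)
  if (length(common) < 3) {
    stop("need at least 3 overlapping years (got ", length(common), ")",
         call. = FALSE)
  }
  temp <- temperature$temperature_c[match(common, temperature$year)]
  if (stats::sd(temp) == 0) {
    stop("temperature series has zero variance over the overlap",
         call. = FALSE)
  }
  u <- chron_draws[, match(common, yrs), drop = FALSE]
  S <- nrow(u)
  if (n_draws < S) {
    set.seed(as.integer(seed))
    u <- u[sample.int(S, n_draws), , drop = FALSE]
  }
  S <- nrow(u)
  tx <- if (method == "spearman") rank(temp) else temp
  r <- apply(u, 1, function(g) {
    gg <- if (method == "spearman") rank(g) else g
    if (stats::sd(gg) == 0) 0 else stats::cor(gg, tx)
  })
  lines <- t(apply(u, 1, function(g) {
    stats::coef(stats::lm.fit(cbind(1, temp), g))
  }))
  colnames(lines) <- c("intercept", "slope")
  mean_g <- colMeans(u)
  mean_line <- stats::coef(stats::lm.fit(cbind(1, temp), mean_g))
  ci <- stats::quantile(r, c(0.025, 0.975), names = FALSE)
  structure(list(r = r, mean_r = mean(r), ci = ci,
                 important = ci[1] > 0 || ci[2] < 0,
                 lines = tibble::as_tibble(lines),
                 mean_line = c(intercept = mean_line[1],
                               slope = mean_line[2]),
                 years = common, temperature = temp,
                 mean_chronology = mean_g,
                 n_draws = S, method = method),
            class = "mc_correlation")
}

#' Tabulate and plot Monte Carlo correlation results per stratum
#'
#' @param results named list of `mc_correlation` objects; names of the form
#'   `"group:environment"` (or any label).
#' @return `correlation_report()`: tibble with one row per stratum (`label`,
#'   `group`, `environment` when parseable, `mean_r`, `ci_low`, `ci_high`,
#'   `important`, `n_draws`).
#' @export
correlation_report <- function(results) {
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, TRUE, "mc_correlation")))
  labels <- names(results)
  if (is.null(labels)) labels <- as.character(seq_along(results))
  parts <- strsplit(labels, ":", fixed = TRUE)
  tibble::tibble(
    label = labels,
    group = vapply(parts, function(p) if (length(p) >= 2) p[1] else
      NA_character_, ""),
    environment = vapply(parts, function(p) if (length(p) >= 2) p[2] else
      NA_character_, ""),
    mean_r = vapply(results, function(x) x$mean_r, 0),
    ci_low = vapply(results, function(x) x$ci[1], 0),
    ci_high = vapply(results, function(x) x$ci[2], 0),
    important = vapply(results, function(x) x$important, TRUE),
    n_draws = vapply(results, function(x) x$n_draws, 0L))
}

#' @rdname correlation_report
#' @param max_lines number of per-draw regression lines to overlay.
#' @return `plot_correlations()`: a ggplot with one panel per stratum, the
#'   chronology points against temperature, thin per-draw fit lines and the
#'   bold mean-fit line.
#' @export
plot_correlations <- function(results, max_lines = 200) {
  rep_tbl <- correlation_report(results)
  pts <- dplyr::bind_rows(lapply(names(results), function(nm) {
    x <- results[[nm]]
    tibble::tibble(label = nm, temperature = x$temperature,
                   growth = x$mean_chronology)
  }))
  lns <- dplyr::bind_rows(lapply(names(results), function(nm) {
    x <- results[[nm]]
    l <- x$lines[seq_len(min(max_lines, nrow(x$lines))), ]
    tibble::tibble(label = nm, intercept = l$intercept, slope = l$slope)
  }))
  mn <- dplyr::bind_rows(lapply(names(results), function(nm) {
    x <- results[[nm]]
    tibble::tibble(label = nm, intercept = x$mean_line["intercept"],
                   slope = x$mean_line["slope"])
  }))
  lab <- sprintf("%s\nr = %.2f [%.2f, %.2f]", rep_tbl$label, rep_tbl$mean_r,
                 rep_tbl$ci_low, rep_tbl$ci_high)
  names(lab) <- rep_tbl$label
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$temperature,
                                    y = .data$growth)) +
    ggplot2::geom_abline(data = lns,
                         ggplot2::aes(intercept = .data$intercept,
                                      slope = .data$slope),
                         alpha = 0.05, colour = "steelblue") +
    ggplot2::geom_abline(data = mn,
                         ggplot2::aes(intercept = .data$intercept,
                                      slope = .data$slope),
                         linewidth = 1) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~label, scales = "free",
                        labeller = ggplot2::labeller(label = lab)) +
    ggplot2::labs(x = "Temperature (°C)",
                  y = "Growth chronology (year effect, log scale)") +
    ggplot2::theme_minimal()
}
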