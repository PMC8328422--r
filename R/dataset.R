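#' Construct a scale-increment analysis dataset
#'
#' Bundles a fish table and an increment table into a validated
#' `trout_dataset` object, the container every downstream stage (filtering,
#' design construction, model fitting) consumes. A provenance log records how
#' many rows each filtering rule removed, so that
#' rows-in = rows-retained + sum(rows removed per rule) always holds.
#'
#' @param fish tibble with one row per fish: `fish_id`, `group`
#'   (`"wild"`/`"hatchery"`), `sex` (`"female"`/`"male"`/`"unknown"`),
#'   `capture_year`, `age_code`, `fork_length_cm`, `scale_radius_um`,
#'   `circulus_count`, `repeat_spawner`.
#' @param increments tibble with one row per annual growth zone:
#'   `fish_id`, `increment_index` (1-based from the scale focus),
#'   `age_class` (`"FW1"`,`"FW2"`,`"SW1"`,`"SW2"`,`"SW3"`), `width_um`,
#'   `is_marginal` (the incomplete plus-growth zone at the scale edge),
#'   `is_spawning_zone` (zone eroded by a spawning event). An `environment`
#'   column is derived from `age_class` if absent; `growth_year` may be
#'   absent until [assign_growth_years()] is called.
#' @param provenance optional existing provenance tibble
#'   (`rule`, `rows_removed`, `fraction_of_increments`) to carry forward.
#' @param validate run invariant checks (default `TRUE`).
#' @return An object of class `trout_dataset`: a list with elements `fish`,
#'   `increments`, `provenance`.
#' @export
trout_dataset <- function(fish, increments, provenance = NULL,
                          validate = TRUE) {
  fish <- tibble::as_tibble(fish)
  increments <- tibble::as_tibble(increments)
  if (!"environment" %in% names(increments)) {
    increments$environment <- age_class_environment(increments$age_class)
  }
  if (is.null(provenance)) {
    provenance <- tibble::tibble(rule = character(),
                                 rows_removed = integer(),
                                 fraction_of_increments = double())
  }
  ds <- structure(list(fish = fish, increments = increments,
                       provenance = provenance),
                  class = "trout_dataset")
  if (validate) validate_trout_dataset(ds)
  ds
}

#' Validate a trout_dataset against its structural invariants
#'
#' Checks id resolution, positivity of widths and lengths, per-fish
#' increment-index contiguity, and the at-most-one-marginal-zone rule.
#' Called by [trout_dataset()]; exported so generated or hand-edited data can
#' be re-checked.
#'
#' @param ds a `trout_dataset`.
#' @return `ds`, invisibly; errors describe the first violated invariant.
#' @export
validate_trout_dataset <- function(ds) {
  fish <- ds$fish
  inc <- ds$increments
  req_fish <- c("fish_id", "group", "capture_year", "age_code")
  miss <- setdiff(req_fish, names(fish))
  if (length(miss)) stop("fish table is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  req_inc <- c("fish_id", "increment_index", "age_class", "width_um",
               "is_marginal", "is_spawning_zone")
  miss <- setdiff(req_inc, names(inc))
  if (length(miss)) stop("increment table is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(fish$fish_id)) stop("duplicated fish_id", call. = FALSE)
  if (!all(fish$group %in% c("wild", "hatchery"))) {
    stop("group must be 'wild' or 'hatchery'", call. = FALSE)
  }
  orphan <- !inc$fish_id %in% fish$fish_id
  if (any(orphan)) {
    stop("increments reference unknown fish_id: ",
         paste(unique(inc$fish_id[orphan])[1:min(3, sum(orphan))],
               collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(inc$width_um)) || any(inc$width_um <= 0)) {
    i <- which(!is.finite(inc$width_um) | inc$width_um <= 0)[1]
    stop("non-positive increment width at row ", i, " (fish ",
         inc$fish_id[i], ")", call. = FALSE)
  }
  if ("fork_length_cm" %in% names(fish) &&
      any(fish$fork_length_cm <= 0, na.rm = TRUE)) {
    stop("fork_length_cm must be positive", call. = FALSE)
  }
  if ("scale_radius_um" %in% names(fish) &&
      any(fish$scale_radius_um <= 0, na.rm = TRUE)) {
    stop("scale_radius_um must be positive", call. = FALSE)
  }
  # per fish: contiguous 1..k indices, at most one marginal zone (the last)
  by_fish <- split(inc, inc$fish_id)
  for (d in by_fish) {
    idx <- sort(d$increment_index)
    if (!identical(as.integer(idx), seq_along(idx))) {
      stop("non-contiguous increment_index for fish ", d$fish_id[1],
           call. = FALSE)
    }
    if (sum(d$is_marginal) > 1) {
      stop("more than one marginal zone for fish ", d$fish_id[1],
           call. = FALSE)
    }
  }
  if ("growth_year" %in% names(inc)) {
    cy <- fish$capture_year[match(inc$fish_id, fish$fish_id)]
    if (any(inc$growth_year > cy, na.rm = TRUE)) {
      stop("growth_year exceeds capture_year", call. = FALSE)
    }
  }
  invisible(ds)
}

#' @export
print.trout_dataset <- function(x, ...) {
  cat("<trout_dataset>\n")
  cat("  fish:      ", nrow(x$fish), " (",
      sum(x$fish$group == "wild"), " wild, ",
      sum(x$fish$group == "hatchery"), " hatchery)\n", sep = "")
  cat("  increments:", nrow(x$increments), "\n")
  if (nrow(x$provenance)) {
    cat("  filters applied:\n")
    for (i in seq_len(nrow(x$provenance))) {
      cat(sprintf("    %-28s removed %d (%.1f%%)\n",
                  x$provenance$rule[i], x$provenance$rows_removed[i],
                  100 * x$provenance$fraction_of_increments[i]))
    }
  }
  invisible(x)
}

add_provenance <- function(ds, rule, rows_removed, fraction) {
  ds$provenance <- dplyr::bind_rows(
    ds$provenance,
    tibble::tibble(rule = rule, rows_removed = as.integer(rows_removed),
                   fraction_of_increments = fraction))
  ds
}
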