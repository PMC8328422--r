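#' Read and write scale-increment datasets as CSV
#'
#' The interchange format is a pair of UTF-8, comma-separated, "."-decimal
#' CSV files with frozen column names:
#'
#' * `fish.csv`: `fish_id, group, sex, capture_year, age_code,
#'   fork_length_cm, scale_radius_um, circulus_count, repeat_spawner`
#' * `increments.csv`: `fish_id, group, sex, capture_year, age_code,
#'   increment_index, age_class, width_um, is_marginal, is_spawning_zone`
#'   (the fish-level columns are denormalised for convenience; on reading,
#'   the increment-specific columns are kept; an optional `growth_year`
#'   column round-trips when present).
#'
#' `write_increment_csv()` followed by `read_increment_csv()` is the
#' identity on all fields.
#'
#' @param fish_path,increments_path file paths.
#' @return `read_increment_csv()`: a [trout_dataset()].
#' @export
read_increment_csv <- function(fish_path, increments_path) {
  fish_cols <- readr::cols(
    fish_id = readr::col_character(),
    group = readr::col_character(),
    sex = readr::col_character(),
    capture_year = readr::col_integer(),
    age_code = readr::col_character(),
    fork_length_cm = readr::col_double(),
    scale_radius_um = readr::col_double(),
    circulus_count = readr::col_integer(),
    repeat_spawner = readr::col_logical())
  inc_cols <- readr::cols(
    fish_id = readr::col_character(),
    increment_index = readr::col_integer(),
    age_class = readr::col_character(),
    width_um = readr::col_double(),
    is_marginal = readr::col_logical(),
    is_spawning_zone = readr::col_logical(),
    .default = readr::col_guess())
  fish <- check_csv(fish_path, fish_cols, "fish")
  inc <- check_csv(increments_path, inc_cols, "increments")
  keep <- c("fish_id", "increment_index", "age_class", "environment",
            "width_um", "growth_year", "is_marginal", "is_spawning_zone")
  inc <- inc[, intersect(keep, names(inc)), drop = FALSE]
  if ("growth_year" %in% names(inc)) {
    inc$growth_year <- as.integer(inc$growth_year)
  }
  trout_dataset(fish, inc)
}

check_csv <- function(path, cols, what) {
  required <- setdiff(names(cols$cols), ".default")
  x <- readr::read_csv(path, col_types = cols, progress = FALSE,
                       show_col_types = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss)) {
    stop(what, " file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  probs <- readr::problems(x)
  if (nrow(probs)) {
    stop(what, " file ", path, ": unparseable value at row ",
         probs$row[1], ", column ", probs$col[1], " (expected ",
         probs$expected[1], ", got ", probs$actual[1], ")", call. = FALSE)
  }
  x
}

#' @rdname read_increment_csv
#' @param ds a [trout_dataset()].
#' @param dir output directory (created if needed); the two files are written
#'   as `fish.csv` and `increments.csv`.
#' @return `write_increment_csv()`: the paths written, invisibly.
#' @export
write_increment_csv <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fish_path <- file.path(dir, "fish.csv")
  inc_path <- file.path(dir, "increments.csv")
  readr::write_csv(ds$fish, fish_path, progress = FALSE)
  extra <- ds$fish[match(ds$increments$fish_id, ds$fish$fish_id),
                   c("group", "sex", "capture_year", "age_code")]
  readr::write_csv(dplyr::bind_cols(ds$increments, extra), inc_path,
                   progress = FALSE)
  invisible(c(fish = fish_path, increments = inc_path))
}

#' Read or write a yearly temperature series
#'
#' Long-format CSV with columns `environment` (`"sea"`/`"freshwater"`),
#' `year` and `temperature_c`. Sea series conventionally hold July-December
#' surface means; freshwater series annual means.
#'
#' @param path CSV file path.
#' @return A tibble with columns `environment`, `year`, `temperature_c`.
#' @export
read_temperature_csv <- function(path) {
  x <- check_csv(path, readr::cols(environment = readr::col_character(),
                                   year = readr::col_integer(),
                                   temperature_c = readr::col_double()),
                 "temperature")
  if (anyDuplicated(x[, c("environment", "year")])) {
    stop("duplicated environment/year in ", path, call. = FALSE)
  }
  x
}

#' @rdname read_temperature_csv
#' @param temperature tibble as returned by [read_temperature_csv()].
#' @export
write_temperature_csv <- function(temperature, path) {
  readr::write_csv(temperature[, c("environment", "year", "temperature_c")],
                   path, progress = FALSE)
  invisible(path)
}
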