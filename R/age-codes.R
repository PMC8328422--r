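#' Parse salmonid age codes
#'
#' Age codes follow the standard sea-trout nomenclature `"<fw>.<sw>"` with an
#' optional trailing `"+"`: the first digit is the number of freshwater
#' winters before smolting (FW age), the second the number of completed
#' post-migration sea winters (SW age), and the `"+"` flags marginal ("plus")
#' growth beyond the last annulus at capture. `"1.2+"` is a fish that smolted
#' after one freshwater winter, completed two sea winters and shows plus
#' growth.
#'
#' @param code character vector of age codes such as `"1.2+"`.
#' @return A tibble with one row per code and columns `fw_age`, `sw_age`
#'   (integers) and `plus` (logical).
#' @examples
#' parse_age_code(c("1.2+", "2.0+", "1.1"))
#' @export
parse_age_code <- function(code) {
  stopifnot(is.character(code), length(code) >= 1)
  m <- regmatches(code, regexec("^([0-9])\\.([0-9])(\\+?)$", code))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) {
    stop("malformed age code(s): ",
         paste(sQuote(code[bad]), collapse = ", "),
         call. = FALSE)
  }
  fw <- vapply(m, function(x) as.integer(x[2]), integer(1))
  sw <- vapply(m, function(x) as.integer(x[3]), integer(1))
  plus <- vapply(m, function(x) x[4] == "+", logical(1))
  if (any(fw < 1L)) {
    stop("freshwater age must be at least 1 winter (offending code(s): ",
         paste(sQuote(code[fw < 1L]), collapse = ", "), ")", call. = FALSE)
  }
  tibble::tibble(fw_age = fw, sw_age = sw, plus = plus)
}

#' Format age codes
#'
#' Inverse of [parse_age_code()]: `format_age_code(parse_age_code(x))`
#' restores `x`.
#'
#' @param ages tibble with columns `fw_age`, `sw_age`, `plus`, as returned by
#'   [parse_age_code()].
#' @return character vector of age codes.
#' @export
format_age_code <- function(ages) {
  paste0(ages$fw_age, ".", ages$sw_age, ifelse(ages$plus, "+", ""))
}

#' Sequence of age-class labels for one life history
#'
#' Expands an age code into the ordered annual growth-zone labels, freshwater
#' first: a `"1.2+"` fish has completed zones FW1, SW1, SW2 (and a marginal
#' SW+ zone at the scale edge, not listed here).
#'
#' @param fw_age,sw_age freshwater and sea ages (scalars).
#' @return character vector of age-class labels among
#'   `"FW1","FW2","FW3","SW1","SW2","SW3"`.
#' @export
age_class_sequence <- function(fw_age, sw_age) {
  c(if (fw_age > 0) paste0("FW", seq_len(fw_age)),
    if (sw_age > 0) paste0("SW", seq_len(sw_age)))
}

#' @rdname age_class_sequence
#' @param age_class character vector of age-class labels.
#' @return `age_class_environment()`: `"freshwater"` for FW classes, `"sea"`
#'   for SW classes.
#' @export
age_class_environment <- function(age_class) {
  ifelse(grepl("^FW", age_class), "freshwater",
         ifelse(grepl("^SW", age_class), "sea", NA_character_))
}
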