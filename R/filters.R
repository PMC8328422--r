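#' Exclude fish with rare life histories
#'
#' Removes fish (and all their increments) whose age code is in a configured
#' exclusion list. The default list holds the life histories too rare to
#' estimate group-by-age effects for in a typical sea-trout sample: 2.0+,
#' 2.3+ and 3.1+.
#'
#' @param ds a [trout_dataset()].
#' @param excluded_codes character vector of age codes to drop.
#' @return The filtered `trout_dataset`; removal counts are appended to the
#'   provenance log. A warning is raised if nothing remains.
#' @export
exclude_rare_life_histories <- function(ds,
                                        excluded_codes = c("2.0+", "2.3+",
                                                           "3.1+")) {
  if (length(excluded_codes)) parse_age_code(excluded_codes)  # validate
  drop <- ds$fish$age_code %in% excluded_codes
  drop_ids <- ds$fish$fish_id[drop]
  inc_drop <- ds$increments$fish_id %in% drop_ids
  n_inc <- nrow(ds$increments)
  out <- ds
  out$fish <- ds$fish[!drop, , drop = FALSE]
  out$increments <- ds$increments[!inc_drop, , drop = FALSE]
  out <- add_provenance(out, "rare_life_history_fish", sum(inc_drop),
                        if (n_inc) sum(inc_drop) / n_inc else 0)
  if (nrow(out$fish) == 0) warning("no fish remain after exclusion")
  out
}

#' Remove marginal and spawning-affected growth zones
#'
#' Marginal (plus-growth, SW+) zones are incomplete — the fish was captured
#' before the annulus formed — and zones laid down in a spawning year are
#' eroded by the spawning mark; neither represents a full year's somatic
#' growth, so both are dropped before modelling. The fractions removed are
#' logged to provenance. Idempotent: filtering twice equals filtering once.
#'
#' @param ds a [trout_dataset()].
#' @return The filtered `trout_dataset`.
#' @export
filter_increments <- function(ds) {
  inc <- ds$increments
  n0 <- nrow(inc)
  marg <- inc$is_marginal
  spawn <- !marg & inc$is_spawning_zone
  out <- ds
  out$increments <- inc[!(marg | spawn), , drop = FALSE]
  out <- add_provenance(out, "marginal_zone", sum(marg),
                        if (n0) sum(marg) / n0 else 0)
  out <- add_provenance(out, "spawning_zone", sum(spawn),
                        if (n0) sum(spawn) / n0 else 0)
  out
}

#' Assign calendar growth years to increments
#'
#' Anchors each fish's growth zones to calendar years: with `m` completed
#' (non-marginal) zones, completed zone `k` is assigned
#' `capture_year - 1 - (m - k)` and the marginal zone, when present, the
#' capture year itself. The convention reflects autumn capture after the
#' season's plus growth, so the last completed annulus closed the year before
#' capture; for captures 2007-2016 and life histories up to 2.2+ it places
#' all completed zones in 2003-2015.
#'
#' @param ds a [trout_dataset()].
#' @return The dataset with a `growth_year` column on the increments.
#' @export
assign_growth_years <- function(ds) {
  inc <- ds$increments
  cap <- ds$fish$capture_year[match(inc$fish_id, ds$fish$fish_id)]
  ord <- order(inc$fish_id, inc$increment_index)
  # completed-zone rank within fish, marginal zones excluded from the count
  inc2 <- inc[ord, , drop = FALSE]
  cap2 <- cap[ord]
  gy <- numeric(nrow(inc2))
  for (ids in split(seq_len(nrow(inc2)), inc2$fish_id)) {
    idx <- inc2$increment_index[ids]
    if (!identical(as.integer(sort(idx)), seq_along(idx))) {
      stop("non-contiguous increment_index for fish ", inc2$fish_id[ids[1]],
           call. = FALSE)
    }
    comp <- ids[!inc2$is_marginal[ids]]
    m <- length(comp)
    k <- rank(inc2$increment_index[comp])
    gy[comp] <- cap2[comp] - 1 - (m - k)
    gy[ids[inc2$is_marginal[ids]]] <- cap2[ids[inc2$is_marginal[ids]]]
  }
  inc2$growth_year <- as.integer(gy)
  out <- ds
  out$increments <- inc2[order(ord), , drop = FALSE]  # original row order
  validate_trout_dataset(out)
  out
}

#' Standard pre-model filtering pipeline
#'
#' Convenience wrapper: rare-life-history exclusion, growth-year assignment,
#' then marginal/spawning-zone removal, in that order.
#'
#' @inheritParams exclude_rare_life_histories
#' @return The filtered, calendar-anchored `trout_dataset`.
#' @export
prepare_dataset <- function(ds, excluded_codes = c("2.0+", "2.3+", "3.1+")) {
  ds |>
    exclude_rare_life_histories(excluded_codes) |>
    assign_growth_years() |>
    filter_increments()
}
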