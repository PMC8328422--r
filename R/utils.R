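#' Derive a stage seed from a master seed
#'
#' Deterministic integer hash so pipeline stages (simulation, fitting,
#' Monte Carlo subsampling) can be run standalone yet reproduce exactly the
#' seeds a full [run_pipeline()] run would use. Results stay within the
#' 32-bit signed integer range.
#'
#' @param seed master seed (integer).
#' @param stage stage index (integer).
#' @return a positive integer seed.
#' @export
derive_seed <- function(seed, stage) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(stage) * 65537
  as.integer(s %% 2147483629 + 1)
}

#' @importFrom rlang .data
NULL
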