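# Internal helpers shared across modules.

# Display rounding: half-up, as used throughout the screen summaries.
# R's round() rounds half to even, which disagrees with the conventional
# half-up rounding of published screen tables (e.g. 7716.5 -> 7717).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# Error conditions carry a class so the command-line driver can map them
# to exit codes (input/schema -> 3, computation -> 4).
stop_input <- function(...) {
  stop(structure(
    class = c("tillingr_input_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_compute <- function(...) {
  stop(structure(
    class = c("tillingr_compute_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

#' Render a mutation density as "1/X kb"
#'
#' Converts base pairs per mutation to the conventional `"1/X"` kilobase
#' rendering, with `X` rounded half-up to the nearest integer.
#'
#' @param bp_per_mutation Numeric vector, base pairs screened per detected
#'   mutation.
#' @return Character vector like `"1/37"`.
#' @examples
#' format_density(36827.4)  # "1/37"
#' @export
format_density <- function(bp_per_mutation) {
  if (any(!is.finite(bp_per_mutation) | bp_per_mutation <= 0)) {
    stop_input("bp_per_mutation must be positive and finite")
  }
  paste0("1/", round_half_up(bp_per_mutation / 1000))
}
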