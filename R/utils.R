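# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Validation helper: stop with the offending field and constraint.
check_that <- function(ok, field, constraint) {
  if (!isTRUE(ok)) {
    stop(sprintf("invalid protocol value: `%s` must satisfy: %s", field, constraint),
         call. = FALSE)
  }
  invisible(TRUE)
}

check_scalar_number <- function(x, field, lower = -Inf, upper = Inf) {
  check_that(is.numeric(x) && length(x) == 1L && is.finite(x),
             field, "a single finite number")
  check_that(x >= lower && x <= upper, field,
             sprintf("in [%s, %s]", format(lower), format(upper)))
  invisible(x)
}

check_range <- function(x, field, lower = 0) {
  check_that(is.numeric(x) && length(x) == 2L && all(is.finite(x)),
             field, "a (min, max) pair")
  check_that(x[1] > lower || (lower == 0 && x[1] >= 0), field,
             sprintf("min > %s", format(lower)))
  check_that(x[1] <= x[2], field, "min <= max")
  invisible(x)
}

#' Derive a per-session random seed from a master seed
#'
#' Deterministic seed-splitting rule used everywhere the package runs more
#' than one session from a single master seed: each (cage, day) pair gets its
#' own stream so that sessions can be re-run independently and cages never
#' share draws. The rule is `(master + 10007 * cage + 101 * day) mod (2^31 - 1)`,
#' kept within the 32-bit integer range R requires of `set.seed()`.
#'
#' @param master_seed integer master seed for the whole run.
#' @param cage_index zero-based cage index.
#' @param day_index one-based training day.
#' @return An integer seed.
#' @export
split_seed <- function(master_seed, cage_index = 0L, day_index = 1L) {
  as.integer((as.numeric(master_seed) + 10007 * cage_index + 101 * day_index) %%
               2147483647)
}
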