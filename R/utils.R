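# Internal helpers shared across modules.

#' Round half-up
#'
#' Rounds to `digits` decimal places with ties going away from zero for
#' positive values, matching the printed style of clinical cohort reports
#' (base R `round()` uses banker's rounding).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

#' Percentage with one decimal, half-up
#'
#' @param num,den numerator and denominator counts.
#' @return `100 * num / den` rounded half-up to one decimal.
#' @keywords internal
pct1 <- function(num, den) round_half_up(100 * num / den, 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with sprintf-style formatting, no call in the message
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Run code with a temporary RNG seed, restoring prior global state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Check a column is one of the allowed enum tokens; NA allowed when na_ok.
check_enum <- function(x, allowed, what, na_ok = FALSE) {
  bad <- if (na_ok) !is.na(x) & !(x %in% allowed) else !(x %in% allowed)
  if (any(bad)) {
    fail("unknown %s token: %s (allowed: %s)", what,
         paste(unique(x[bad]), collapse = ", "),
         paste(allowed, collapse = ", "))
  }
  invisible(x)
}
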