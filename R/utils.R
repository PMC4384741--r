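## Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

#' The 12 possible mismatch types
#'
#' Ordered pairs `ref>alt` over A/C/G/T with ref != alt, e.g. `"A>G"`.
#'
#' @return Character vector of length 12.
#' @export
mismatch_types <- function() {
  out <- as.vector(outer(BASES, BASES, function(r, a) paste0(r, ">", a)))
  out[substr(out, 1, 1) != substr(out, 3, 3)]
}

## Evaluate `code` under a temporary RNG state seeded with `seed`;
## the caller's RNG stream is untouched.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Derive a stream of sub-seeds from one seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Format a count ratio as a whole-number percentage
#'
#' Helper used by summary formatters and run reports, e.g.
#' `fraction_percent(16425, 87574)` is `19`.
#'
#' @param num,den Numerator and denominator counts.
#' @param digits Decimal digits to keep (default 0).
#' @return Numeric percentage.
#' @export
fraction_percent <- function(num, den, digits = 0) {
  stopifnot(den > 0)
  round(100 * num / den, digits)
}

## stop unless all conditions hold, with a compact message
check_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
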