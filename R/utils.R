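#' @keywords internal
"_PACKAGE"

## Shared internal helpers: argument checks, seeding, rounding, checksums.

stop_if <- function(cond, ...) {
  if (cond) stop(sprintf(...), call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

#' Round half away from zero
#'
#' Percentages in cohort tables are conventionally rounded half away from
#' zero (so 46.75 -> 46.8), unlike [base::round()] which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_up(c(0.125, -0.125), 2)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Derive a stage-specific RNG seed from a global seed
#'
#' Deterministic fan-out of one global integer seed into per-stage seeds, so
#' pipeline stages are reproducible yet statistically independent of one
#' another. The result always fits in a 32-bit signed integer.
#'
#' @param seed global integer seed.
#' @param stage character stage label.
#' @return a single integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stop_if(!is_count(abs(seed)), "seed must be a single integer")
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) %% 1000003L) * 2017L + h * 7919L) %% 2147483629L
}

## Evaluate expr under a local, restored RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

## md5 of a set of files, named by basename; NA entries dropped.
file_checksums <- function(paths) {
  sums <- tools::md5sum(paths)
  names(sums) <- basename(paths)
  sums[!is.na(sums)]
}
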