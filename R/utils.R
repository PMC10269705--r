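#' Round half away from zero
#'
#' Percentages in the composition and partition tables are reported to a
#' fixed number of decimals with ties rounded up (5 rounds away from zero),
#' the convention used for the printed shares this package reproduces.
#' Base `round()` rounds half to even, which disagrees on exact ties.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# stop() with a consistent prefix for user-facing argument errors
.fail <- function(...) stop(sprintf(...), call. = FALSE)

# Run expr with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards. All stochastic operations in the package go
# through this so pipelines are reproducible stage by stage.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic per-stage seed derived from a root seed; kept below 2^31.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}
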