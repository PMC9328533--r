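# x first so pmin/pmax keep dim attributes
.clip01 <- function(x) pmin(pmax(x, 0), 1)

.clip255 <- function(x) pmin(pmax(x, 0), 255)

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded library functions do not disturb user scripts.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed from a global seed; keeps every
# module independently re-runnable from one recorded integer.
# Result stays within 32-bit signed range.
derive_seed <- function(seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

.assert_scalar_num <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x > max)
    stop(sprintf("`%s` must be a single number in [%s, %s]", name,
                 format(min), format(max)), call. = FALSE)
  invisible(x)
}
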