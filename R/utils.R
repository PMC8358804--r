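## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_eq <- function(...) stop(..., call. = FALSE)

#' @noRd
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    stop_eq(sprintf("`%s` must be supplied", name))
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_eq(sprintf("`%s` must be a single finite number", name))
  if (x < lower || x > upper)
    stop_eq(sprintf("`%s` must be in [%g, %g]", name, lower, upper))
  invisible(x)
}

## Run the body under a locally-set RNG state when `seed` is given, restoring
## the caller's state afterwards so simulators never perturb user code.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive reproducible child seeds from one master seed
#'
#' A single pipeline seed fans out deterministically to per-stage (or
#' per-replicate) seeds so that stages can be re-run in isolation and still
#' reproduce the full-run stream. Children are drawn from the master seed's
#' own RNG stream and kept within the 32-bit integer range.
#'
#' @param seed master seed (integer).
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
child_seeds <- function(seed, n) {
  check_number(seed, "seed")
  check_number(n, "n", lower = 1)
  with_seed(seed, sample.int(.Machine$integer.max, n))
}
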