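#' @keywords internal
"_PACKAGE"

#' @useDynLib eegtraj, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft sd var median quantile rnorm runif approx
#'   predict glm binomial wilcox.test complete.cases setNames
#' @importFrom utils head tail write.csv read.csv
NULL

## Condition helpers: every user-facing failure carries a condition class so
## callers (and tests) can distinguish config errors from data errors.
et_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "eegtraj_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_invalid_config <- function(msg) et_stop(msg, "eegtraj_invalid_config")
stop_invalid_input <- function(msg) et_stop(msg, "eegtraj_invalid_input")
stop_insufficient_data <- function(msg) et_stop(msg, "eegtraj_insufficient_data")
stop_degenerate_input <- function(msg) et_stop(msg, "eegtraj_degenerate_input")
stop_undefined_entropy <- function(msg) et_stop(msg, "eegtraj_undefined_entropy")

## Derive a stream of child seeds from one base seed without disturbing the
## caller's RNG state more than the draw itself. Kept below 2^31 - 1.
derive_seeds <- function(seed, n) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

## Evaluate expr with a locally seeded RNG, restoring the caller's state.
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

## Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}
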