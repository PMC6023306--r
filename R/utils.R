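# condition helpers: classed errors so callers/tests can discriminate failures

stop_invalid <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("blockcor_invalid_argument", "blockcor_error")))
}

stop_data <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("blockcor_data_error", "blockcor_error")))
}

stop_budget <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("blockcor_budget_error", "blockcor_error")))
}

stop_corrupt <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("blockcor_corruption_error", "blockcor_error")))
}

#' Demote values to single precision
#'
#' Rounds each element to the nearest IEEE-754 binary32 value (via a 4-byte
#' binary round trip) while keeping the R storage mode double. Used to
#' emulate an `f32` compute pipeline: demoted operands, double accumulation.
#'
#' @param x Numeric vector, matrix or array.
#' @return Object of the same shape whose values are all exactly
#'   representable in single precision.
#' @keywords internal
#' @export
demote_single <- function(x) {
  d <- dim(x)
  y <- readBin(writeBin(as.double(x), raw(), size = 4L),
               "double", n = length(x), size = 4L)
  dim(y) <- d
  y
}

scalar_width <- function(precision) {
  switch(precision, f32 = 4L, f64 = 8L,
         stop_invalid("precision must be 'f32' or 'f64', got '%s'", precision))
}

# run `expr` with the global RNG seeded, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
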