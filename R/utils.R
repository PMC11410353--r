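`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG state
#'
#' Seeds the global RNG, evaluates `expr`, and restores the previous RNG
#' state afterwards, so seeded helpers do not disturb the caller's stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream as is.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
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

#' Derive a reproducible sub-seed from a master seed
#'
#' A fixed affine congruential map so that every randomised stage of the
#' pipeline draws from a named substream of one master seed. The result is
#' always a non-negative integer below 2^31 - 1.
#'
#' @param master Integer master seed.
#' @param index Integer substream index (0, 1, 2, ...).
#' @return An integer seed.
#' @export
#' @examples
#' derive_seed(1, 0)
#' derive_seed(1, 1)
derive_seed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1,
            is.numeric(index), length(index) == 1)
  m <- as.double(master) %% 2147483647
  as.integer((m * 48271 + as.double(index) * 104729 + 1) %% 2147483647)
}

# interval membership on a closed window, tolerant of reversed input
in_window <- function(x, window) {
  w <- sort(window[1:2])
  x >= w[1] & x <= w[2]
}
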