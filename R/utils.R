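# Small numerical helpers shared across the model, training and evaluation code.

#' Row-wise softmax with max subtraction
#'
#' Numerically stable softmax applied independently to each row of a matrix.
#' The row maximum is subtracted before exponentiation so arbitrarily large
#' scores do not overflow.
#'
#' @param x Numeric matrix.
#' @return Matrix of the same shape; every row is non-negative and sums to 1.
#' @keywords internal
softmaxRows <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds R's RNG, runs `expr`, and restores the previous RNG state so that
#' package internals never perturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @keywords internal
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a distinct 31-bit sub-seed from a base seed and a stream label.
subSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

stopifnot_scalar <- function(x, what) {
  if (length(x) != 1L || is.na(x)) stop(what, " must be a non-missing scalar", call. = FALSE)
  invisible(x)
}

AA_ALPHABET20 <- c("A","C","D","E","F","G","H","I","K","L",
                   "M","N","P","Q","R","S","T","V","W","Y")
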