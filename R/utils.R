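#' @keywords internal
"_PACKAGE"

## Moore-Penrose pseudoinverse via SVD; tol relative to largest singular value.
pinv <- function(A, tol = sqrt(.Machine$double.eps)) {
  s <- svd(A)
  keep <- s$d > tol * s$d[1L]
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

## Run code with a temporary RNG state; restores .Random.seed on exit so
## callers' random streams are untouched (independent-stream guarantee of the
## simulator rests on this).
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

## Derive a child seed from a base seed and a stream label, keeping the result
## a valid 32-bit R integer.
derive_seed <- function(seed, stream) {
  h <- digest::digest(list(as.integer(seed), as.character(stream)),
                      algo = "xxhash32")
  as.integer(strtoi(substr(h, 1L, 7L), base = 16L))
}

## Class labels to an indicator (dummy) matrix, columns in `classes` order.
class_indicator <- function(y, classes = NULL) {
  y <- as.character(y)
  if (is.null(classes)) classes <- sort(unique(y))
  Y <- matrix(0, length(y), length(classes),
              dimnames = list(NULL, classes))
  Y[cbind(seq_along(y), match(y, classes))] <- 1
  Y
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)
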