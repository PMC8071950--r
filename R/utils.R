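#' @useDynLib boostseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats lm coef rnorm runif rbinom setNames
#' @importFrom utils write.csv read.csv
NULL

# Run `code` under a temporary RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package route through this so that a
# user-level seed fully determines the output without clobbering the
# session RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_contract <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# Validate a {0,1} integer mask matrix.
assert_mask <- function(m, what = "mask") {
  if (!is.matrix(m)) stop_contract("%s must be a matrix", what)
  if (!all(m %in% c(0L, 1L))) stop_contract("%s must be strictly binary (0/1)", what)
  invisible(m)
}

assert_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) {
    stop_contract("%s have mismatched shapes: %dx%d vs %dx%d",
                  what, nrow(a), ncol(a), nrow(b), ncol(b))
  }
  invisible(NULL)
}
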