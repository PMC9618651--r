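#' @importFrom rlang abort warn %||%
#' @importFrom Rcpp sourceCpp
#' @useDynLib gaitattn, .registration = TRUE
NULL

abort_config <- function(msg) abort(msg, class = "gaitattn_error_config")
abort_shape <- function(msg) abort(msg, class = "gaitattn_error_shape")
abort_provenance <- function(msg) abort(msg, class = "gaitattn_error_provenance")
abort_numeric <- function(msg) abort(msg, class = "gaitattn_error_numeric")

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards so library code never clobbers user RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic 31-bit child seed for stream `i` of a parent seed.
derive_seed <- function(seed, i) {
  s <- (as.numeric(seed) %% 65521) * 40503 + as.numeric(i) * 2654435 + 97
  as.integer(s %% 2147483647)
}

# Numerically stable softmax over a vector.
softmax <- function(e) {
  z <- exp(e - max(e))
  z / sum(z)
}

# Row-wise stable softmax for a matrix (one distribution per row).
softmax_rows <- function(E) {
  m <- apply(E, 1L, max)
  Z <- exp(E - m)
  Z / rowSums(Z)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}
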