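#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the R random seed, evaluates `code`, and restores the previous global
#' RNG state so that library calls never perturb a user's random stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(abs(as.double(seed)) %% 2147483646))
  }
  code
}

# Deterministic stream-splitting: derive a child seed < 2^31 from a parent
# seed and an index, so every stochastic component gets its own stream.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) %% 2147483629 * 7919 + 104729 * as.double(k)) %% 2147483629)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Block-mean downsampling by an integer factor; trailing rows/columns that do
# not fill a block are dropped.
downsample_image <- function(m, f) {
  f <- as.integer(f)
  if (f <= 1L) return(m)
  h2 <- nrow(m) %/% f
  w2 <- ncol(m) %/% f
  if (h2 < 1L || w2 < 1L) stop("image too small for downsampling factor ", f)
  m <- m[seq_len(h2 * f), seq_len(w2 * f), drop = FALSE]
  tmp <- matrix(colMeans(matrix(m, nrow = f)), nrow = h2)   # h2 x (f*w2)
  tmp <- t(tmp)                                             # (f*w2) x h2
  t(matrix(colMeans(matrix(tmp, nrow = f)), nrow = w2))     # h2 x w2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
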