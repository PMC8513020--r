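#' @importFrom rlang .data
#' @importFrom stats median sd var approx fft predict rnorm runif quantile setNames
#' @importFrom utils head tail write.csv read.csv
NULL

# Deterministic sub-seed derivation: mixes a master seed with stream indices so
# participants/bouts/stages get independent, reproducible RNG streams. Kept
# below 2^31 - 1 (R integers are 32-bit).
fan_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (i in idx) {
    s <- (s * 48271 + as.double(i) * 9349 + 1) %% 2147483647
  }
  as.integer(s)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# local extrema of a numeric vector; ties broken toward the earlier sample
local_minima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] < x[1:(n - 2)] & x[2:(n - 1)] <= x[3:n]) + 1L
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
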