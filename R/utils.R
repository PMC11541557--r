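#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx coef cor dnorm lm median na.omit plogis pnorm
#'   predict pt qlogis qnorm quantile rbeta rbinom rgamma rmultinom rnorm runif sd
#'   setNames smooth.spline var filter
#' @importFrom utils head read.csv tail write.csv
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so generators stay pure functions of
# (parameters, seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
  }
  force(code)
}

# Derive a reproducible child seed below 2^31 from a parent seed and an index.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 7907 * k) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

as_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(x)
}

# Trailing-inclusive rolling sum of x with window k; entries before the first
# complete window are NA.
roll_sum <- function(x, k) {
  n <- length(x)
  if (n < k) return(rep(NA_real_, n))
  cs <- cumsum(x)
  out <- rep(NA_real_, n)
  out[k:n] <- cs[k:n] - c(0, cs[seq_len(n - k)])
  out
}
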