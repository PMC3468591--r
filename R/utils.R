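#' @keywords internal
"_PACKAGE"

#' @importFrom stats aggregate as.formula coef cor dnbinom fitted lm
#'   median optimize pchisq pf predict qnorm quantile rnbinom rnorm
#'   rpois runif sd var dist residuals setNames
#' @importFrom utils read.csv write.csv packageVersion
NULL

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Restore the caller's RNG state after running seeded code, so library
## functions don't silently disturb an enclosing simulation stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
  }
  force(code)
}

## Deterministic per-component sub-seed (Lehmer step), kept below 2^31 so it
## is always a valid R integer seed. Changing the draw count of one survey
## component then leaves the streams of the others untouched.
component_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647) * 48271 %% 2147483647 +
               9973 * k) %% 2147483647L
}

log_msg <- function(fmt, ...) message(sprintf(fmt, ...))

skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2)^1.5)
}

kurtosis <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  mean((x - m)^4) / (mean((x - m)^2)^2)
}
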