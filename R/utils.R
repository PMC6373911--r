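# Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under a temporary RNG state so library code does not
## disturb the caller's random stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## Trapezoidal integral of y(t) over the sampled grid t.
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(0)
  sum((t[-1] - t[-n]) * (y[-1] + y[-n])) / 2
}

## Centred moving average with window `width` samples (odd), edges shrink.
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width == 1L) return(x)
  half <- width %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

## One truncated-normal draw via the inverse-CDF method (consumes one
## uniform, keeping per-patient draws cheap and reproducible).
rtnorm1 <- function(mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(min(max(mean, lo), hi))
  p <- runif(1, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(p, mean, sd)
}

## djb2 string hash, returned as 8 hex digits; used for run manifests.
djb2_hash <- function(s) {
  h <- 5381
  for (b in as.integer(charToRaw(s))) h <- (h * 33 + b) %% 4294967296
  sprintf("%08x", as.integer(h %% 2147483647))
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
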