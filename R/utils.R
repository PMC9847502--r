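## Internal numerical helpers shared across modules.

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

## Hyperbolic (Michaelis-Menten / Emax) saturation; returns 0 when dose = 0.
hillSat <- function(dose, ec50) {
  ifelse(dose <= 0, 0, dose / (dose + ec50))
}

## Derive a reproducible child seed from a user seed and a stream offset,
## staying inside the 32-bit integer range.
childSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

#' Local-quadratic (Savitzky--Golay) smoothing with reflect padding
#'
#' Smooths a uniformly sampled series by least-squares fitting a quadratic in a
#' sliding window. Ends are handled by reflecting the series about its first
#' and last points, so the filter length is preserved.
#'
#' @param x numeric vector, uniformly sampled.
#' @param window odd integer window length in samples (>= 3).
#' @return numeric vector of the same length as `x`.
#' @keywords internal
#' @noRd
sgSmooth <- function(x, window = 5L) {
  n <- length(x)
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  if (window < 3L || n < 3L) return(x)
  if (window > n) window <- if (n %% 2L == 1L) n else n - 1L
  h <- (window - 1L) %/% 2L
  ts <- seq.int(-h, h)
  A <- cbind(1, ts, ts^2)
  ## central-row smoothing weights of the quadratic least-squares fit
  w <- (solve(crossprod(A)) %*% t(A))[1L, ]
  ## point reflection through the end values: preserves linear trends, so
  ## boundary derivatives of smooth series are not biased toward zero
  xp <- c(2 * x[1L] - x[(h + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - h)])
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- sum(w * xp[i:(i + window - 1L)])
  out
}

## Central-difference derivative on a (possibly non-uniform) grid; one-sided at
## the ends.
gridDeriv <- function(y, t) {
  n <- length(y)
  d <- numeric(n)
  if (n < 2L) return(d)
  d[1L] <- (y[2L] - y[1L]) / (t[2L] - t[1L])
  d[n] <- (y[n] - y[n - 1L]) / (t[n] - t[n - 1L])
  if (n > 2L) {
    i <- 2L:(n - 1L)
    d[i] <- (y[i + 1L] - y[i - 1L]) / (t[i + 1L] - t[i - 1L])
  }
  d
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
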