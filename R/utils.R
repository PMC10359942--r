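#' @import data.table
#' @importFrom stats approx cor.test dnorm median optim pnorm qnorm quantile
#'   rnorm runif sd setNames var
NULL

# Modulus for the per-cell substream hash (2^31 - 1, a Mersenne prime).
.HASH_MOD <- 2147483647

#' Derive a deterministic per-cell RNG seed
#'
#' Each simulated cell owns an independent RNG substream derived from the
#' cohort seed and the cell's lineage path (e.g. `"m12"`, `"m12.1.2"`), so
#' enlarging a cohort never reshuffles the randomness of existing cells.
#'
#' @param seed Integer cohort seed.
#' @param path Character lineage path of the cell.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @keywords internal
substream_seed <- function(seed, path) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(path) == 1L)
  h <- as.numeric(seed %% .HASH_MOD)
  for (c in utf8ToInt(path)) {
    # Horner update; intermediate values stay < 2^36, exact in doubles.
    h <- (h * 131 + c) %% .HASH_MOD
  }
  as.integer(h %% (.HASH_MOD - 2) + 1)
}

# Position the global RNG at a cell's substream. A short burn-in decorrelates
# the first draws from the seeding itself (freshly seeded Mersenne-Twister
# states are weakly biased in their first outputs across many nearby seeds).
seed_substream <- function(seed, path) {
  set.seed(substream_seed(seed, path))
  invisible(runif(10))
}

# Run `expr` under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# ---- truncated normal (lower truncation only) --------------------------------
# No truncated-distribution package is shipped with the environment, so the
# few lines needed (inverse-CDF sampler + first two moments) live here.

rtnorm <- function(n, mean, sd, lower) {
  pa <- pnorm(lower, mean, sd)
  u <- runif(n, pa, 1)
  qnorm(u, mean, sd)
}

tnorm_moments <- function(mean, sd, lower) {
  a <- (lower - mean) / sd
  z <- 1 - pnorm(a)
  lam <- dnorm(a) / z
  m <- mean + sd * lam
  v <- sd^2 * (1 + a * lam - lam^2)
  c(mean = m, sd = sqrt(v))
}

#' Moment-matched truncated-normal parameters
#'
#' Finds location/scale such that the normal truncated below at `lower` has
#' exactly the requested mean and SD. Used so that configured phase-duration
#' means are the true means of the sampled (non-negative) durations.
#'
#' @keywords internal
tnorm_match <- function(target_mean, target_sd, lower = 0.25) {
  obj <- function(p) {
    m <- tnorm_moments(p[1], exp(p[2]), lower)
    (m[["mean"]] - target_mean)^2 + (m[["sd"]] - target_sd)^2
  }
  fit <- optim(c(target_mean, log(target_sd)), obj,
               method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 2000))
  list(location = fit$par[1], scale = exp(fit$par[2]))
}

# ---- shared small numerics ---------------------------------------------------

#' Centered moving-average smoothing
#'
#' Smooths a trace with a centered moving average of odd width; near the ends
#' the window shrinks symmetrically so the output keeps the input length.
#'
#' @param values Numeric trace.
#' @param window Odd integer window width in frames (1 = identity).
#' @return Smoothed numeric vector of the same length.
#' @export
smooth_trace <- function(values, window = 5L) {
  if (length(values) == 0L) stop("empty trace")
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  n <- length(values)
  if (window == 1L || n == 1L) return(values)
  half <- window %/% 2L
  cs <- cumsum(c(0, values))
  i <- seq_len(n)
  h <- pmin(half, i - 1L, n - i)  # symmetric shrink at the ends
  lo <- i - h
  hi <- i + h
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Rolling least-squares slope over `window` frames (centered, shrunk ends).
rolling_slope <- function(values, times, window = 5L) {
  n <- length(values)
  half <- window %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    h <- min(half, i - 1L, n - i)
    idx <- (i - h):(i + h)
    if (length(idx) < 2L) {
      out[i] <- NA_real_
    } else {
      tt <- times[idx] - mean(times[idx])
      out[i] <- sum(tt * (values[idx] - mean(values[idx]))) / sum(tt^2)
    }
  }
  out
}
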