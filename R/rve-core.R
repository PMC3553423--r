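#' Sample lag from sample rate and lowpass corner
#'
#' A signal lowpassed at `fc` is fully determined at `2 * fc` samples per
#' second, so rank windows need only span every `xi`-th sample, where
#' `xi = ceiling(fs / (2 * fc))`.  This ties the embedding lag to the signal
#' bandwidth instead of leaving it as a free parameter.
#'
#' @param fs Sample rate in Hz.
#' @param fc Lowpass corner frequency in Hz; must satisfy `0 < fc <= fs / 2`.
#' @return Integer lag in samples (>= 1).
#' @examples
#' compute_lag(600, 100) # 3
#' compute_lag(600, 150) # 2
#' @export
compute_lag <- function(fs, fc) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a single positive number (Hz)")
  if (!is.numeric(fc) || length(fc) != 1L || fc <= 0)
    stop("'fc' must be a single positive number (Hz)")
  if (fc > fs / 2)
    stop("'fc' exceeds the Nyquist frequency fs/2; the band cannot be represented")
  as.integer(ceiling(fs / (2 * fc)))
}

#' Rank-encode a window of samples
#'
#' Converts `W` sample values to their integer ranks: rank 1 is assigned to
#' the largest value and rank `W` to the smallest.  Ties are broken by
#' temporal order; the earlier sample receives the smaller rank (stable
#' descending sort).  The encoding discards absolute amplitude: any
#' positive-affine transform of the window yields the same rank vector.
#'
#' @param window Numeric vector of finite values (the lagged sub-window).
#' @return Integer vector of the same length, a permutation of `1:W`.
#' @examples
#' rank_encode(c(4.07, -3.12, 3.95, 8.51, -1.21)) # 2 5 3 1 4
#' @export
rank_encode <- function(window) {
  if (!is.numeric(window) || any(!is.finite(window)))
    stop("window must be a numeric vector of finite values")
  W <- length(window)
  ord <- order(-window) # stable: ties keep temporal order
  ranks <- integer(W)
  ranks[ord] <- seq_len(W)
  ranks
}

#' Symbol index of a rank vector
#'
#' Maps a rank vector (a permutation of `1:W`) to its 1-based position in
#' the ascending lexicographic ordering of all `factorial(W)` permutations,
#' via the factoradic (Lehmer code) expansion.  The identity permutation
#' maps to 1 and the reversed permutation to `factorial(W)`.
#'
#' @param rv Integer vector, a permutation of `1:W`.
#' @return Integer symbol index in `1:factorial(W)`.
#' @examples
#' symbol_index(c(2, 5, 3, 1, 4)) # 45
#' @seealso [symbol_rank_vector()] for the inverse mapping.
#' @export
symbol_index <- function(rv) {
  W <- length(rv)
  if (!is.numeric(rv) || any(sort(rv) != seq_len(W)))
    stop("'rv' must be a permutation of 1..W")
  idx <- 0
  for (i in seq_len(W - 1L)) {
    smaller_after <- sum(rv[(i + 1L):W] < rv[i])
    idx <- idx + smaller_after * factorial(W - i)
  }
  as.integer(idx + 1L)
}

#' Rank vector for a symbol index (inverse of [symbol_index()])
#'
#' @param index Integer in `1:factorial(W)`.
#' @param W Window length.
#' @return Integer permutation of `1:W` whose lexicographic position is
#'   `index`.
#' @export
symbol_rank_vector <- function(index, W) {
  nf <- factorial(W)
  if (!is.numeric(index) || length(index) != 1L || index < 1 || index > nf)
    stop("'index' must lie in 1..factorial(W)")
  rem <- as.integer(index) - 1L
  avail <- seq_len(W)
  out <- integer(W)
  for (i in seq_len(W)) {
    f <- factorial(W - i)
    d <- rem %/% f
    rem <- rem %% f
    out[i] <- avail[d + 1L]
    avail <- avail[-(d + 1L)]
  }
  out
}

#' Histogram decay multiplier
#'
#' The per-sample multiplier `alpha = exp(-1 / (tau * fs))` implementing the
#' leaky integrator: symbol counts decay to `1/e` of their value over `tau`
#' seconds.  `tau = Inf` gives `alpha = 1` exactly (cumulative entropy over
#' the whole series).
#'
#' @param tau Decay time constant in seconds (`> 0` or `Inf`).
#' @param fs Sample rate in Hz.
#' @return The decay multiplier, a number in (0, 1].
#' @export
decay_multiplier <- function(tau, fs) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau <= 0)
    stop("'tau' must be a positive number of seconds (or Inf)")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a single positive number (Hz)")
  if (is.infinite(tau)) return(1)
  exp(-1 / (tau * fs))
}

#' Default integrator decay time
#'
#' Chooses `tau` such that the 1/e time in samples equals three times the
#' number of symbol states: `tau = 3 * factorial(W) / fs`.  This keeps the
#' histogram well populated while retaining temporal resolution.
#'
#' @param W Window length (>= 2).
#' @param fs Sample rate in Hz.
#' @return Decay time constant in seconds.
#' @examples
#' default_tau(5, 600) # 0.6
#' @export
default_tau <- function(W, fs) {
  if (!is.numeric(W) || length(W) != 1L || W < 2)
    stop("'W' must be an integer >= 2")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a single positive number (Hz)")
  3 * factorial(W) / fs
}

#' Initialize a decaying state histogram
#'
#' All `factorial(W)` counts start at 1.0, so every state probability is
#' strictly positive from the first update and the entropy begins near its
#' maximum.
#'
#' @param W Window length.
#' @param alpha Per-sample decay multiplier in (0, 1].
#' @return An object of class `state_histogram` with fields `counts`,
#'   `alpha`, `W`.
#' @export
state_histogram <- function(W, alpha = 1) {
  if (!is.numeric(W) || length(W) != 1L || W < 2 || W != round(W))
    stop("'W' must be an integer >= 2")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("'alpha' must lie in (0, 1]")
  structure(list(counts = rep(1, factorial(W)), alpha = alpha, W = as.integer(W)),
            class = "state_histogram")
}

#' Update a state histogram with one symbol
#'
#' Applies the leaky-integrator step: every count is multiplied by `alpha`
#' (decay), then the count of the observed symbol is incremented by one.
#' After the update the total mass equals `alpha * previous_mass + 1`.
#'
#' @param h A `state_histogram`.
#' @param symbol Integer symbol index in `1:factorial(W)`.
#' @return The updated `state_histogram`.
#' @export
update_histogram <- function(h, symbol) {
  stopifnot(inherits(h, "state_histogram"))
  nf <- length(h$counts)
  if (!is.numeric(symbol) || length(symbol) != 1L || symbol < 1 || symbol > nf ||
      symbol != round(symbol))
    stop("'symbol' must be an integer in 1..factorial(W)")
  h$counts <- h$counts * h$alpha
  h$counts[symbol] <- h$counts[symbol] + 1
  h
}

#' Normalized Shannon entropy of a state histogram
#'
#' Converts counts to probabilities and returns the Shannon entropy in bits
#' divided by its maximum `log2(factorial(W))`, constraining the result to
#' `[0, 1]`.  Only strictly positive probabilities contribute.
#'
#' @param h A `state_histogram`, or a bare nonnegative count vector.
#' @return Normalized entropy in `[0, 1]`.
#' @export
histogram_entropy <- function(h) {
  counts <- if (inherits(h, "state_histogram")) h$counts else h
  if (!is.numeric(counts) || any(counts < 0))
    stop("counts must be nonnegative")
  tot <- sum(counts)
  if (tot <= 0) stop("histogram has zero total mass")
  p <- counts[counts > 0] / tot
  hval <- -sum(p * log2(p)) / log2(length(counts))
  min(max(hval, 0), 1)
}

#' Rank vector entropy of a sampled signal
#'
#' Transforms a single-channel signal into a time-resolved, normalized
#' rank-vector-entropy series.  A window of `W` samples spaced `xi` apart
#' (`xi = ceiling(fs / (2 * fc))`) is advanced one raw sample at a time;
#' each window is rank-encoded, mapped to its symbol, accumulated in a
#' decaying state histogram (decay `alpha = exp(-1 / (tau * fs))` per
#' sample), and the normalized Shannon entropy of the histogram is emitted.
#' The result is amplitude-invariant: `rve(a * x + b)` is identical to
#' `rve(x)` for any `a > 0` when no ties are created.
#'
#' Each entropy value is timestamped at the most recent (trailing) sample of
#' its window.  The first `3 * tau` seconds are flagged as lead-in — the
#' histogram is still converging from its uniform initialization — but are
#' returned, not dropped.
#'
#' @param x A `sampled_signal` (single channel) or numeric vector.
#' @param fs Sample rate in Hz; ignored (taken from `x`) when `x` is a
#'   `sampled_signal`.
#' @param W Window length (number of lagged samples), between 3 and 7.
#'   `W = 5` (120 states) is the recommended compromise between state
#'   resolution and the sample count needed to populate the histogram.
#' @param fc Lowpass corner frequency in Hz defining the lag; defaults to
#'   the Nyquist frequency (lag 1).
#' @param tau Integrator decay time in seconds; `Inf` for cumulative
#'   entropy.  Default `3 * factorial(W) / fs`.
#' @return An object of class `rve`: list with `h` (entropy values in
#'   `[0, 1]`), `times` (seconds, trailing-sample convention), `fs`, `W`,
#'   `fc`, `tau`, `xi`, `alpha`, `lead_in` (seconds), and `lead_in_mask`
#'   (TRUE where the output is within the lead-in).
#' @examples
#' set.seed(1)
#' r <- rve(rnorm(6000), fs = 600, W = 4, fc = 150)
#' summary(r)
#' @export
rve <- function(x, fs = NULL, W = 5L, fc = NULL, tau = NULL) {
  if (inherits(x, "sampled_signal")) {
    fs <- x$fs
    start_time <- x$start_time
    x <- signal_vector(x)
  } else {
    if (is.null(fs)) stop("'fs' is required when 'x' is a plain vector")
    start_time <- 0
  }
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("signal values must be finite numbers")
  if (!is.numeric(W) || length(W) != 1L || W != round(W) || W < 3 || W > 7)
    stop("'W' must be an integer between 3 and 7")
  W <- as.integer(W)
  if (is.null(fc)) fc <- fs / 2
  if (is.null(tau)) tau <- default_tau(W, fs)
  xi <- compute_lag(fs, fc)
  alpha <- decay_multiplier(tau, fs)
  span <- (W - 1L) * xi + 1L
  K <- length(x)
  if (K < span)
    stop(sprintf("signal too short: need at least %d samples for W=%d, lag=%d",
                 span, W, xi))

  symbols <- window_symbols(x, W, xi)
  n_out <- length(symbols)
  nf <- factorial(W)
  log2max <- log2(nf)

  counts <- rep(1, nf)
  h <- numeric(n_out)
  for (k in seq_len(n_out)) {
    counts <- counts * alpha
    s <- symbols[k]
    counts[s] <- counts[s] + 1
    p <- counts / sum(counts)
    p <- p[p > 0]
    h[k] <- -sum(p * log2(p)) / log2max
  }
  h[h < 0] <- 0
  h[h > 1] <- 1

  times <- start_time + (seq_len(n_out) + span - 2L) / fs
  lead_in <- 3 * tau
  structure(list(h = h, times = times, fs = fs, W = W, fc = fc, tau = tau,
                 xi = xi, alpha = alpha, lead_in = lead_in,
                 lead_in_mask = times - start_time < lead_in,
                 symbols = symbols),
            class = "rve")
}

# Vectorized symbol stream: ranks by stable descending comparison counts,
# then the Lehmer code summed into a 1-based lexicographic index.
window_symbols <- function(x, W, xi) {
  span <- (W - 1L) * xi + 1L
  n <- length(x) - span + 1L
  win <- matrix(0, n, W)
  for (j in seq_len(W)) win[, j] <- x[seq_len(n) + (j - 1L) * xi]
  ranks <- matrix(1L, n, W)
  for (i in seq_len(W)) {
    for (j in seq_len(W)) {
      if (i == j) next
      if (j < i) {
        ranks[, i] <- ranks[, i] + (win[, j] > win[, i] | win[, j] == win[, i])
      } else {
        ranks[, i] <- ranks[, i] + (win[, j] > win[, i])
      }
    }
  }
  idx <- rep(0, n)
  for (i in seq_len(W - 1L)) {
    smaller_after <- rep(0L, n)
    for (j in (i + 1L):W)
      smaller_after <- smaller_after + (ranks[, j] < ranks[, i])
    idx <- idx + smaller_after * factorial(W - i)
  }
  as.integer(idx + 1)
}

#' @export
print.rve <- function(x, ...) {
  cat(sprintf("<rve> %d entropy values @ %g Hz\n", length(x$h), x$fs))
  cat(sprintf("  W = %d (%d states), fc = %g Hz, lag = %d, tau = %g s, alpha = %.6f\n",
              x$W, factorial(x$W), x$fc, x$xi, x$tau, x$alpha))
  cat(sprintf("  lead-in: %g s (%d samples flagged)\n",
              x$lead_in, sum(x$lead_in_mask)))
  invisible(x)
}

#' @export
summary.rve <- function(object, ...) {
  ok <- !object$lead_in_mask
  post <- if (any(ok)) object$h[ok] else object$h
  out <- list(n = length(object$h), n_lead_in = sum(object$lead_in_mask),
              W = object$W, xi = object$xi, tau = object$tau,
              mean = mean(post), sd = stats::sd(post),
              range = range(post),
              mode = if (length(post) >= 100) rve_mode(post) else NA_real_)
  class(out) <- "summary.rve"
  out
}

#' @export
print.summary.rve <- function(x, ...) {
  cat(sprintf("Rank vector entropy: %d values (%d in lead-in)\n", x$n, x$n_lead_in))
  cat(sprintf("  W = %d, lag = %d, tau = %g s\n", x$W, x$xi, x$tau))
  cat(sprintf("  post lead-in: mean %.4f, sd %.4f, range [%.4f, %.4f]",
              x$mean, x$sd, x$range[1], x$range[2]))
  if (!is.na(x$mode)) cat(sprintf(", mode %.4f", x$mode))
  cat("\n")
  invisible(x)
}

#' @export
plot.rve <- function(x, shade_lead_in = TRUE, ...) {
  graphics::plot(x$times, x$h, type = "l", xlab = "time (s)",
                 ylab = "normalized entropy h", ylim = c(0, 1), ...)
  if (shade_lead_in && any(x$lead_in_mask)) {
    t_end <- max(x$times[x$lead_in_mask])
    graphics::rect(min(x$times), 0, t_end, 1,
                   col = grDevices::adjustcolor("grey", 0.3), border = NA)
  }
  invisible(x)
}

#' @export
as.data.frame.rve <- function(x, ...) {
  data.frame(time = x$times, h = x$h, lead_in = x$lead_in_mask)
}
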