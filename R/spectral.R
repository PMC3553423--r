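#' Define a frequency band
#'
#' @param low,high Band edges in Hz, `0 < low < high`.
#' @param name Optional label (e.g. "alpha").
#' @return Object of class `band_definition`.
#' @export
band_definition <- function(low, high, name = sprintf("%g-%g Hz", low, high)) {
  if (!is.numeric(low) || !is.numeric(high) || length(low) != 1L ||
      length(high) != 1L || low <= 0 || high <= low)
    stop("need 0 < low < high (Hz)")
  structure(list(name = name, low = low, high = high),
            class = "band_definition")
}

#' Canonical electrophysiology bands
#'
#' theta 4-8, alpha 8-13, beta 15-30, low gamma 35-70, high gamma
#' 70-150 Hz, plus the broadband 4-150 Hz used for entropy analysis.
#'
#' @return Named list of `band_definition`s.
#' @export
standard_bands <- function() {
  list(broadband = band_definition(4, 150, "broadband"),
       theta = band_definition(4, 8, "theta"),
       alpha = band_definition(8, 13, "alpha"),
       beta = band_definition(15, 30, "beta"),
       low_gamma = band_definition(35, 70, "low gamma"),
       high_gamma = band_definition(70, 150, "high gamma"))
}

check_band <- function(band, fs) {
  stopifnot(inherits(band, "band_definition"))
  if (band$high > fs / 2)
    stop(sprintf("band %s exceeds the Nyquist frequency %g Hz",
                 band$name, fs / 2))
  invisible(band)
}

#' Zero-phase bandpass filter
#'
#' Forward-backward (zero group delay) Butterworth bandpass of the given
#' order, applied per channel.  The effective magnitude response is the
#' squared single-pass response.
#'
#' @param x A `sampled_signal` or numeric vector.
#' @param band A `band_definition`.
#' @param fs Sample rate, required when `x` is a vector.
#' @param order Butterworth order per pass (default 4).
#' @return Filtered signal of the same class and shape as the input.
#' @export
bandpass <- function(x, band, fs = NULL, order = 4) {
  is_sig <- inherits(x, "sampled_signal")
  if (is_sig) fs <- x$fs
  if (is.null(fs)) stop("'fs' required when 'x' is a plain vector")
  check_band(band, fs)
  wn <- c(band$low, band$high) / (fs / 2)
  wn[2] <- min(wn[2], 0.999)
  bf <- signal::butter(order, wn, type = "pass")
  filt1 <- function(v) as.numeric(signal::filtfilt(bf, v))
  if (is_sig) {
    out <- apply(x$values, 2L, filt1)
    if (!is.matrix(out)) out <- matrix(out, ncol = ncol(x$values))
    sampled_signal(out, fs = fs, start_time = x$start_time,
                   channel_names = colnames(x$values))
  } else {
    filt1(x)
  }
}

# analytic signal via the frequency-domain construction
analytic_signal <- function(v) {
  n <- length(v)
  Xf <- stats::fft(v)
  hmul <- numeric(n)
  if (n %% 2 == 0) {
    hmul[c(1, n / 2 + 1)] <- 1
    hmul[2:(n / 2)] <- 2
  } else {
    hmul[1] <- 1
    hmul[2:((n + 1) / 2)] <- 2
  }
  stats::fft(Xf * hmul, inverse = TRUE) / n
}

#' Smoothed Hilbert-envelope power
#'
#' Bandpasses the signal, computes the squared magnitude of its analytic
#' signal (instantaneous power), and smooths the result with a zero-phase
#' lowpass at the band's upper corner frequency (configurable via
#' `smooth_fc`).  The first and last `3 / low` seconds are edge-affected by
#' the filters; `edge_mask` flags them.
#'
#' @inheritParams bandpass
#' @param smooth_fc Lowpass corner for envelope smoothing in Hz; default
#'   the band's upper corner.  `NA` disables smoothing.
#' @return A single-channel `sampled_signal` of power (input units squared)
#'   with an `edge_mask` attribute, or a numeric vector when `x` is one.
#' @export
hilbert_envelope_power <- function(x, band, fs = NULL, order = 4,
                                   smooth_fc = band$high) {
  is_sig <- inherits(x, "sampled_signal")
  if (is_sig) fs <- x$fs
  if (is.null(fs)) stop("'fs' required when 'x' is a plain vector")
  v <- if (is_sig) signal_vector(x) else x
  bp <- bandpass(v, band, fs = fs, order = order)
  pw <- Mod(analytic_signal(bp))^2
  if (!is.na(smooth_fc)) {
    wn <- min(smooth_fc / (fs / 2), 0.999)
    lp <- signal::butter(order, wn, type = "low")
    pw <- as.numeric(signal::filtfilt(lp, pw))
    pw[pw < 0] <- 0 # filter ringing can slightly undershoot zero
  }
  n_edge <- min(length(pw), ceiling(3 / band$low * fs))
  mask <- rep(FALSE, length(pw))
  mask[seq_len(n_edge)] <- TRUE
  mask[seq.int(length(pw) - n_edge + 1L, length(pw))] <- TRUE
  if (is_sig) {
    out <- sampled_signal(pw, fs = fs, start_time = x$start_time,
                          channel_names = paste0("power_", band$name))
    attr(out, "edge_mask") <- mask
    out
  } else {
    attr(pw, "edge_mask") <- mask
    pw
  }
}
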