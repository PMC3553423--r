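#' Construct a uniformly sampled signal
#'
#' A `sampled_signal` bundles one or more channels of uniformly sampled data
#' with the sample rate and start time, the common currency of all analysis
#' functions in this package.
#'
#' @param values Numeric vector (one channel) or matrix with samples in rows
#'   and channels in columns.
#' @param fs Sample rate in Hz. Must be positive.
#' @param start_time Time of the first sample in seconds (default 0).
#' @param channel_names Optional character vector of channel labels; defaults
#'   to existing column names or `"ch1"`, `"ch2"`, ...
#' @return An object of class `sampled_signal`: a list with elements
#'   `values` (samples x channels matrix), `fs`, `start_time`.
#' @examples
#' x <- sampled_signal(sin(2 * pi * 10 * (0:599) / 600), fs = 600)
#' x
#' @export
sampled_signal <- function(values, fs, start_time = 0, channel_names = NULL) {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a single positive number (Hz)")
  if (is.vector(values)) values <- matrix(values, ncol = 1L)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric vector or matrix (samples x channels)")
  if (nrow(values) < 1L) stop("signal must contain at least one sample")
  if (any(!is.finite(values))) stop("signal values must be finite")
  if (is.null(channel_names)) {
    channel_names <- colnames(values)
    if (is.null(channel_names))
      channel_names <- paste0("ch", seq_len(ncol(values)))
  }
  if (length(channel_names) != ncol(values))
    stop("'channel_names' length must match the number of channels")
  colnames(values) <- channel_names
  structure(list(values = values, fs = fs, start_time = start_time),
            class = "sampled_signal")
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal> %d channel(s) x %d samples @ %g Hz (%.3f s)\n",
              ncol(x$values), nrow(x$values), x$fs, nrow(x$values) / x$fs))
  invisible(x)
}

#' @export
length.sampled_signal <- function(x) nrow(x$values)

#' Sample times of a signal
#'
#' @param x A `sampled_signal`.
#' @return Numeric vector of sample times in seconds.
#' @export
signal_times <- function(x) {
  stopifnot(inherits(x, "sampled_signal"))
  x$start_time + (seq_len(nrow(x$values)) - 1L) / x$fs
}

#' @export
as.matrix.sampled_signal <- function(x, ...) x$values

# single-channel values as a plain vector (errors on multichannel)
signal_vector <- function(x) {
  stopifnot(inherits(x, "sampled_signal"))
  if (ncol(x$values) != 1L)
    stop("expected a single-channel signal; got ", ncol(x$values), " channels")
  drop(x$values[, 1L])
}
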