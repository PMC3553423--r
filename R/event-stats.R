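series_values_times <- function(x) {
  if (inherits(x, "rve")) {
    list(values = x$h, times = x$times, fs = x$fs)
  } else if (inherits(x, "sampled_signal")) {
    list(values = signal_vector(x), times = signal_times(x), fs = x$fs)
  } else stop("'x' must be an 'rve' or single-channel 'sampled_signal'")
}

marker_times <- function(markers, label = NULL) {
  if (inherits(markers, "event_markers") || is.data.frame(markers)) {
    tm <- markers$time
    if (!is.null(label)) tm <- tm[markers$label %in% label]
    tm
  } else as.numeric(markers)
}

#' Cut event-locked epochs from a series
#'
#' Extracts trials x samples epochs around marker times.  Cutting is
#' sample-accurate (nearest sample to each marker); trials whose window
#' extends past either end of the recording are dropped and counted.
#'
#' @param x An `rve` or single-channel `sampled_signal`.
#' @param markers An `event_markers` object, data frame with a `time`
#'   column, or numeric vector of times (seconds).
#' @param window Length-2 numeric `(pre, post)` in seconds relative to the
#'   marker, e.g. `c(-0.2, 0.8)`.
#' @param label Optional marker label(s) to select.
#' @return Object of class `epoch_set`: list with `epochs` (trials x
#'   samples), `latencies` (seconds relative to marker), `window`, `fs`,
#'   `n_dropped`, `marker_times`.
#' @export
epoch <- function(x, markers, window, label = NULL) {
  s <- series_values_times(x)
  tm <- marker_times(markers, label)
  if (!length(tm)) stop("no usable markers")
  if (length(window) != 2L || window[2] <= window[1])
    stop("'window' must be (pre, post) seconds with post > pre")
  fs <- s$fs
  n <- length(s$values)
  n_pre <- round(window[1] * fs)
  n_post <- round(window[2] * fs)
  latencies <- (n_pre:n_post) / fs
  rows <- list(); kept_t <- numeric(0); dropped <- 0L
  for (t0 in tm) {
    k0 <- which.min(abs(s$times - t0)) # nearest sample to the marker
    lo <- k0 + n_pre; hi <- k0 + n_post
    if (lo < 1L || hi > n) { dropped <- dropped + 1L; next }
    rows[[length(rows) + 1L]] <- s$values[lo:hi]
    kept_t <- c(kept_t, t0)
  }
  if (!length(rows)) stop("no usable markers: all windows fall outside the recording")
  structure(list(epochs = do.call(rbind, rows), latencies = latencies,
                 window = window, fs = fs, n_dropped = dropped,
                 marker_times = kept_t),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials x %d samples (%g to %g s, %d dropped)\n",
              nrow(x$epochs), ncol(x$epochs), x$window[1], x$window[2],
              x$n_dropped))
  invisible(x)
}

#' Event-locked average
#'
#' Pointwise mean across trials (the average of the entropy, never the
#' entropy of an averaged signal), with per-latency SD and trial count.
#'
#' @param E An `epoch_set`.
#' @return List with `mean`, `sd`, `n`, `latencies`.
#' @export
event_average <- function(E) {
  stopifnot(inherits(E, "epoch_set"))
  list(mean = colMeans(E$epochs),
       sd = apply(E$epochs, 2L, stats::sd),
       n = nrow(E$epochs), latencies = E$latencies)
}

#' Baseline-referenced t-value series
#'
#' Subtracts each trial's own baseline mean (over `baseline = (start, end)`
#' seconds relative to the marker), then computes a one-sample Student's t
#' across trials at every latency: `t = mean / (sd / sqrt(n))` with
#' `df = n - 1`.
#'
#' @param E An `epoch_set` with at least 2 trials.
#' @param baseline Length-2 numeric `(start, end)` seconds relative to the
#'   marker; must lie inside the epoch window.
#' @return List with `t`, `df`, `latencies`, `baseline`.
#' @export
baseline_tseries <- function(E, baseline) {
  stopifnot(inherits(E, "epoch_set"))
  if (nrow(E$epochs) < 2L) stop("need at least 2 trials for a t-statistic")
  if (length(baseline) != 2L || baseline[2] <= baseline[1])
    stop("'baseline' must be (start, end) seconds with end > start")
  sel <- E$latencies >= baseline[1] - 1e-12 & E$latencies <= baseline[2] + 1e-12
  if (!any(sel)) stop("baseline interval lies outside the epoch window")
  base <- rowMeans(E$epochs[, sel, drop = FALSE])
  dev <- sweep(E$epochs, 1L, base)
  n <- nrow(dev)
  mu <- colMeans(dev)
  sdv <- apply(dev, 2L, stats::sd)
  tval <- mu / (sdv / sqrt(n))
  tval[sdv == 0 & mu == 0] <- 0
  list(t = tval, df = n - 1L, latencies = E$latencies, baseline = baseline)
}

#' Segment-integrated two-condition contrast
#'
#' Cuts `+/- half_window` segments around the two marker sets, integrates
#' the series over each segment (trapezoidal rule), and compares the two
#' populations of integrals with Welch's two-sample t-test (two-sided).
#'
#' @param x An `rve` or single-channel `sampled_signal`.
#' @param markers_a,markers_b Marker times for the two conditions (any form
#'   accepted by [epoch()]).
#' @param half_window Segment half width in seconds (default 0.25, i.e.
#'   0.5-s segments).
#' @return List with `t`, `p`, `df`, `integrals_a`, `integrals_b`.
#' @export
segment_contrast <- function(x, markers_a, markers_b, half_window = 0.25) {
  Ea <- epoch(x, markers_a, c(-half_window, half_window))
  Eb <- epoch(x, markers_b, c(-half_window, half_window))
  if (nrow(Ea$epochs) < 2L || nrow(Eb$epochs) < 2L)
    stop("need at least 2 segments per condition")
  integ <- function(E) apply(E$epochs, 1L, function(v) trapezoid(E$latencies, v))
  ia <- integ(Ea); ib <- integ(Eb)
  if (stats::sd(ia) == 0 && stats::sd(ib) == 0) {
    eq <- isTRUE(all.equal(mean(ia), mean(ib)))
    return(list(t = if (eq) 0 else Inf, p = if (eq) 1 else 0,
                df = NA_real_, integrals_a = ia, integrals_b = ib))
  }
  tt <- stats::t.test(ia, ib, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), integrals_a = ia, integrals_b = ib)
}

trapezoid <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Modal value of an entropy series
#'
#' The mode is the midpoint of the maximal bin of a fixed-width histogram
#' over `[0, 1]` (bin width 0.005); ties go to the lower bin.
#'
#' @param h Numeric vector of entropy values in `[0, 1]` (an `rve` object
#'   is also accepted).
#' @param bin_width Histogram bin width (default 0.005).
#' @return The modal value.
#' @export
rve_mode <- function(h, bin_width = 0.005) {
  if (inherits(h, "rve")) h <- h$h
  edges <- seq(0, 1 + bin_width, by = bin_width)
  bins <- findInterval(h, edges, rightmost.closed = TRUE)
  bins[bins < 1L] <- 1L
  counts <- tabulate(bins, nbins = length(edges) - 1L)
  k <- which.max(counts) # which.max takes the first (lower) bin on ties
  edges[k] + bin_width / 2
}

#' Deviation of a series from its statistical mode
#'
#' Used for task-free analysis: fluctuations are expressed relative to the
#' series' modal value rather than its mean.
#'
#' @param x An `rve` object or numeric series (length >= 100 so the mode is
#'   meaningful).
#' @param bin_width Histogram bin width passed to [rve_mode()].
#' @return Numeric vector `series - mode`, with the mode as attribute
#'   `"mode"`.
#' @export
mode_deviation <- function(x, bin_width = 0.005) {
  h <- if (inherits(x, "rve")) x$h else as.numeric(x)
  if (length(h) < 100L)
    warning("series shorter than 100 samples; mode estimate is unstable")
  m <- rve_mode(h, bin_width)
  structure(h - m, mode = m)
}
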