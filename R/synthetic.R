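#' Describe one regime segment of a source script
#'
#' @param start Segment start in seconds.
#' @param duration Segment duration in seconds.
#' @param regime One of `"oscillation"` (sinusoid), `"noise"` (iid
#'   Gaussian), `"pink"` (1/f-shaped Gaussian noise), `"silence"`, or
#'   `"evoked"` (Gaussian-windowed sinusoid transient).
#' @param amplitude Peak amplitude (oscillation, evoked) or standard
#'   deviation (noise regimes), in source units (A m for dipole moments).
#' @param freq Carrier frequency in Hz (oscillation, evoked).
#' @param width Gaussian envelope SD in seconds (evoked only).
#' @param latency Center of the evoked transient relative to the segment
#'   start, seconds; default `duration / 2`.
#' @param label Marker label attached to evoked transients.
#' @return One-row data frame; rbind rows to build a script.
#' @export
segment_spec <- function(start, duration, regime, amplitude, freq = 10,
                         width = 0.05, latency = duration / 2,
                         label = "evoked") {
  regime <- match.arg(regime, c("oscillation", "noise", "pink", "silence",
                                "evoked"))
  if (duration <= 0) stop("'duration' must be positive")
  data.frame(start = start, duration = duration, regime = regime,
             amplitude = amplitude, freq = freq, width = width,
             latency = latency, label = label, stringsAsFactors = FALSE)
}

#' A dipole source with a scripted activity time course
#'
#' @param position 3-vector source location in meters (inside the sphere
#'   when used with [simulate_meg()]).
#' @param orientation 3-vector dipole orientation (normalized internally).
#' @param segments Data frame of segments from [segment_spec()];
#'   non-overlapping.
#' @return Object of class `source_script`.
#' @export
source_script <- function(position, orientation, segments) {
  position <- as.numeric(position)
  orientation <- as.numeric(orientation)
  if (length(position) != 3L || length(orientation) != 3L)
    stop("'position' and 'orientation' must be 3-vectors")
  nrm <- sqrt(sum(orientation^2))
  if (nrm < 1e-12) stop("'orientation' must be nonzero")
  check_segments(segments)
  structure(list(position = position, orientation = orientation / nrm,
                 segments = segments),
            class = "source_script")
}

check_segments <- function(segments) {
  need <- c("start", "duration", "regime", "amplitude")
  if (!is.data.frame(segments) || !all(need %in% names(segments)))
    stop("'segments' must be a data frame with columns ",
         paste(need, collapse = ", "))
  if (nrow(segments) > 1L) {
    o <- order(segments$start)
    s <- segments$start[o]
    e <- s + segments$duration[o]
    if (any(s[-1] < e[-length(e)] - 1e-12))
      stop("segments overlap; regimes must be non-overlapping in time")
  }
  invisible(segments)
}

# 1/f amplitude-shaped Gaussian noise, unit variance
pink_noise <- function(n) {
  white <- stats::rnorm(n)
  Xf <- stats::fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1) # symmetric frequency magnitude
  Xf <- Xf / sqrt(f)
  v <- Re(stats::fft(Xf, inverse = TRUE)) / n
  v / stats::sd(v)
}

#' Generate a signal from a regime script
#'
#' Deterministic for a fixed seed.  Oscillation segments are sinusoids,
#' noise segments iid Gaussian (or 1/f-shaped), evoked segments
#' Gaussian-windowed sinusoids; everything else is silence.
#'
#' @param fs Sample rate in Hz.
#' @param segments Segment data frame ([segment_spec()]) or a
#'   `source_script`.
#' @param duration Total duration in seconds; default the end of the last
#'   segment.
#' @param seed Integer seed for the stochastic regimes.
#' @return A single-channel `sampled_signal`.
#' @export
make_regime_signal <- function(fs, segments, duration = NULL, seed = 1) {
  if (inherits(segments, "source_script")) segments <- segments$segments
  check_segments(segments)
  if (is.null(duration)) duration <- max(segments$start + segments$duration)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1L) / fs
  v <- numeric(n)
  set.seed(seed)
  for (i in seq_len(nrow(segments))) {
    sg <- segments[i, ]
    idx <- which(t >= sg$start - 1e-12 & t < sg$start + sg$duration - 1e-12)
    if (!length(idx)) next
    tt <- t[idx] - sg$start
    v[idx] <- switch(sg$regime,
      silence = 0,
      oscillation = sg$amplitude * sin(2 * pi * sg$freq * tt),
      noise = sg$amplitude * stats::rnorm(length(idx)),
      pink = sg$amplitude * pink_noise(length(idx)),
      evoked = {
        lat <- if (is.null(sg$latency) || is.na(sg$latency))
          sg$duration / 2 else sg$latency
        env <- exp(-(tt - lat)^2 / (2 * sg$width^2))
        sg$amplitude * env * sin(2 * pi * sg$freq * (tt - lat))
      })
  }
  sampled_signal(v, fs = fs, channel_names = "source")
}

#' Event markers
#'
#' @param labels Character vector of marker labels.
#' @param times Numeric vector of marker times in seconds.
#' @return Object of class `event_markers`: data frame sorted by time.
#' @export
event_markers <- function(labels, times) {
  if (length(labels) != length(times)) stop("labels and times must align")
  o <- order(times)
  structure(data.frame(label = as.character(labels)[o], time = times[o],
                       stringsAsFactors = FALSE),
            class = c("event_markers", "data.frame"))
}

#' Markers implied by a script's evoked transients
#'
#' One marker per evoked segment, at the transient center (segment start +
#' latency), carrying the segment's label.
#'
#' @param script A `source_script` or segment data frame.
#' @return An `event_markers` object (possibly empty).
#' @export
markers_from_script <- function(script) {
  seg <- if (inherits(script, "source_script")) script$segments else script
  ev <- seg[seg$regime == "evoked", , drop = FALSE]
  lat <- ev$latency
  if (is.null(lat)) lat <- ev$duration / 2
  lat[is.na(lat)] <- ev$duration[is.na(lat)] / 2
  lab <- if ("label" %in% names(ev)) ev$label else rep("evoked", nrow(ev))
  event_markers(lab, ev$start + lat)
}

#' Quasi-uniform helmet sensor array
#'
#' Places `n` point magnetometers on a spherical cap of the given radius
#' using a Fibonacci lattice, radially oriented.  `coverage` is the
#' fraction of the full sphere covered by the cap, measured from the +z
#' pole (0.5 = upper hemisphere).
#'
#' @param n Number of sensors (>= 3).
#' @param radius Cap radius in meters (default 0.12, a whole-head helmet).
#' @param coverage Fraction of sphere area (default 0.45).
#' @param center Cap center, default the origin (head frame).
#' @return A `sensor_array`.
#' @export
helmet_array <- function(n, radius = 0.12, coverage = 0.45,
                         center = c(0, 0, 0)) {
  if (!is.numeric(n) || length(n) != 1L || n < 3)
    stop("'n' must be an integer >= 3")
  n <- as.integer(n)
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n) - 0.5
  z <- 1 - (2 * coverage) * i / n # from the +z pole down the cap
  theta <- golden * (seq_len(n) - 1L)
  rho <- sqrt(pmax(0, 1 - z^2))
  unit <- cbind(rho * cos(theta), rho * sin(theta), z)
  positions <- sweep(radius * unit, 2L, center, "+")
  sensor_array(positions, unit, names = sprintf("MEG%03d", seq_len(n)))
}

#' Simulate a multichannel MEG session
#'
#' Forward-projects each scripted dipole source through the sphere model
#' (`sensor data = sum_s L(r_s) u_s s_s(t) + noise`), adds iid Gaussian
#' sensor noise, and collects the markers of all evoked transients.
#' Deterministic for a fixed seed.
#'
#' @param sources List of `source_script`s (positions inside the sphere).
#' @param sensors A `sensor_array`.
#' @param model A `sphere_model`.
#' @param noise_sd Per-sensor noise SD in Tesla.
#' @param fs Sample rate in Hz.
#' @param duration Recording length in seconds.
#' @param seed Integer seed.
#' @return List with `data` (multichannel `sampled_signal`), `markers`
#'   (`event_markers`), and `truth` (per-source positions, orientations,
#'   and the noiseless source series).
#' @export
simulate_meg <- function(sources, sensors, model, noise_sd, fs, duration,
                         seed = 1) {
  stopifnot(inherits(sensors, "sensor_array"), inherits(model, "sphere_model"))
  if (inherits(sources, "source_script")) sources <- list(sources)
  if (!length(sources) && noise_sd == 0)
    return(list(data = sampled_signal(
      matrix(0, round(duration * fs), nrow(sensors$positions)), fs = fs),
      markers = event_markers(character(0), numeric(0)), truth = list()))
  n <- round(duration * fs)
  M <- nrow(sensors$positions)
  dat <- matrix(0, n, M)
  truth <- list()
  labels <- character(0); times <- numeric(0)
  for (si in seq_along(sources)) {
    src <- sources[[si]]
    stopifnot(inherits(src, "source_script"))
    rc <- src$position - model$center
    if (sqrt(sum(rc^2)) >= model$radius)
      stop("source position lies outside the sphere model")
    s <- make_regime_signal(fs, src$segments, duration = duration,
                            seed = seed + 1000L * si)
    sv <- signal_vector(s)
    gain <- drop(sphere_leadfield(src$position, sensors, model) %*%
                   src$orientation)
    dat <- dat + outer(sv, gain)
    mk <- markers_from_script(src)
    labels <- c(labels, mk$label); times <- c(times, mk$time)
    truth[[si]] <- list(position = src$position,
                        orientation = src$orientation, series = sv)
  }
  if (noise_sd > 0) {
    set.seed(seed)
    dat <- dat + matrix(stats::rnorm(n * M, sd = noise_sd), n, M)
  }
  keep <- times < duration
  list(data = sampled_signal(dat, fs = fs, channel_names = sensors$names),
       markers = event_markers(labels[keep], times[keep]),
       truth = truth)
}

#' Evoked-transient protocol at one cortical source
#'
#' Builds the pair of source scripts used throughout validation: an
#' ongoing broadband-noise background at the source location, plus a train
#' of evoked transients (Gaussian-windowed sinusoids, an N100m-like shape)
#' at pseudo-random inter-stimulus intervals.  Defaults mirror a
#' desk-scale auditory oddball session: 1.0-1.5 s ISI, ~0.08 s transient
#' width, 8 Hz carrier, 40 nA m transient over a 10 nA m RMS background.
#'
#' @param position,orientation Dipole location (m) and orientation.
#' @param n_trials Number of evoked transients.
#' @param isi_range Inter-stimulus interval range in seconds.
#' @param transient_amp Transient peak amplitude, A m.
#' @param background_amp Background noise SD, A m.
#' @param freq Transient carrier frequency, Hz.
#' @param width Transient envelope SD, seconds.
#' @param lead Silent lead time before the first stimulus, seconds.
#' @param seed Integer seed for the ISI draw.
#' @return List with `sources` (list of two `source_script`s), `markers`,
#'   and `duration` (seconds).
#' @export
evoked_protocol <- function(position, orientation, n_trials = 40,
                            isi_range = c(1.0, 1.5), transient_amp = 40e-9,
                            background_amp = 10e-9, freq = 8, width = 0.08,
                            lead = 2, seed = 1) {
  set.seed(seed)
  isi <- stats::runif(n_trials, isi_range[1], isi_range[2])
  onsets <- lead + cumsum(isi)
  duration <- max(onsets) + 1.5
  seg_w <- 6 * width # evoked segment long enough to hold the transient
  ev <- do.call(rbind, lapply(onsets, function(t0)
    segment_spec(t0 - seg_w / 2, seg_w, "evoked", transient_amp,
                 freq = freq, width = width, latency = seg_w / 2,
                 label = "stim")))
  bg <- segment_spec(0, duration, "noise", background_amp)
  src_ev <- source_script(position, orientation, ev)
  src_bg <- source_script(position, orientation, bg)
  list(sources = list(src_bg, src_ev),
       markers = markers_from_script(src_ev), duration = duration)
}
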