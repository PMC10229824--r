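## Continuous multichannel LFP -> per-region tone-offset-locked ERPs:
## anti-aliased decimation to 1 kHz, zero-phase 1-32 Hz band-pass,
## event-locked epoch averaging, peak-to-trough channel selection.

#' Construct a raw recording
#'
#' @param samples Channels x time matrix of potentials (arbitrary units).
#' @param rate Sampling rate (Hz), positive.
#' @param events Event (tone-offset) times in seconds, strictly increasing
#'   and inside the recording.
#' @param channels Optional data frame with one row per channel
#'   (columns `channel_id`, `region`); defaults to sequential ids.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(samples, rate, events, channels = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  stopifnot(is.matrix(samples), rate > 0)
  dur <- ncol(samples) / rate
  if (length(events)) {
    if (any(diff(events) <= 0)) stop("events must be strictly increasing")
    if (any(events < 0 | events > dur)) stop("events must lie inside the recording")
  }
  if (is.null(channels))
    channels <- data.frame(channel_id = seq_len(nrow(samples)),
                           region = NA_character_)
  stopifnot(nrow(channels) == nrow(samples))
  structure(list(samples = samples, rate = rate, events = as.numeric(events),
                 channels = channels), class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channel(s), %.2f s at %g Hz, %d event(s)\n",
              nrow(x$samples), ncol(x$samples) / x$rate, x$rate,
              length(x$events)))
  invisible(x)
}

## zero-phase frequency-domain filtering with reflection padding.
## mag2 is the squared-magnitude (forward-backward) response as a function
## of frequency in Hz.
.fft_filter <- function(x, rate, mag2, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(n - pad):(n - 1)]))
  np <- length(xp)
  f <- (seq_len(np) - 1) / np * rate
  f <- pmin(f, rate - f)       # two-sided frequency axis
  X <- stats::fft(xp) * mag2(f)
  out <- Re(stats::fft(X, inverse = TRUE)) / np
  out[(pad + 1):(pad + n)]
}

## squared-magnitude responses (zero-phase application of Butterworth designs)
.butter_lowpass_mag2 <- function(fc, order = 8) {
  function(f) 1 / (1 + (f / fc)^(2 * order))
}

.butter_bandpass_mag2 <- function(low, high, order = 4) {
  function(f) {
    ## band-pass prototype frequency mapping; DC maps to infinity
    om <- ifelse(f > 0, (f^2 - low * high) / (f * (high - low)), Inf)
    1 / (1 + om^(2 * order))
  }
}

#' Decimate a recording
#'
#' Anti-alias filters each channel (order-8 zero-phase Butterworth low-pass
#' with cutoff at a quarter of the target rate) and keeps every
#' `rate / target_rate`-th sample. Event times are expressed in seconds and
#' are unchanged.
#'
#' @param recording A [raw_recording()].
#' @param target_rate Target sampling rate (Hz); must divide the recording
#'   rate exactly.
#' @return The decimated [raw_recording()].
#' @export
decimate <- function(recording, target_rate) {
  stopifnot(inherits(recording, "raw_recording"))
  factor <- recording$rate / target_rate
  if (abs(factor - round(factor)) > 1e-9)
    stop("target_rate must divide the recording rate (no resampling dialects)")
  factor <- as.integer(round(factor))
  if (factor == 1L) return(recording)
  fc <- target_rate / 4
  mag2 <- .butter_lowpass_mag2(fc)
  pad <- as.integer(ceiling(4 * recording$rate / fc))
  filt <- t(apply(recording$samples, 1, .fft_filter,
                  rate = recording$rate, mag2 = mag2, pad = pad))
  keep <- seq(1, ncol(filt), by = factor)
  raw_recording(filt[, keep, drop = FALSE], target_rate, recording$events,
                recording$channels)
}

#' Zero-phase band-pass filter
#'
#' Applies an order-4 Butterworth band-pass, realized as a zero-phase
#' (forward-backward) squared-magnitude response in the frequency domain,
#' to every channel. DC is removed (it lies outside the band).
#'
#' @param recording A [raw_recording()].
#' @param low,high Band edges (Hz), defaults 1 and 32;
#'   `0 < low < high < rate / 2` required.
#' @return The filtered [raw_recording()].
#' @export
bandpass <- function(recording, low = 1, high = 32) {
  stopifnot(inherits(recording, "raw_recording"))
  if (!(low > 0 && high > low && high < recording$rate / 2))
    stop("band edges must satisfy 0 < low < high < rate / 2")
  mag2 <- .butter_bandpass_mag2(low, high)
  pad <- as.integer(ceiling(2 * recording$rate / low))
  filt <- t(apply(recording$samples, 1, .fft_filter,
                  rate = recording$rate, mag2 = mag2, pad = pad))
  raw_recording(filt, recording$rate, recording$events, recording$channels)
}

#' Construct an evoked response
#'
#' @param region Region label (e.g. `"MCN"`, `"vlPAG"`).
#' @param time_ms Time grid (ms relative to the event).
#' @param amplitude Mean waveform.
#' @param n_trials Number of events averaged.
#' @param channel_id Provenance channel id.
#' @return An object of class `evoked_response`.
#' @export
evoked_response <- function(region, time_ms, amplitude, n_trials,
                            channel_id = NA_integer_) {
  stopifnot(length(time_ms) == length(amplitude))
  structure(list(region = region, time_ms = time_ms, amplitude = amplitude,
                 n_trials = n_trials, channel_id = channel_id),
            class = "evoked_response")
}

#' Event-locked epoch averaging
#'
#' Averages each channel over epochs time-locked to the recorded events on
#' the window grid (1 ms resolution relative to the event; the recording
#' rate must be a multiple of 1 kHz). Events whose window extends beyond the
#' recording are dropped with a warning.
#'
#' @param recording A [raw_recording()] (typically decimated to 1 kHz and
#'   band-passed).
#' @param window_ms Window `(start, end)` in ms relative to the event,
#'   default `c(1, 200)`.
#' @return A list of [evoked_response()] objects, one per channel.
#' @export
epoch_average <- function(recording, window_ms = c(1, 200)) {
  stopifnot(inherits(recording, "raw_recording"), length(window_ms) == 2)
  step <- recording$rate / 1000
  if (abs(step - round(step)) > 1e-9)
    stop("recording rate must be a multiple of 1 kHz for 1 ms epoch grids")
  step <- as.integer(round(step))
  grid_ms <- seq(window_ms[1], window_ms[2])
  n <- ncol(recording$samples)
  usable <- list()
  dropped <- 0L
  for (ev in recording$events) {
    idx0 <- round(ev * recording$rate)
    idx <- idx0 + grid_ms * step + 1L   # 1-based; sample i is t=(i-1)/rate
    if (min(idx) < 1L || max(idx) > n) { dropped <- dropped + 1L; next }
    usable[[length(usable) + 1L]] <- idx
  }
  if (dropped > 0L)
    warning(sprintf("%d event(s) dropped: window extends beyond the recording",
                    dropped))
  if (!length(usable)) stop("no usable events for epoch averaging")
  lapply(seq_len(nrow(recording$samples)), function(ch) {
    ep <- vapply(usable, function(idx) recording$samples[ch, idx],
                 numeric(length(grid_ms)))
    evoked_response(recording$channels$region[ch], grid_ms, rowMeans(ep),
                    n_trials = length(usable),
                    channel_id = recording$channels$channel_id[ch])
  })
}

#' Select the channel with the largest peak-to-trough ERP
#'
#' Returns the evoked response with the largest `max - min` amplitude inside
#' the analysis window; ties are broken by the lowest list position.
#'
#' @param erps Non-empty list of [evoked_response()] objects on a common
#'   time grid.
#' @param window_ms Analysis window (ms), default `c(1, 200)`.
#' @return The selected [evoked_response()].
#' @export
select_best_channel <- function(erps, window_ms = c(1, 200)) {
  if (!length(erps)) stop("empty list of evoked responses")
  ptp <- vapply(erps, function(e) {
    sel <- e$time_ms >= window_ms[1] & e$time_ms <= window_ms[2]
    if (!any(sel)) stop("analysis window outside the ERP time grid")
    diff(range(e$amplitude[sel]))
  }, numeric(1))
  erps[[which.max(ptp)]]
}
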