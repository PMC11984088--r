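# Complex Morlet wavelet transform via frequency-domain Gaussians. For each
# analysis frequency the filter is a Gaussian of width f / n_cycles centered
# on f, applied to the positive-frequency half of the spectrum (analytic
# output) with unit gain at the center frequency, so a pure tone of
# amplitude A yields |W| = A at its own frequency regardless of f.
morlet_transform <- function(x, fs, freqs, n_cycles = 7) {
  n <- length(x)
  nfft <- stats::nextn(n, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(nfft - n)))
  fgrid <- (seq_len(nfft) - 1) * fs / nfft
  pos <- fgrid <= fs / 2
  out <- matrix(0i, length(freqs), n)
  for (k in seq_along(freqs)) {
    f <- freqs[k]
    sf <- f / n_cycles
    H <- numeric(nfft)
    H[pos] <- 2 * exp(-(fgrid[pos] - f)^2 / (2 * sf^2))
    H[1] <- H[1] / 2
    w <- stats::fft(X * H, inverse = TRUE) / nfft
    out[k, ] <- w[seq_len(n)]
  }
  out
}

#' Morlet wavelet power of an LFP segment
#'
#' @param x LFP samples (microvolts).
#' @param fs sampling rate, Hz.
#' @param freqs analysis frequencies, Hz (default 2-250 in 1 Hz steps).
#' @param n_cycles wavelet width in cycles at every frequency.
#' @return frequency x time power matrix (amplitude squared).
#' @export
morlet_power <- function(x, fs, freqs = 2:250, n_cycles = 7) {
  Mod(morlet_transform(x, fs, freqs, n_cycles))^2
}

#' Peri-event time-frequency power
#'
#' Extracts an LFP segment around each event onset, computes Morlet wavelet
#' power in 1 Hz steps across `cfg$wavelet_band`, z-scores within each
#' frequency over the concatenated peri-event segments, and averages the
#' aligned maps across events.
#'
#' @param lfp LFP channel (list with `fs_hz`, `samples`, `t0`).
#' @param onsets_s event onset times, s.
#' @param cfg an [analysis_config()] (`event_power_win_s` sets the
#'   half-window).
#' @return object of class `power_map`: `freqs_hz`, `times_s` (relative to
#'   onset), `z_power` (frequency x time, averaged over events),
#'   `per_event` (list of per-event z-scored matrices), `n_events`.
#'   Events whose window exceeds the LFP extent are dropped with a warning.
#' @export
event_power <- function(lfp, onsets_s, cfg = analysis_config()) {
  stopifnot(length(onsets_s) >= 1)
  fs <- lfp$fs_hz
  freqs <- seq(cfg$wavelet_band[1], cfg$wavelet_band[2], by = 1)
  half <- round(cfg$event_power_win_s * fs)
  n <- length(lfp$samples)
  idx0 <- round((onsets_s - lfp$t0) * fs) + 1L
  keep <- idx0 - half >= 1 & idx0 + half <= n
  if (!all(keep)) {
    warning(sprintf("%d event(s) dropped: window exceeds LFP extent",
                    sum(!keep)))
  }
  idx0 <- idx0[keep]
  if (!length(idx0)) stop("no events with a full peri-event LFP window")
  pows <- lapply(idx0, function(i0) {
    morlet_power(lfp$samples[(i0 - half):(i0 + half)], fs, freqs,
                 cfg$wavelet_cycles)
  })
  # z-score within frequency over the concatenated peri-event segments
  all_p <- do.call(cbind, pows)
  mu <- rowMeans(all_p)
  sd_ <- apply(all_p, 1, stats::sd)
  sd_[sd_ == 0] <- 1
  z_events <- lapply(pows, function(p) (p - mu) / sd_)
  avg <- Reduce(`+`, z_events) / length(z_events)
  structure(list(freqs_hz = freqs,
                 times_s = (seq(-half, half)) / fs,
                 z_power = avg,
                 per_event = z_events,
                 per_event_raw = pows,
                 n_events = length(z_events)),
            class = "power_map")
}

#' @export
print.power_map <- function(x, ...) {
  cat(sprintf("<power_map> %d-%d Hz x %.0f ms around onset, %d event(s)\n",
              min(x$freqs_hz), max(x$freqs_hz),
              1000 * diff(range(x$times_s)), x$n_events))
  invisible(x)
}

#' Peak ripple frequency of one event
#'
#' The frequency with the highest time-averaged power within the ripple
#' band; ties break deterministically toward the lower frequency. Use the
#' raw per-event wavelet power here (`per_event_raw`): the wavelets have
#' unit gain at every center frequency, so raw power preserves an
#' oscillation's spectral profile, whereas within-frequency z-scoring is
#' scale-invariant per row and flattens the profile of any transient that
#' dominates its own rows' variance.
#'
#' @param z_event one per-event frequency x time power matrix (from
#'   [event_power()]'s `per_event_raw` for this measure).
#' @param freqs_hz frequency axis of the matrix.
#' @param band ripple band, Hz.
#' @param t_sel optional logical/integer selection of time columns (e.g. the
#'   event's own extent); default all.
#' @return frequency in Hz.
#' @export
peak_ripple_frequency <- function(z_event, freqs_hz, band = c(150, 250),
                                  t_sel = NULL) {
  if (is.null(t_sel)) t_sel <- seq_len(ncol(z_event))
  rows <- which(freqs_hz >= band[1] & freqs_hz <= band[2])
  m <- rowMeans(z_event[rows, t_sel, drop = FALSE])
  freqs_hz[rows[which.max(m)]]
}

#' Mean slow-gamma power of one event
#'
#' Average z-scored power across the slow-gamma band and across time.
#'
#' @inheritParams peak_ripple_frequency
#' @param band slow-gamma band, Hz.
#' @return mean z-scored power.
#' @export
slow_gamma_power <- function(z_event, freqs_hz, band = c(25, 55),
                             t_sel = NULL) {
  if (is.null(t_sel)) t_sel <- seq_len(ncol(z_event))
  rows <- which(freqs_hz >= band[1] & freqs_hz <= band[2])
  mean(z_event[rows, t_sel, drop = FALSE])
}

#' Detect sharp wave-ripples
#'
#' Bandpass filters the LFP in the ripple band (zero-phase Butterworth),
#' takes the Hilbert envelope, smooths it with an 8 ms SD Gaussian,
#' z-scores it over the channel, and returns the intervals where the
#' z-scored envelope is at or above `cfg$ripple_z`.
#'
#' @param lfp LFP channel (list with `fs_hz`, `samples`, `t0`).
#' @param cfg an [analysis_config()].
#' @return data.frame of ripple intervals: `start_s`, `end_s`, `peak_z`.
#' @export
detect_ripples <- function(lfp, cfg = analysis_config()) {
  fs <- lfp$fs_hz
  bf <- signal::butter(4, cfg$ripple_band / (fs / 2), type = "pass")
  filt <- filtfilt_pad(bf, lfp$samples, ceiling(3 * fs / cfg$ripple_band[1]))
  env <- Mod(hilbert_analytic(filt))
  env <- smooth_linear(env, cfg$ripple_smooth_s * fs)
  z <- (env - mean(env)) / stats::sd(env)
  above <- z >= cfg$ripple_z
  if (!any(above)) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      peak_z = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(
    start_s = lfp$t0 + (starts[keep] - 1) / fs,
    end_s = lfp$t0 + (ends[keep] - 1) / fs,
    peak_z = vapply(which(keep), function(k) {
      max(z[starts[k]:ends[k]])
    }, numeric(1)))
}

#' Count ripples overlapping each event
#'
#' A ripple counts toward an event when its interval overlaps the event
#' bounds.
#'
#' @param events data.frame with `start_s`, `end_s`.
#' @param ripples data.frame from [detect_ripples()].
#' @return integer vector, one count per event.
#' @export
count_ripples_per_event <- function(events, ripples) {
  vapply(seq_len(nrow(events)), function(i) {
    sum(ripples$start_s <= events$end_s[i] &
          ripples$end_s >= events$start_s[i])
  }, integer(1))
}

#' Replay-event LFP summary table
#'
#' Per replay event: peak ripple frequency, mean slow-gamma z-power over
#' the event's own extent, and the number of detected ripples overlapping
#' the event.
#'
#' @param session a `place_session`.
#' @param events classified event table (rows with `is_replay` are used).
#' @param cfg an [analysis_config()].
#' @param channel LFP channel index.
#' @return data.frame: `start_s`, `duration_s`, `peak_ripple_hz`,
#'   `slow_gamma_z`, `n_ripples`.
#' @export
replay_lfp_table <- function(session, events, cfg = analysis_config(),
                             channel = 1L) {
  ev <- events[events$is_replay, , drop = FALSE]
  if (!nrow(ev)) stop("no replay events")
  lfp <- session$lfp[[channel]]
  pw <- event_power(lfp, ev$start_s, cfg)
  # event_power may drop edge events; align by recomputing the keep mask
  fs <- lfp$fs_hz
  half <- round(cfg$event_power_win_s * fs)
  idx0 <- round((ev$start_s - lfp$t0) * fs) + 1L
  keep <- idx0 - half >= 1 & idx0 + half <= length(lfp$samples)
  ev <- ev[keep, , drop = FALSE]
  ripples <- detect_ripples(lfp, cfg)
  out <- data.frame(start_s = ev$start_s, duration_s = ev$duration_s,
                    peak_ripple_hz = NA_real_, slow_gamma_z = NA_real_,
                    n_ripples = count_ripples_per_event(ev, ripples))
  for (i in seq_len(nrow(ev))) {
    t_sel <- pw$times_s >= 0 & pw$times_s <= ev$duration_s[i]
    out$peak_ripple_hz[i] <- peak_ripple_frequency(
      pw$per_event_raw[[i]], pw$freqs_hz, cfg$ripple_band, t_sel)
    out$slow_gamma_z[i] <- slow_gamma_power(
      pw$per_event[[i]], pw$freqs_hz, cfg$slowgamma_band, t_sel)
  }
  out
}
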