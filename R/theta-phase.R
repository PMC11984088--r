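# Zero-phase filtering with odd-reflection padding at both ends, so steps
# and offsets at the segment boundaries do not ring into the series.
filtfilt_pad <- function(bf, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1)
  left <- 2 * x[1] - x[seq(pad + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - pad)]
  y <- signal::filtfilt(bf, c(left, x, right))
  y[(pad + 1):(pad + n)]
}

# Analytic signal via the frequency-domain Hilbert construction.
hilbert_analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous theta phase of an LFP channel
#'
#' Zero-phase (forward-backward) 4th-order Butterworth bandpass in the theta
#' band followed by the analytic-signal (Hilbert) phase. Phase convention:
#' 0 degrees at the peak of the filtered waveform, 180 at the trough, and
#' phase advances through `[0, 360)` each cycle.
#'
#' The channel is first decimated (anti-aliased) to roughly 20 times the
#' band's upper edge: a theta-wide Butterworth bandpass expressed at a
#' 2,000 Hz rate has a normalized band so narrow that its transfer-function
#' coefficients are numerically ill-conditioned, producing degree-scale
#' phase ripple; at the decimated rate the filter is well behaved. The
#' phase is interpolated back onto the original sample grid, so the result
#' has one phase per input sample.
#'
#' @param lfp LFP channel: list with `fs_hz`, `samples`, `t0`.
#' @param band bandpass edges, Hz.
#' @param cfg an [analysis_config()] (used for its `theta_band` when `band`
#'   is missing).
#' @return object of class `phase_series`: data.frame `t`, `phase_deg`, with
#'   the filtered (decimated-rate) trace in attribute `"filtered"`.
#' @export
theta_filter_phase <- function(lfp, band = NULL, cfg = analysis_config()) {
  if (is.null(band)) band <- cfg$theta_band
  fs <- lfp$fs_hz
  stopifnot(fs >= 4 * band[2])
  n <- length(lfp$samples)
  if (n < 3 * fs / band[1]) {
    stop("LFP segment too short to filter at this band")
  }
  q <- max(1L, floor(fs / (20 * band[2])))
  x <- lfp$samples
  if (q > 1) {
    aa <- signal::butter(4, 0.8 / q, type = "low")   # anti-alias
    x <- filtfilt_pad(aa, x, 10 * q)[seq(1, n, by = q)]
  }
  fs_d <- fs / q
  bf <- signal::butter(4, band / (fs_d / 2), type = "pass")
  filt <- filtfilt_pad(bf, x, ceiling(3 * fs_d / band[1]))
  ph_d <- rad2deg(Arg(hilbert_analytic(filt)))
  t_d <- lfp$t0 + (seq_along(x) - 1) * q / fs
  t_full <- lfp$t0 + (seq_len(n) - 1) / fs
  u <- unwrap_deg(ph_d)
  phase <- wrap_deg(stats::approx(t_d, u, xout = t_full, rule = 2)$y)
  out <- data.frame(t = t_full, phase_deg = phase)
  attr(out, "filtered") <- filt
  attr(out, "fs_filtered_hz") <- fs_d
  class(out) <- c("phase_series", "data.frame")
  out
}

#' Interpolate instantaneous phase at arbitrary times
#'
#' Linear interpolation on the unwrapped phase, wrapped back to `[0, 360)`.
#'
#' @param phase_series a `phase_series` from [theta_filter_phase()].
#' @param t times, s.
#' @return phases in degrees.
#' @export
phase_at_time <- function(phase_series, t) {
  u <- unwrap_deg(phase_series$phase_deg)
  wrap_deg(stats::approx(phase_series$t, u, xout = t, rule = 2)$y)
}

#' In-field spike phases and normalized positions
#'
#' For every spike a unit fires inside a place field during the given run
#' epochs, while the rat moves faster than the speed gate, returns the
#' normalized distance through the field (0 at the field start, 1 at its
#' end, wrap-aware) and the interpolated theta phase at the spike time.
#'
#' @param spike_t spike times of the unit, s.
#' @param field one row of the [detect_place_fields()] table (uses
#'   `start_deg`, `size_deg`).
#' @param position position trace of the session.
#' @param phase a `phase_series` covering the run epochs.
#' @param epochs data.frame of run epochs (`start_s`, `end_s`).
#' @param cfg an [analysis_config()].
#' @return data.frame with `t`, `norm_pos`, `phase_deg` (possibly 0 rows).
#' @export
spike_phases_in_field <- function(spike_t, field, position, phase, epochs,
                                  cfg = analysis_config()) {
  keep <- rep(FALSE, length(spike_t))
  for (i in seq_len(nrow(epochs))) {
    keep <- keep | (spike_t >= epochs$start_s[i] & spike_t < epochs$end_s[i])
  }
  st <- spike_t[keep]
  if (!length(st)) {
    return(data.frame(t = numeric(0), norm_pos = numeric(0),
                      phase_deg = numeric(0)))
  }
  st <- st[speed_at_time(position, st) > cfg$speed_min]
  if (!length(st)) {
    return(data.frame(t = numeric(0), norm_pos = numeric(0),
                      phase_deg = numeric(0)))
  }
  ang <- angle_at_time(position, st)
  off <- (ang - field$start_deg) %% 360
  inside <- off <= field$size_deg
  st <- st[inside]
  data.frame(t = st,
             norm_pos = off[inside] / field$size_deg,
             phase_deg = phase_at_time(phase, st))
}

#' Circular-linear phase-precession fit
#'
#' Regresses theta phase (circular) on normalized field position (linear):
#' the slope maximizes the mean resultant length of the phase residuals over
#' a bounded range, and the correlation magnitude `r` is the standard
#' circular-linear correlation of phase with position. Units firing fewer
#' than `cfg$precession_min_spikes` in-field spikes are returned as excluded
#' records rather than errors.
#'
#' @param norm_pos normalized positions in `[0, 1]`.
#' @param phase_deg spike theta phases, degrees.
#' @param cfg an [analysis_config()] (`precession_slope_bounds`,
#'   `precession_min_spikes`).
#' @param unit_id carried onto the result.
#' @return object of class `precession_result`: list with `unit_id`,
#'   `n_spikes`, `slope_deg_per_field`, `phi0_deg`, `r`, `p_value`,
#'   `included`, `reason`.
#' @export
circular_linear_fit <- function(norm_pos, phase_deg, cfg = analysis_config(),
                                unit_id = NA_character_) {
  n <- length(norm_pos)
  if (n < cfg$precession_min_spikes) {
    return(structure(list(unit_id = unit_id, n_spikes = n,
                          slope_deg_per_field = NA_real_, phi0_deg = NA_real_,
                          r = NA_real_, p_value = NA_real_, included = FALSE,
                          reason = sprintf("only %d in-field spikes (minimum %d)",
                                           n, cfg$precession_min_spikes)),
                     class = "precession_result"))
  }
  fit <- circ_lin_fit(norm_pos, phase_deg,
                      slope_bounds = cfg$precession_slope_bounds)
  cc <- circ_lin_corr(norm_pos, phase_deg)
  structure(list(unit_id = unit_id, n_spikes = n,
                 slope_deg_per_field = fit$slope,
                 phi0_deg = fit$intercept_deg,
                 r = cc$r, p_value = cc$p_value,
                 included = TRUE, reason = NA_character_),
            class = "precession_result")
}

#' @export
print.precession_result <- function(x, ...) {
  if (!x$included) {
    cat(sprintf("<precession_result> unit %s excluded: %s\n", x$unit_id,
                x$reason))
  } else {
    cat(sprintf("<precession_result> unit %s: n=%d, slope %.1f deg/field, r=%.3f (p=%.3g)\n",
                x$unit_id, x$n_spikes, x$slope_deg_per_field, x$r, x$p_value))
  }
  invisible(x)
}

#' Phase precession for every included place cell of a day
#'
#' Detects each included unit's place fields on its day-averaged map, takes
#' the field with the highest peak rate, collects in-field spike phases
#' across all run sessions, and fits the circular-linear regression.
#'
#' @param session a `place_session`.
#' @param maps result of [day_rate_maps()] (computed if missing).
#' @param phase a `phase_series` (computed from channel 1 if missing).
#' @param cfg an [analysis_config()].
#' @return data.frame, one row per included unit with a field: `unit_id`,
#'   `n_spikes`, `slope_deg_per_field`, `r`, `p_value`, `included`.
#' @export
phase_precession_table <- function(session, maps = NULL, phase = NULL,
                                   cfg = analysis_config()) {
  if (is.null(maps)) maps <- day_rate_maps(session, cfg)
  if (is.null(phase)) phase <- theta_filter_phase(session$lfp[[1]], cfg = cfg)
  runs <- session$schedule[grepl("^run", session$schedule$label),
                           c("start_s", "end_s")]
  rows <- list()
  for (j in seq_along(session$units)) {
    if (!maps$included[j]) next
    flds <- detect_place_fields(maps$day_maps[[j]], cfg)
    if (!nrow(flds)) next
    fld <- flds[which.max(flds$peak_rate_hz), ]
    pr <- spike_phases_in_field(session$units[[j]]$spike_t, fld,
                                session$position, phase, runs, cfg)
    fit <- circular_linear_fit(pr$norm_pos, pr$phase_deg, cfg,
                               unit_id = session$units[[j]]$unit_id)
    rows[[length(rows) + 1]] <- data.frame(
      unit_id = fit$unit_id, n_spikes = fit$n_spikes,
      slope_deg_per_field = fit$slope_deg_per_field,
      r = fit$r, p_value = fit$p_value, included = fit$included)
  }
  if (!length(rows)) {
    return(data.frame(unit_id = character(0), n_spikes = integer(0),
                      slope_deg_per_field = numeric(0), r = numeric(0),
                      p_value = numeric(0), included = logical(0)))
  }
  do.call(rbind, rows)
}
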