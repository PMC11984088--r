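#' Analysis configuration
#'
#' Collects every threshold and window used by the pipeline as a named
#' parameter. The defaults reproduce the published CA1 circular-track
#' methods exactly; override individual values by name.
#'
#' @param bin_deg spatial bin width of the rate map, degrees (90 bins).
#' @param smooth_deg Gaussian smoothing SD for rate maps, degrees.
#' @param speed_min running-speed gate, cm/s; samples and spikes at or below
#'   this speed are excluded from run analyses.
#' @param peak_min_hz minimum day-averaged peak rate for a unit to count as
#'   an active place cell.
#' @param interneuron_hz mean-rate threshold above which a unit is flagged a
#'   putative interneuron and excluded.
#' @param field_z_enter,field_z_exit z-score thresholds that seed and bound a
#'   place field.
#' @param field_min_deg minimum place-field extent, degrees.
#' @param precession_min_spikes minimum in-field spikes for the
#'   phase-precession fit.
#' @param theta_band theta bandpass, Hz.
#' @param acc_win_s,acc_step_s decoding-accuracy window length and step, s.
#' @param acc_criterion_deg decoding-accuracy inclusion criterion: the
#'   cumulative error distribution must reach 50% below this error, degrees
#'   (equivalently, median error below it).
#' @param seq_win_s,seq_step_s theta-sequence decoding window and step, s.
#' @param seq_min_cells minimum active place cells per theta cycle.
#' @param seq_gap_bins number of consecutive spikeless decoding windows that
#'   breaks contiguity within a cycle.
#' @param seq_n_shuffle number of circular shuffles for sequence significance.
#' @param seq_alpha shuffle significance level.
#' @param seq_prob_frac minimum fraction of posterior mass that must lie near
#'   the fitted line.
#' @param seq_prob_dist_deg,seq_actual_dist_deg "near" distances for the
#'   posterior-mass and line-to-actual-position criteria, degrees.
#' @param seq_slope_bounds admissible theta-sequence slopes, deg/s.
#' @param precession_slope_bounds admissible precession slopes, deg per
#'   traversed field.
#' @param replay_z population-rate threshold for candidate events, SDs above
#'   the mean.
#' @param replay_merge_s candidate events closer than this are merged, s.
#' @param replay_dur_s admissible candidate durations, s (length 2).
#' @param replay_min_cells minimum distinct cells firing in a candidate.
#' @param replay_win_s,replay_step_s replay decoding window and step, s.
#' @param replay_r2_min minimum regression r-squared for significant replay.
#' @param replay_jump_frac maximum decoded jump between adjacent windows, as
#'   a fraction of the track.
#' @param replay_slope_bounds admissible replay slopes, deg/s.
#' @param psth_bin_s,psth_smooth_s replay PSTH bin width and Gaussian
#'   smoothing SD, s.
#' @param psth_win_s PSTH extent around event onset, s (length 2, signed).
#' @param wavelet_band wavelet frequency range, Hz (evaluated in 1 Hz steps).
#' @param wavelet_cycles Morlet wavelet width, cycles.
#' @param ripple_band ripple bandpass, Hz.
#' @param slowgamma_band slow-gamma band, Hz.
#' @param ripple_smooth_s Gaussian SD for the ripple envelope, s.
#' @param ripple_z ripple detection threshold, envelope z-score.
#' @param event_power_win_s peri-event extent of the time-frequency maps, s.
#' @param decode_rate_floor_hz tuning-curve floor inside the Poisson
#'   log-likelihood, Hz.
#' @param cycle_phase_bin_deg spike-phase histogram bin for theta-cycle
#'   cutting, degrees.
#' @param rng_seed integer seed recorded with reports for reproducibility.
#' @return an object of class `analysis_config` (a named list).
#' @export
analysis_config <- function(bin_deg = 4,
                            smooth_deg = 8,
                            speed_min = 5,
                            peak_min_hz = 1,
                            interneuron_hz = 5,
                            field_z_enter = 2,
                            field_z_exit = 0.5,
                            field_min_deg = 18,
                            precession_min_spikes = 50,
                            theta_band = c(6, 10),
                            acc_win_s = 0.5,
                            acc_step_s = 0.1,
                            acc_criterion_deg = 20,
                            seq_win_s = 0.04,
                            seq_step_s = 0.01,
                            seq_min_cells = 3,
                            seq_gap_bins = 2,
                            seq_n_shuffle = 1000,
                            seq_alpha = 0.05,
                            seq_prob_frac = 0.6,
                            seq_prob_dist_deg = 20,
                            seq_actual_dist_deg = 20,
                            seq_slope_bounds = c(-3000, 3000),
                            precession_slope_bounds = c(-1080, 1080),
                            replay_z = 3,
                            replay_merge_s = 0.04,
                            replay_dur_s = c(0.05, 2.0),
                            replay_min_cells = 5,
                            replay_win_s = 0.02,
                            replay_step_s = 0.01,
                            replay_r2_min = 0.5,
                            replay_jump_frac = 0.25,
                            replay_slope_bounds = c(-5000, 5000),
                            psth_bin_s = 0.001,
                            psth_smooth_s = 0.01,
                            psth_win_s = c(-0.5, 0.5),
                            wavelet_band = c(2, 250),
                            wavelet_cycles = 7,
                            ripple_band = c(150, 250),
                            slowgamma_band = c(25, 55),
                            ripple_smooth_s = 0.008,
                            ripple_z = 3,
                            event_power_win_s = 0.5,
                            decode_rate_floor_hz = 0.01,
                            cycle_phase_bin_deg = 20,
                            rng_seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$bin_deg > 0, 360 %% cfg$bin_deg == 0,
    cfg$smooth_deg >= 0, cfg$speed_min >= 0,
    cfg$theta_band[1] < cfg$theta_band[2],
    cfg$ripple_band[1] < cfg$ripple_band[2],
    cfg$slowgamma_band[1] < cfg$slowgamma_band[2],
    cfg$wavelet_band[1] < cfg$wavelet_band[2],
    cfg$acc_win_s > 0, cfg$acc_step_s > 0,
    cfg$seq_win_s > 0, cfg$seq_step_s > 0,
    cfg$replay_win_s > 0, cfg$replay_step_s > 0,
    cfg$replay_dur_s[1] < cfg$replay_dur_s[2],
    cfg$psth_bin_s > 0, cfg$seq_n_shuffle >= 0
  )
  structure(cfg, class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>", length(x), "parameters\n")
  nm <- names(x)
  for (i in seq_along(x)) {
    cat(sprintf("  %-24s %s\n", nm[i], paste(format(x[[i]]), collapse = ", ")))
  }
  invisible(x)
}

n_bins_for <- function(cfg) as.integer(360 / cfg$bin_deg)

bin_centers_deg <- function(cfg) {
  (seq_len(n_bins_for(cfg)) - 0.5) * cfg$bin_deg
}
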