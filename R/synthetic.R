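#' Ground truth for a synthetic circular-track session
#'
#' Defines every generative parameter of the synthetic session: Gaussian
#' place tuning on the circle, theta LFP and phase-precessing spike
#' modulation during running, sparse rest firing with scripted replay
#' trajectories, and ripple oscillations coincident with replay bursts.
#' Downstream analyses are validated by recovering these parameters.
#'
#' The phase-precession model assigns each spike a preferred theta phase
#' `phi(d) = phi0 - precession_slope_deg_per_field * d`, where `d` in
#' `[0, 1]` is the normalized distance through the field (field extent
#' `4 * field_sigma_deg`), with von Mises concentration `precession_kappa`
#' around the preferred phase. Because cells at different field positions
#' then fire at different phases, each theta cycle sweeps a compressed path
#' across the track: the implied theta-sequence slope is approximately
#' `4 * field_sigma_deg * 360 * theta_f_hz / precession_slope_deg_per_field`
#' degrees per second.
#'
#' @param n_units number of simulated place cells.
#' @param field_center_deg field centers, degrees (default evenly spaced).
#' @param field_sigma_deg Gaussian tuning SD, degrees.
#' @param peak_rate_hz in-field peak firing rate, Hz.
#' @param theta_f_hz theta frequency, Hz (band of interest is 6-10 Hz).
#' @param theta_amp_uv theta LFP amplitude, microvolts.
#' @param noise_amp_uv SD of the 1/f LFP background, microvolts.
#' @param precession_slope_deg_per_field total phase advance across a field,
#'   degrees of theta phase per traversed field.
#' @param precession_kappa von Mises concentration of spike phases around
#'   the preferred phase (larger = tighter phase locking).
#' @param run_speed_cm_s running speed on the track.
#' @param pos_jitter_deg SD of smoothed tracker jitter added to the
#'   trajectory, degrees.
#' @param baseline_rest_rate_hz per-unit mean Poisson rate during rest
#'   outside replay events.
#' @param baseline_mod_cv coefficient of variation of an optional shared
#'   slow (log-normal) excitability modulation of rest baseline firing
#'   (0 = constant-rate baseline, the default study condition).
#' @param baseline_mod_tau_s correlation timescale of that modulation, s.
#' @param event_quiet_s margin around each scripted replay event in which
#'   baseline firing is suppressed, s. Population bursts rise out of
#'   relative quiescence; without this margin the burst-bounding rule
#'   (crossings of the mean population rate) attaches unrelated baseline
#'   spikes to the event edges.
#' @param event_quiet_factor multiplier on baseline rate inside the quiet
#'   margin.
#' @param replay_peak_rate_hz per-unit peak rate while a scripted replay
#'   trajectory crosses the unit's field.
#' @param replay_sigma_deg tuning SD used during replay events, degrees.
#' @param replay_speed_deg_s scripted replay trajectory speed, deg/s.
#' @param replay_dur_s scripted replay event duration, s.
#' @param replay_gap_s minimum spacing between scheduled replay events, s.
#' @param ripple_f_hz ripple oscillation frequency during replay events, Hz.
#' @param ripple_amp_uv peak ripple amplitude, microvolts.
#' @param rng_seed integer seed making the whole generated day reproducible.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(n_units = 60,
                         field_center_deg = NULL,
                         field_sigma_deg = 15,
                         peak_rate_hz = 10,
                         theta_f_hz = 8,
                         theta_amp_uv = 150,
                         noise_amp_uv = 40,
                         precession_slope_deg_per_field = 360,
                         precession_kappa = 2,
                         run_speed_cm_s = 30,
                         pos_jitter_deg = 1,
                         baseline_rest_rate_hz = 1,
                         baseline_mod_cv = 0,
                         baseline_mod_tau_s = 0.25,
                         event_quiet_s = 0.15,
                         event_quiet_factor = 0.02,
                         replay_peak_rate_hz = 80,
                         replay_sigma_deg = 15,
                         replay_speed_deg_s = 600,
                         replay_dur_s = 0.2,
                         replay_gap_s = 1,
                         ripple_f_hz = 180,
                         ripple_amp_uv = 120,
                         rng_seed = 1L) {
  if (is.null(field_center_deg)) {
    field_center_deg <- seq(0, 360, length.out = n_units + 1)[seq_len(n_units)]
  }
  n_units <- length(field_center_deg)
  gt <- list(
    n_units = n_units,
    field_center_deg = field_center_deg,
    field_sigma_deg = rep_len(field_sigma_deg, n_units),
    peak_rate_hz = rep_len(peak_rate_hz, n_units),
    theta_f_hz = theta_f_hz,
    theta_amp_uv = theta_amp_uv,
    noise_amp_uv = noise_amp_uv,
    precession_slope_deg_per_field = precession_slope_deg_per_field,
    precession_kappa = precession_kappa,
    run_speed_cm_s = run_speed_cm_s,
    pos_jitter_deg = pos_jitter_deg,
    baseline_rest_rate_hz = baseline_rest_rate_hz,
    baseline_mod_cv = baseline_mod_cv,
    baseline_mod_tau_s = baseline_mod_tau_s,
    event_quiet_s = event_quiet_s,
    event_quiet_factor = event_quiet_factor,
    replay_peak_rate_hz = replay_peak_rate_hz,
    replay_sigma_deg = replay_sigma_deg,
    replay_speed_deg_s = replay_speed_deg_s,
    replay_dur_s = replay_dur_s,
    replay_gap_s = replay_gap_s,
    ripple_f_hz = ripple_f_hz,
    ripple_amp_uv = ripple_amp_uv,
    rng_seed = as.integer(rng_seed),
    replay_events = NULL
  )
  stopifnot(all(gt$field_sigma_deg > 0), all(gt$peak_rate_hz >= 0),
            gt$theta_f_hz > 0, gt$precession_kappa >= 0,
            gt$replay_dur_s > 0, gt$replay_speed_deg_s > 0)
  structure(gt, class = "ground_truth")
}

#' Preset ground truths emulating the two genotypes
#'
#' `"wt"` uses the generator defaults; `"fxs"` lowers the replay trajectory
#' speed, lengthens replay events, lowers in-event firing, lowers the ripple
#' frequency, and spreads the within-cycle theta sweep over more theta phase
#' (lower implied sequence slope) -- the direction of every group contrast
#' the pipeline is expected to resolve.
#'
#' @param preset `"wt"` or `"fxs"`.
#' @param rng_seed seed passed through to [ground_truth()].
#' @param ... further overrides forwarded to [ground_truth()].
#' @return a `ground_truth`.
#' @export
preset_ground_truth <- function(preset = c("wt", "fxs"), rng_seed = 1L, ...) {
  preset <- match.arg(preset)
  if (preset == "wt") {
    ground_truth(rng_seed = rng_seed, ...)
  } else {
    ground_truth(replay_speed_deg_s = 350,
                 replay_dur_s = 0.35,
                 replay_peak_rate_hz = 45,
                 ripple_f_hz = 165,
                 precession_slope_deg_per_field = 640,
                 rng_seed = rng_seed, ...)
  }
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>\n")
  cat(sprintf("  %d units, field sigma %.1f deg, peak %.1f Hz\n",
              x$n_units, mean(x$field_sigma_deg), mean(x$peak_rate_hz)))
  cat(sprintf("  theta %.1f Hz, precession %.0f deg/field (kappa %.1f)\n",
              x$theta_f_hz, x$precession_slope_deg_per_field,
              x$precession_kappa))
  cat(sprintf("  replay %.0f deg/s x %.0f ms, ripple %.0f Hz, seed %d\n",
              x$replay_speed_deg_s, 1000 * x$replay_dur_s, x$ripple_f_hz,
              x$rng_seed))
  if (!is.null(x$replay_events)) {
    cat(sprintf("  %d scripted replay events\n", nrow(x$replay_events)))
  }
  invisible(x)
}

serialize_ground_truth <- function(gt) {
  out <- unclass(gt)
  if (!is.null(out$replay_events)) {
    out$replay_events <- lapply(seq_len(nrow(gt$replay_events)), function(i) {
      as.list(gt$replay_events[i, ])
    })
  }
  out
}

deserialize_ground_truth <- function(x) {
  ev <- x$replay_events
  x$replay_events <- NULL
  gt <- do.call(ground_truth, x[setdiff(names(x),
                                        c("n_units", "replay_events"))])
  if (!is.null(ev)) {
    gt$replay_events <- do.call(rbind, lapply(ev, as.data.frame))
  }
  gt
}

# 1/f ("pink") Gaussian noise via spectral shaping, scaled to SD = amp.
pink_noise <- function(n, amp) {
  if (amp <= 0 || n < 4) return(numeric(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)                   # two-sided frequency index
  W <- W / sqrt(f)
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  amp * (x - mean(x)) / stats::sd(x)
}

# Inhomogeneous Poisson spike times on [t0, t0 + duration) by thinning.
# rate_fn(t) must be vectorized and bounded by rate_max.
poisson_thin <- function(rate_fn, rate_max, t0, duration) {
  if (rate_max <= 0 || duration <= 0) return(numeric(0))
  n_cand <- stats::rpois(1, rate_max * duration)
  if (n_cand == 0) return(numeric(0))
  tc <- sort(stats::runif(n_cand, t0, t0 + duration))
  keep <- stats::runif(n_cand) < rate_fn(tc) / rate_max
  tc[keep]
}

#' Simulate a track-running epoch
#'
#' Constant-speed unidirectional running with smoothed tracker jitter, a
#' theta-frequency LFP over 1/f background noise, and place-cell spikes from
#' an inhomogeneous Poisson process (thinning): Gaussian place tuning
#' multiplied by a von Mises theta modulation whose preferred phase advances
#' linearly with normalized distance through the field (phase precession).
#'
#' @param gt a [ground_truth()].
#' @param duration_s epoch length, s.
#' @param t_start_s absolute start time of the epoch, s.
#' @param start_angle_deg track angle at epoch start.
#' @param track_circumference_cm track circumference.
#' @return list with `position` (data.frame `t`, `angle_deg`), `spike_t`
#'   (list of per-unit spike-time vectors) and `lfp_uv` (2,000 Hz samples).
#'   Uses the current RNG state; seed externally (or via [make_day()]).
#' @export
simulate_run_epoch <- function(gt, duration_s, t_start_s = 0,
                               start_angle_deg = 0,
                               track_circumference_cm = 100 * pi) {
  stopifnot(duration_s > 0)
  fs_pos <- 29.97
  fs_lfp <- 2000
  omega <- gt$run_speed_cm_s * 360 / track_circumference_cm   # deg/s
  tp <- t_start_s + seq(0, duration_s - 1 / fs_pos, by = 1 / fs_pos)
  jit <- smooth_linear(stats::rnorm(length(tp), 0, gt$pos_jitter_deg * 3), 5)
  ang_unwrapped <- start_angle_deg + omega * (tp - t_start_s) + jit
  position <- data.frame(t = tp, angle_deg = wrap_deg(ang_unwrapped))

  # analytic angle/phase used by the intensity (jitter interpolated)
  angle_at <- function(t) {
    start_angle_deg + omega * (t - t_start_s) +
      stats::approx(tp, jit, xout = t, rule = 2)$y
  }
  phase_at <- function(t) wrap_deg(360 * gt$theta_f_hz * (t - t_start_s))

  kappa <- gt$precession_kappa
  i0 <- besselI(kappa, 0)
  extent <- 4 * gt$field_sigma_deg
  spike_t <- vector("list", gt$n_units)
  for (j in seq_len(gt$n_units)) {
    cj <- gt$field_center_deg[j]
    sj <- gt$field_sigma_deg[j]
    pk <- gt$peak_rate_hz[j]
    ext <- extent[j]
    rate_fn <- function(t) {
      x <- angle_at(t)
      d <- circ_dist_deg(x, cj)
      place <- pk * exp(-d^2 / (2 * sj^2))
      # normalized progress through the field along the running direction
      dprog <- pmin(1, pmax(0, (circ_diff_deg(x, cj) + ext / 2) / ext))
      phi_pref <- (180 + gt$precession_slope_deg_per_field / 2) -
        gt$precession_slope_deg_per_field * dprog
      mod <- exp(kappa * cos(deg2rad(phase_at(t) - phi_pref))) / i0
      place * mod
    }
    spike_t[[j]] <- poisson_thin(rate_fn, pk * exp(kappa) / i0,
                                 t_start_s, duration_s)
  }
  n_lfp <- round(duration_s * fs_lfp)
  tl <- t_start_s + (seq_len(n_lfp) - 1) / fs_lfp
  lfp <- gt$theta_amp_uv * cos(deg2rad(phase_at(tl))) +
    pink_noise(n_lfp, gt$noise_amp_uv)
  list(position = position, spike_t = spike_t, lfp_uv = lfp)
}

#' Simulate a run epoch with scripted within-cycle sweeps
#'
#' Alternative run-epoch generator in which the represented position sweeps
#' around the rat's actual position at a scripted, constant rate within
#' every theta cycle (the compressed path a theta sequence codes), instead
#' of arising from the phase-precession model. Spike intensity is the
#' Gaussian place tuning evaluated at the swept position, multiplied by a
#' von Mises theta envelope that concentrates spiking mid-cycle. Used for
#' slope-recovery validation where the decoded trajectory slope must be
#' known exactly.
#'
#' @param gt a [ground_truth()].
#' @param duration_s epoch length, s.
#' @param sweep_slope_deg_s scripted within-cycle sweep rate, deg/s (the
#'   target theta-sequence slope).
#' @param sweep_peak_hz peak firing rate at the swept position, Hz.
#' @param envelope_kappa concentration of the mid-cycle theta envelope.
#' @param t_start_s,start_angle_deg,track_circumference_cm as in
#'   [simulate_run_epoch()].
#' @return list with `position`, `spike_t`, `lfp_uv` as in
#'   [simulate_run_epoch()].
#' @export
simulate_sweep_run <- function(gt, duration_s, sweep_slope_deg_s,
                               sweep_peak_hz = 40,
                               envelope_kappa = 0.5,
                               t_start_s = 0, start_angle_deg = 0,
                               track_circumference_cm = 100 * pi) {
  stopifnot(duration_s > 0, sweep_slope_deg_s != 0)
  fs_pos <- 29.97
  fs_lfp <- 2000
  omega <- gt$run_speed_cm_s * 360 / track_circumference_cm
  tp <- t_start_s + seq(0, duration_s - 1 / fs_pos, by = 1 / fs_pos)
  jit <- smooth_linear(stats::rnorm(length(tp), 0, gt$pos_jitter_deg * 3), 5)
  position <- data.frame(
    t = tp, angle_deg = wrap_deg(start_angle_deg + omega * (tp - t_start_s) + jit))
  angle_at <- function(t) {
    start_angle_deg + omega * (t - t_start_s) +
      stats::approx(tp, jit, xout = t, rule = 2)$y
  }
  f <- gt$theta_f_hz
  phase_at <- function(t) wrap_deg(360 * f * (t - t_start_s))
  # represented position: sweeps through the rat's position mid-cycle
  rep_pos_at <- function(t) {
    tr <- t - t_start_s
    t_mid <- (floor(tr * f) + 0.5) / f
    angle_at(t) + sweep_slope_deg_s * (tr - t_mid)
  }
  i0 <- besselI(envelope_kappa, 0)
  spike_t <- vector("list", gt$n_units)
  rate_max <- sweep_peak_hz * exp(envelope_kappa) / i0
  for (j in seq_len(gt$n_units)) {
    cj <- gt$field_center_deg[j]
    sj <- gt$field_sigma_deg[j]
    rate_fn <- function(t) {
      d <- circ_dist_deg(rep_pos_at(t), cj)
      env <- exp(envelope_kappa * cos(deg2rad(phase_at(t) - 180))) / i0
      sweep_peak_hz * exp(-d^2 / (2 * sj^2)) * env
    }
    spike_t[[j]] <- poisson_thin(rate_fn, rate_max, t_start_s, duration_s)
  }
  n_lfp <- round(duration_s * fs_lfp)
  tl <- t_start_s + (seq_len(n_lfp) - 1) / fs_lfp
  lfp <- gt$theta_amp_uv * cos(deg2rad(phase_at(tl))) +
    pink_noise(n_lfp, gt$noise_amp_uv)
  list(position = position, spike_t = spike_t, lfp_uv = lfp)
}

#' Tuning model from the generator's true place fields
#'
#' Builds the decoder's expected-rate matrix directly from the scripted
#' Gaussian tuning curves (peak rate and field width per unit) instead of
#' estimating rate maps from spikes.
#'
#' @param gt a [ground_truth()].
#' @param cfg an [analysis_config()] (binning).
#' @param peak_hz optional peak rate override (e.g. the sweep peak used to
#'   generate the data).
#' @return a [tuning_model()].
#' @export
true_tuning_model <- function(gt, cfg = analysis_config(), peak_hz = NULL) {
  centers <- bin_centers_deg(cfg)
  pk <- if (is.null(peak_hz)) gt$peak_rate_hz else rep_len(peak_hz, gt$n_units)
  tun <- do.call(rbind, lapply(seq_len(gt$n_units), function(j) {
    d <- circ_dist_deg(centers, gt$field_center_deg[j])
    pk[j] * exp(-d^2 / (2 * gt$field_sigma_deg[j]^2))
  }))
  structure(list(unit_ids = sprintf("u%02d", seq_len(gt$n_units)),
                 tuning_hz = tun,
                 bin_deg = cfg$bin_deg),
            class = "tuning_model")
}

#' Schedule non-overlapping replay events within a rest epoch
#'
#' @param gt a [ground_truth()].
#' @param duration_s rest epoch length, s.
#' @param n_events number of events to script.
#' @param margin_s keep-out margin at the epoch edges, s.
#' @return data.frame with `start_s` (relative to epoch start), `duration_s`,
#'   `start_angle_deg`, `speed_deg_s`, `direction` (+1/-1).
#' @export
schedule_replay_events <- function(gt, duration_s, n_events,
                                   margin_s = 1) {
  if (n_events == 0) {
    return(data.frame(start_s = numeric(0), duration_s = numeric(0),
                      start_angle_deg = numeric(0), speed_deg_s = numeric(0),
                      direction = numeric(0)))
  }
  span <- duration_s - 2 * margin_s - gt$replay_dur_s
  need <- n_events * (gt$replay_dur_s + gt$replay_gap_s)
  if (span <= 0 || need > duration_s - 2 * margin_s) {
    stop("rest epoch too short for the requested replay events")
  }
  starts <- margin_s + span * (seq_len(n_events) - 0.5) / n_events
  data.frame(
    start_s = starts,
    duration_s = gt$replay_dur_s,
    start_angle_deg = stats::runif(n_events, 0, 360),
    speed_deg_s = gt$replay_speed_deg_s,
    direction = ifelse(stats::runif(n_events) < 0.8, 1, -1)
  )
}

#' Simulate a rest epoch with scripted replay events
#'
#' Baseline sparse Poisson firing in every unit; at each scripted event the
#' population fires in field-center order along a constant-speed trajectory
#' across the track, and the LFP gains an amplitude-enveloped ripple
#' oscillation over the 1/f background.
#'
#' @param gt a [ground_truth()].
#' @param duration_s epoch length, s.
#' @param events event table as from [schedule_replay_events()]; `start_s`
#'   relative to the epoch start. Must not overlap.
#' @param t_start_s absolute epoch start time, s.
#' @return list with `spike_t` (per-unit spike times), `lfp_uv`, and
#'   `events` (the realized script with absolute times).
#' @export
simulate_rest_epoch <- function(gt, duration_s, events = NULL,
                                t_start_s = 0) {
  stopifnot(duration_s > 0)
  fs_lfp <- 2000
  if (is.null(events)) {
    events <- schedule_replay_events(gt, duration_s,
                                     n_events = max(0L, floor(duration_s / 10)))
  }
  if (nrow(events) > 1) {
    o <- order(events$start_s)
    events <- events[o, ]
    if (any(events$start_s[-1] < (events$start_s + events$duration_s)[-nrow(events)])) {
      stop("scripted replay events overlap")
    }
  }
  if (nrow(events) &&
      any(events$start_s < 0 | events$start_s + events$duration_s > duration_s)) {
    stop("scripted replay event falls outside the rest epoch")
  }
  # shared slow excitability modulation: rest firing is phasic, with the
  # whole population waxing and waning together
  grid <- seq(0, duration_s, by = 0.01)
  if (gt$baseline_mod_cv > 0 && length(grid) > 10) {
    sz <- sqrt(log(1 + gt$baseline_mod_cv^2))
    z <- smooth_linear(stats::rnorm(length(grid)),
                       gt$baseline_mod_tau_s / 0.01)
    z <- z / stats::sd(z) * sz
    m <- exp(z - sz^2 / 2)
  } else {
    m <- rep(1, length(grid))
  }
  # suppress baseline in a margin around each scripted burst: population
  # bursts rise out of relative quiescence
  if (nrow(events)) {
    for (k in seq_len(nrow(events))) {
      hit <- grid >= events$start_s[k] - gt$event_quiet_s &
        grid <= events$start_s[k] + events$duration_s[k] + gt$event_quiet_s
      m[hit] <- m[hit] * gt$event_quiet_factor
    }
  }
  mfun <- stats::approxfun(t_start_s + grid, m, rule = 2)
  base_max <- gt$baseline_rest_rate_hz * max(m)
  spike_t <- vector("list", gt$n_units)
  for (j in seq_len(gt$n_units)) {
    spike_t[[j]] <- poisson_thin(function(t) gt$baseline_rest_rate_hz *
                                   mfun(t),
                                 base_max, t_start_s, duration_s)
  }
  n_lfp <- round(duration_s * fs_lfp)
  lfp <- pink_noise(n_lfp, gt$noise_amp_uv)
  tl_rel <- (seq_len(n_lfp) - 1) / fs_lfp
  for (k in seq_len(nrow(events))) {
    e0 <- t_start_s + events$start_s[k]
    dur <- events$duration_s[k]
    traj <- function(t) {
      wrap_deg(events$start_angle_deg[k] +
                 events$direction[k] * events$speed_deg_s[k] * (t - e0))
    }
    for (j in seq_len(gt$n_units)) {
      cj <- gt$field_center_deg[j]
      rate_fn <- function(t) {
        d <- circ_dist_deg(traj(t), cj)
        gt$replay_peak_rate_hz * exp(-d^2 / (2 * gt$replay_sigma_deg^2))
      }
      s <- poisson_thin(rate_fn, gt$replay_peak_rate_hz, e0, dur)
      if (length(s)) spike_t[[j]] <- sort(c(spike_t[[j]], s))
    }
    sel <- tl_rel >= events$start_s[k] & tl_rel < events$start_s[k] + dur
    tt <- tl_rel[sel] - events$start_s[k]
    env <- sin(pi * tt / dur)^2                     # Hann envelope
    lfp[sel] <- lfp[sel] +
      gt$ripple_amp_uv * env * cos(2 * pi * gt$ripple_f_hz * tt)
  }
  events$start_abs_s <- t_start_s + events$start_s
  list(spike_t = spike_t, lfp_uv = lfp, events = events)
}

#' Assemble a full synthetic recording day
#'
#' Builds the interleaved schedule rest1, run1, rest2, ..., run4, rest5 and
#' simulates every epoch, returning a validated [place_session()] with the
#' full ground truth (including the realized replay script) attached. The
#' position trace is constant during rest epochs (the rat sits in the
#' flowerpot). Deterministic given `gt$rng_seed`.
#'
#' @param gt a [ground_truth()].
#' @param run_s,rest_s epoch durations, s (defaults: the 10 min epochs of
#'   the emulated protocol).
#' @param events_per_rest scripted replay events per rest epoch.
#' @param track_circumference_cm track circumference.
#' @param cfg an [analysis_config()].
#' @return a `place_session`.
#' @export
make_day <- function(gt, run_s = 600, rest_s = 600,
                     events_per_rest = max(0L, floor(rest_s / 10)),
                     track_circumference_cm = 100 * pi,
                     cfg = analysis_config()) {
  set.seed(gt$rng_seed)
  labels <- c("rest1", "run1", "rest2", "run2", "rest3", "run3",
              "rest4", "run4", "rest5")
  durs <- ifelse(grepl("^run", labels), run_s, rest_s)
  starts <- cumsum(c(0, durs[-length(durs)]))
  schedule <- data.frame(label = labels, start_s = starts,
                         end_s = starts + durs)
  fs_pos <- 29.97
  pos_list <- list()
  spike_t <- rep(list(numeric(0)), gt$n_units)
  lfp <- numeric(0)
  all_events <- list()
  angle <- 0
  for (i in seq_along(labels)) {
    if (grepl("^run", labels[i])) {
      ep <- simulate_run_epoch(gt, durs[i], t_start_s = starts[i],
                               start_angle_deg = angle,
                               track_circumference_cm = track_circumference_cm)
      pos_list[[i]] <- ep$position
      angle <- ep$position$angle_deg[nrow(ep$position)]
      for (j in seq_len(gt$n_units)) {
        spike_t[[j]] <- c(spike_t[[j]], ep$spike_t[[j]])
      }
      lfp <- c(lfp, ep$lfp_uv)
    } else {
      ev <- schedule_replay_events(gt, durs[i], events_per_rest)
      ep <- simulate_rest_epoch(gt, durs[i], events = ev,
                                t_start_s = starts[i])
      tp <- starts[i] + seq(0, durs[i] - 1 / fs_pos, by = 1 / fs_pos)
      pos_list[[i]] <- data.frame(t = tp, angle_deg = rep(angle, length(tp)))
      for (j in seq_len(gt$n_units)) {
        spike_t[[j]] <- c(spike_t[[j]], ep$spike_t[[j]])
      }
      lfp <- c(lfp, ep$lfp_uv)
      if (nrow(ep$events)) {
        ep$events$rest_label <- labels[i]
        all_events[[length(all_events) + 1]] <- ep$events
      }
    }
  }
  gt$replay_events <- if (length(all_events)) {
    do.call(rbind, all_events)
  }
  position <- do.call(rbind, pos_list)
  units <- lapply(seq_len(gt$n_units), function(j) {
    list(unit_id = sprintf("u%02d", j), spike_t = sort(spike_t[[j]]))
  })
  place_session(
    position = position,
    units = units,
    lfp = list(list(fs_hz = 2000, samples = lfp, t0 = 0)),
    schedule = schedule,
    track_circumference_cm = track_circumference_cm,
    ground_truth = gt,
    cfg = cfg
  )
}
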