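# Core circular-linear trajectory fit shared by theta sequences and replay:
# slope/intercept from resultant maximization, r^2 from circular variances,
# 1 - var(shortest-arc residuals) / var(COM angles).
fit_com_line <- function(t_rel, com_deg, slope_bounds) {
  fit <- circ_lin_fit(t_rel, com_deg, slope_bounds = slope_bounds)
  pred <- fit$slope * t_rel + fit$intercept_deg
  resid <- circ_diff_deg(com_deg, pred)
  v_tot <- circ_var(com_deg)
  r2 <- if (v_tot < 1e-12) 0 else max(0, min(1, 1 - circ_var(resid) / v_tot))
  list(slope = fit$slope, intercept_deg = fit$intercept_deg, r2 = r2)
}

#' Segment theta cycles at the sparsest spike phase
#'
#' Builds a histogram of place-cell spike theta phases (20-degree bins) over
#' speed-passing run times, takes the phase bin with the fewest spikes (ties
#' resolved toward the smallest phase) as the cutting phase, and cuts the
#' unwrapped theta phase at every crossing of that phase, so each cycle
#' keeps the population burst intact.
#'
#' @param phase a `phase_series` from [theta_filter_phase()].
#' @param spike_t pooled place-cell spike times (s).
#' @param epochs data.frame of run epochs (`start_s`, `end_s`).
#' @param position position trace (for the speed gate on histogram spikes).
#' @param cfg an [analysis_config()].
#' @return data.frame of cycles (`start_s`, `end_s`) with the cutting phase
#'   in attribute `"cut_phase_deg"`.
#' @export
segment_theta_cycles <- function(phase, spike_t, epochs, position,
                                 cfg = analysis_config()) {
  keep <- rep(FALSE, length(spike_t))
  for (i in seq_len(nrow(epochs))) {
    keep <- keep | (spike_t >= epochs$start_s[i] & spike_t < epochs$end_s[i])
  }
  st <- spike_t[keep]
  st <- st[speed_at_time(position, st) > cfg$speed_min]
  if (!length(st)) stop("no spikes available to locate the cutting phase")
  ph <- phase_at_time(phase, st)
  nb <- as.integer(360 / cfg$cycle_phase_bin_deg)
  counts <- tabulate(pmin(nb, floor(ph / cfg$cycle_phase_bin_deg) + 1L), nb)
  cut <- (which.min(counts) - 0.5) * cfg$cycle_phase_bin_deg
  out <- list()
  for (i in seq_len(nrow(epochs))) {
    sel <- phase$t >= epochs$start_s[i] & phase$t < epochs$end_s[i]
    if (sum(sel) < 2) next
    tt <- phase$t[sel]
    u <- unwrap_deg(phase$phase_deg[sel])
    k <- floor((u - cut) / 360)
    cross <- which(diff(k) >= 1)
    if (length(cross) < 2) next
    # linear interpolation of each crossing time
    tc <- tt[cross] + (tt[cross + 1] - tt[cross]) *
      ((k[cross + 1] * 360 + cut) - u[cross]) / (u[cross + 1] - u[cross])
    out[[length(out) + 1]] <- data.frame(start_s = tc[-length(tc)],
                                         end_s = tc[-1])
  }
  cycles <- if (length(out)) do.call(rbind, out) else
    data.frame(start_s = numeric(0), end_s = numeric(0))
  attr(cycles, "cut_phase_deg") <- cut
  cycles
}

#' Circular-linear fit of a decoded trajectory
#'
#' Computes the posterior-weighted circular center of mass of each decoding
#' window and regresses it (circular) on window-center time (linear).
#' `r^2 = 1 - V(residuals) / V(COM)` with `V` the circular variance and
#' residuals the shortest-arc distances to the line; it reduces to the
#' ordinary coefficient of determination in the small-angle limit. The
#' x-span is `|slope| * t_span`, the extent of the regression line over the
#' fitted windows.
#'
#' @param dec a `decoded_posterior`.
#' @param cfg an [analysis_config()].
#' @param slope_bounds admissible slopes, deg/s (default
#'   `cfg$seq_slope_bounds`).
#' @param min_windows minimum usable windows (3 for theta sequences; replay
#'   classification uses 2).
#' @param track_circumference_cm for the cm conversions.
#' @return object of class `sequence_fit` (or `NULL` if fewer than
#'   `min_windows` usable windows): `slope_deg_s`, `slope_cm_s`,
#'   `intercept_deg`, `r2`, `x_span_deg`, `x_span_cm`, `t_span_s`,
#'   `com_deg`, `t_s`, `n_windows`.
#' @export
fit_decoded_trajectory <- function(dec, cfg = analysis_config(),
                                   slope_bounds = cfg$seq_slope_bounds,
                                   min_windows = 3L,
                                   track_circumference_cm = 100 * pi) {
  nb <- ncol(dec$posterior)
  centers <- (seq_len(nb) - 0.5) * dec$bin_deg
  com <- apply(dec$posterior, 1, function(p) {
    if (!all(is.finite(p)) || sum(p) <= 0) return(NA_real_)
    circ_mean_deg(centers, p)
  })
  ok <- is.finite(com)
  if (sum(ok) < min_windows) return(NULL)
  t_s <- dec$window_centers_s[ok]
  com <- com[ok]
  t_rel <- t_s - t_s[1]
  f <- fit_com_line(t_rel, com, slope_bounds)
  t_span <- t_rel[length(t_rel)]
  cm_per_deg <- track_circumference_cm / 360
  structure(list(slope_deg_s = f$slope,
                 slope_cm_s = f$slope * cm_per_deg,
                 intercept_deg = f$intercept_deg,
                 r2 = f$r2,
                 x_span_deg = abs(f$slope) * t_span,
                 x_span_cm = abs(f$slope) * t_span * cm_per_deg,
                 t_span_s = t_span,
                 com_deg = com,
                 t_s = t_s,
                 n_windows = length(t_s)),
            class = "sequence_fit")
}

#' @export
print.sequence_fit <- function(x, ...) {
  cat(sprintf("<sequence_fit> %d windows: slope %.0f deg/s, x-span %.1f deg, t-span %.0f ms, r2=%.3f\n",
              x$n_windows, x$slope_deg_s, x$x_span_deg, 1000 * x$t_span_s,
              x$r2))
  invisible(x)
}

#' Circular-shuffle significance test of a trajectory fit
#'
#' Each of `n` shuffles independently rotates every decoding window's
#' posterior by a uniformly random number of position bins and refits the
#' circular-linear regression; the returned p-value is the fraction of
#' shuffles whose r-squared reaches the observed one. Rotating a posterior
#' on the equispaced circular bin grid rotates its circular center of mass
#' by exactly the shift, so the refits operate on shifted centers of mass
#' (identical, and much cheaper, than recomputing them from rotated
#' posteriors).
#'
#' @param fit a `sequence_fit`.
#' @param n_bins number of position bins of the posterior.
#' @param bin_deg bin width, degrees.
#' @param n number of shuffles.
#' @param slope_bounds slope bounds used for the refits, deg/s.
#' @param seed optional seed; when `NULL` the current RNG state is used.
#' @return shuffle p-value in `[1/(n+1), 1]`.
#' @export
shuffle_test <- function(fit, n_bins = 90L, bin_deg = 4,
                         n = 1000L, slope_bounds = c(-3000, 3000),
                         seed = NULL) {
  force(fit)
  if (!is.null(seed)) set.seed(seed)
  t_rel <- fit$t_s - fit$t_s[1]
  w <- length(t_rel)
  shifts <- matrix(sample.int(n_bins, n * w, replace = TRUE) - 1L, n, w)
  r2s <- numeric(n)
  for (s in seq_len(n)) {
    com_s <- wrap_deg(fit$com_deg + shifts[s, ] * bin_deg)
    r2s[s] <- fit_com_line(t_rel, com_s, slope_bounds)$r2
  }
  # add-one estimator keeps the p-value away from an exact zero
  (sum(r2s >= fit$r2) + 1) / (n + 1)
}

# Posterior mass within dist_deg of the fitted line, as a fraction of the
# total posterior over the fitted windows.
posterior_near_line <- function(dec, fit, dist_deg) {
  nb <- ncol(dec$posterior)
  centers <- (seq_len(nb) - 0.5) * dec$bin_deg
  idx <- match(fit$t_s, dec$window_centers_s)
  t_rel <- fit$t_s - fit$t_s[1]
  pred <- fit$slope_deg_s * t_rel + fit$intercept_deg
  num <- 0; den <- 0
  for (i in seq_along(idx)) {
    p <- dec$posterior[idx[i], ]
    num <- num + sum(p[circ_dist_deg(centers, pred[i]) <= dist_deg])
    den <- den + sum(p)
  }
  num / den
}

#' Detect and quantify theta sequences
#'
#' For every theta cycle in which at least `cfg$seq_min_cells` place cells
#' fired while the rat ran faster than the speed gate: decodes the cycle in
#' partially overlapping 40 ms windows stepped by 10 ms, restricts to the
#' longest set of contiguous windows (contiguity breaks at
#' `cfg$seq_gap_bins` consecutive spikeless windows), fits the
#' circular-linear trajectory, and assesses significance by the circular
#' shuffle test plus two posterior-concentration criteria: at least
#' `cfg$seq_prob_frac` of the posterior within `cfg$seq_prob_dist_deg` of
#' the line, and a minimum line-to-actual-position distance below
#' `cfg$seq_actual_dist_deg`.
#'
#' @param session a `place_session` (must have passed the decoding gate for
#'   scientific use; not enforced here).
#' @param model a [tuning_model()].
#' @param cfg an [analysis_config()]; set `seq_n_shuffle = 0` to skip the
#'   significance machinery (slope/r2 recovery runs).
#' @param phase optional precomputed `phase_series`.
#' @param cycles optional precomputed cycle table.
#' @param max_cycles cap on the number of qualifying cycles analyzed (keeps
#'   exploratory runs fast); `Inf` analyzes all.
#' @return data.frame, one row per fitted cycle: times, `n_active`,
#'   `mean_speed_cm_s`, `n_windows`, `slope_deg_s`, `slope_cm_s`,
#'   `x_span_deg`, `x_span_cm`, `t_span_s`, `r2`, `shuffle_p`,
#'   `prob_near_line_frac`, `min_dist_to_actual_deg`, `significant`.
#' @export
detect_theta_sequences <- function(session, model, cfg = analysis_config(),
                                   phase = NULL, cycles = NULL,
                                   max_cycles = Inf) {
  if (is.null(phase)) phase <- theta_filter_phase(session$lfp[[1]], cfg = cfg)
  spk <- model_spikes(session, model)
  runs <- session$schedule[grepl("^run", session$schedule$label),
                           c("start_s", "end_s")]
  if (is.null(cycles)) {
    cycles <- segment_theta_cycles(phase, sort(unlist(spk)), runs,
                                   session$position, cfg)
  }
  empty <- data.frame(
    cycle_start_s = numeric(0), cycle_end_s = numeric(0),
    n_active = integer(0), mean_speed_cm_s = numeric(0),
    n_windows = integer(0), slope_deg_s = numeric(0), slope_cm_s = numeric(0),
    x_span_deg = numeric(0), x_span_cm = numeric(0), t_span_s = numeric(0),
    r2 = numeric(0), shuffle_p = numeric(0),
    prob_near_line_frac = numeric(0), min_dist_to_actual_deg = numeric(0),
    significant = logical(0))
  if (!nrow(cycles)) return(empty)
  circum <- session$track_circumference_cm
  rows <- list()
  for (i in seq_len(nrow(cycles))) {
    if (length(rows) >= max_cycles) break
    c0 <- cycles$start_s[i]; c1 <- cycles$end_s[i]
    n_active <- sum(vapply(spk, function(s) any(s >= c0 & s < c1),
                           logical(1)))
    if (n_active < cfg$seq_min_cells) next
    sp_sel <- session$position$t >= c0 & session$position$t <= c1
    spd <- if (any(sp_sel)) mean(session$position$speed_cm_s[sp_sel]) else
      speed_at_time(session$position, (c0 + c1) / 2)
    if (spd < cfg$speed_min) next
    win <- make_windows(c0, c1, cfg$seq_win_s, cfg$seq_step_s)
    if (nrow(win) < 3) next
    dec <- decode_posterior(model, spk, win, cfg)
    use <- longest_contiguous(dec$n_spikes > 0, cfg$seq_gap_bins)
    if (length(use) < 3) next
    sub <- subset_posterior(dec, use)
    fit <- fit_decoded_trajectory(sub, cfg,
                                  slope_bounds = cfg$seq_slope_bounds,
                                  track_circumference_cm = circum)
    if (is.null(fit)) next
    if (cfg$seq_n_shuffle > 0) {
      p <- shuffle_test(fit, n_bins = ncol(sub$posterior),
                        bin_deg = sub$bin_deg, n = cfg$seq_n_shuffle,
                        slope_bounds = cfg$seq_slope_bounds)
      frac <- posterior_near_line(sub, fit, cfg$seq_prob_dist_deg)
      pred <- fit$slope_deg_s * (fit$t_s - fit$t_s[1]) + fit$intercept_deg
      actual <- angle_at_time(session$position, fit$t_s)
      mind <- min(circ_dist_deg(pred, actual))
      sig <- p < cfg$seq_alpha && frac >= cfg$seq_prob_frac &&
        mind < cfg$seq_actual_dist_deg
    } else {
      p <- NA_real_; frac <- NA_real_; mind <- NA_real_; sig <- NA
    }
    rows[[length(rows) + 1]] <- data.frame(
      cycle_start_s = c0, cycle_end_s = c1, n_active = n_active,
      mean_speed_cm_s = spd, n_windows = fit$n_windows,
      slope_deg_s = fit$slope_deg_s, slope_cm_s = fit$slope_cm_s,
      x_span_deg = fit$x_span_deg, x_span_cm = fit$x_span_cm,
      t_span_s = fit$t_span_s, r2 = fit$r2, shuffle_p = p,
      prob_near_line_frac = frac, min_dist_to_actual_deg = mind,
      significant = sig)
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

# Longest run of window indices not interrupted by `gap` consecutive FALSE
# values; leading/trailing FALSE windows are trimmed from the run.
longest_contiguous <- function(has_spikes, gap = 2L) {
  n <- length(has_spikes)
  if (!any(has_spikes)) return(integer(0))
  r <- rle(has_spikes)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # break the index range at every empty run of length >= gap
  breaks <- which(!r$values & r$lengths >= gap)
  seg_bounds <- c(0L, ends[breaks], n)
  best <- integer(0)
  for (k in seq_len(length(seg_bounds) - 1L)) {
    lo <- seg_bounds[k] + 1L
    hi <- seg_bounds[k + 1L]
    if (lo > hi) next
    idx <- lo:hi
    idx <- idx[cumsum(has_spikes[idx]) > 0]              # trim leading empties
    if (!length(idx)) next
    last_spike <- max(idx[has_spikes[idx]])
    idx <- idx[idx <= last_spike]                        # trim trailing empties
    if (length(idx) > length(best)) best <- idx
  }
  best
}

subset_posterior <- function(dec, idx) {
  structure(list(windows = dec$windows[idx, , drop = FALSE],
                 window_centers_s = dec$window_centers_s[idx],
                 posterior = dec$posterior[idx, , drop = FALSE],
                 n_spikes = dec$n_spikes[idx],
                 n_active = dec$n_active[idx],
                 bin_deg = dec$bin_deg),
            class = "decoded_posterior")
}
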