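# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

# a small synthetic day exercising every pipeline stage
small_day <- function() {
  if (is.null(.fixtures$day)) {
    gt <- ground_truth(rng_seed = 42)
    .fixtures$day <- make_day(gt, run_s = 60, rest_s = 30,
                              events_per_rest = 2)
  }
  .fixtures$day
}

small_maps <- function() {
  if (is.null(.fixtures$maps)) .fixtures$maps <- day_rate_maps(small_day())
  .fixtures$maps
}

small_model <- function() {
  if (is.null(.fixtures$model)) .fixtures$model <- tuning_model(small_maps())
  .fixtures$model
}

# day report on the small day (reduced shuffle count / cycle cap keeps the
# default test run fast; the acceptance tests run the calibrated versions)
small_report <- function() {
  if (is.null(.fixtures$report)) {
    cfg <- analysis_config(seq_n_shuffle = 50, rng_seed = 42)
    .fixtures$report <- run_day(small_day(), cfg, max_cycles = 30)
  }
  .fixtures$report
}

# constant-speed position trace (deg_per_s > 0, unidirectional)
make_trace <- function(duration_s, deg_per_s, fs = 29.97, angle0 = 0) {
  t <- seq(0, duration_s, by = 1 / fs)
  data.frame(t = t, angle_deg = (angle0 + deg_per_s * t) %% 360)
}

# minimal session around explicit spike trains
make_manual_session <- function(spikes, duration_s, label = "rest1",
                                position = NULL, lfp = NULL) {
  if (is.null(position)) {
    position <- make_trace(duration_s, if (grepl("^run", label)) 36 else 0)
  }
  if (is.null(lfp)) lfp <- list()
  units <- lapply(seq_along(spikes), function(j) {
    list(unit_id = sprintf("u%02d", j), spike_t = spikes[[j]])
  })
  place_session(position, units, lfp,
                data.frame(label = label, start_s = 0, end_s = duration_s))
}

# tuning model with Gaussian fields at given centers
make_tuning <- function(centers_deg, sigma_deg = 15, peak_hz = 10,
                        cfg = analysis_config()) {
  gt <- ground_truth(n_units = length(centers_deg),
                     field_center_deg = centers_deg,
                     field_sigma_deg = sigma_deg)
  true_tuning_model(gt, cfg, peak_hz = peak_hz)
}

# hand-built rate_map object
manual_rate_map <- function(rate_hz, occupancy_s = NULL, bin_deg = NULL,
                            counts = NULL) {
  nb <- length(rate_hz)
  if (is.null(bin_deg)) bin_deg <- 360 / nb
  if (is.null(occupancy_s)) occupancy_s <- rep(1, nb)
  if (is.null(counts)) counts <- rate_hz * occupancy_s
  p <- occupancy_s / sum(occupancy_s)
  structure(list(bin_deg = bin_deg, occupancy_s = occupancy_s,
                 spike_counts = counts, raw_rate_hz = rate_hz,
                 rate_hz = rate_hz, mean_rate_hz = sum(p * rate_hz),
                 peak_rate_hz = max(rate_hz), unit_id = "m",
                 session_label = "manual"),
            class = "rate_map")
}

# start bin of a circular run of bins (wrap-aware)
min_circular_bin <- function(bins, nb = 90) {
  for (b in sort(bins)) {
    prev <- ((b - 2) %% nb) + 1
    if (!(prev %in% bins)) return(b)
  }
  min(bins)
}

# hand-built decoded posterior from a windows x bins matrix
manual_posterior <- function(post, step_s = 0.01, win_s = 0.04,
                             bin_deg = 360 / ncol(post)) {
  nw <- nrow(post)
  starts <- (seq_len(nw) - 1) * step_s
  structure(list(
    windows = data.frame(start_s = starts, end_s = starts + win_s,
                         center_s = starts + win_s / 2),
    window_centers_s = starts + win_s / 2,
    posterior = post / rowSums(post),
    n_spikes = rep(1, nw),
    n_active = rep(1, nw),
    bin_deg = bin_deg), class = "decoded_posterior")
}
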