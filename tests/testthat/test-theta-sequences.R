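test_that("theta cycles are cut at the sparsest spike phase", {
  fs <- 2000
  t <- seq(0, 10, by = 1 / fs)
  lfp <- list(fs_hz = fs, samples = cos(2 * pi * 8 * t), t0 = 0)
  ph <- theta_filter_phase(lfp)
  tr <- compute_speed(make_trace(10, 36))
  # spikes exactly at phase 180 (waveform troughs)
  spikes <- seq(0.0625, 9.9, by = 1 / 8)
  cyc <- segment_theta_cycles(ph, spikes, data.frame(start_s = 0, end_s = 10),
                              tr)
  # ~80 cycles of ~125 ms
  expect_gt(nrow(cyc), 70)
  expect_lt(nrow(cyc), 82)
  durs <- cyc$end_s - cyc$start_s
  expect_equal(median(durs), 0.125, tolerance = 0.01)
  # the cutting phase lies in the empty region (ties -> smallest phase bin)
  expect_equal(attr(cyc, "cut_phase_deg"), 10)
  # every interior cycle contains exactly one of its 180-degree spikes
  n_in <- sapply(seq_len(nrow(cyc)), function(i) {
    sum(spikes >= cyc$start_s[i] & spikes < cyc$end_s[i])
  })
  expect_true(all(n_in[2:(length(n_in) - 1)] == 1))
  expect_error(segment_theta_cycles(ph, numeric(0),
                                    data.frame(start_s = 0, end_s = 10), tr),
               "no spikes")
})

test_that("the cutting phase matches a brute-force histogram argmin", {
  fs <- 2000
  t <- seq(0, 20, by = 1 / fs)
  lfp <- list(fs_hz = fs, samples = cos(2 * pi * 8 * t), t0 = 0)
  ph <- theta_filter_phase(lfp)
  tr <- compute_speed(make_trace(20, 36))
  set.seed(12)
  # von Mises-ish spike phases concentrated near 230 degrees
  target <- wrap_deg(230 + rnorm(600, 0, 50))
  spikes <- sort((sample(0:150, 600, replace = TRUE) + target / 360) / 8)
  spikes <- spikes[spikes < 19.5]
  cyc <- segment_theta_cycles(ph, spikes, data.frame(start_s = 0, end_s = 20),
                              tr)
  realized <- phase_at_time(ph, spikes)
  oracle_counts <- tabulate(floor(realized / 20) + 1, 18)
  expect_equal(attr(cyc, "cut_phase_deg"),
               (which.min(oracle_counts) - 0.5) * 20)
})

test_that("trajectory fits are exact on noiseless linear inputs", {
  # COMs advancing 4 deg per 10 ms window -> slope 400 deg/s, r2 = 1
  nw <- 8
  post <- matrix(0, nw, 90)
  for (w in seq_len(nw)) {
    b <- w %% 90
    post[w, c(b, b + 1)] <- 0.5                  # COM at the shared bin edge
  }
  dec <- manual_posterior(post)
  fit <- fit_decoded_trajectory(dec)
  expect_equal(fit$slope_deg_s, 400, tolerance = 0.01)
  expect_gt(fit$r2, 0.9999)
  expect_equal(fit$t_span_s, (nw - 1) * 0.01)
  expect_equal(fit$x_span_deg, abs(fit$slope_deg_s) * fit$t_span_s,
               tolerance = 1e-9)
  expect_equal(fit$x_span_cm, fit$x_span_deg * 100 * pi / 360,
               tolerance = 1e-9)
  # constant-angle posteriors -> zero slope and span
  flat <- matrix(0, 5, 90); flat[, 30] <- 1
  f0 <- fit_decoded_trajectory(manual_posterior(flat))
  expect_equal(f0$slope_deg_s, 0, tolerance = 1e-3)
  expect_equal(f0$x_span_deg, 0, tolerance = 1e-4)
})

test_that("fits are rotation-invariant and time-antisymmetric", {
  set.seed(13)
  nw <- 9
  post <- matrix(rgamma(nw * 90, 0.3), nw, 90)
  for (w in seq_len(nw)) post[w, (5 + 3 * w):(9 + 3 * w)] <-
      post[w, (5 + 3 * w):(9 + 3 * w)] + 8
  dec <- manual_posterior(post)
  fit <- fit_decoded_trajectory(dec)
  k <- 17
  rot <- manual_posterior(post[, c((90 - k + 1):90, 1:(90 - k))])
  fit_rot <- fit_decoded_trajectory(rot)
  expect_equal(fit_rot$slope_deg_s, fit$slope_deg_s, tolerance = 0.1)
  expect_equal(fit_rot$r2, fit$r2, tolerance = 1e-6)
  expect_equal(fit_rot$x_span_deg, fit$x_span_deg, tolerance = 0.01)
  expect_equal(wrap_deg(fit_rot$intercept_deg - fit$intercept_deg),
               wrap_deg(k * 4), tolerance = 0.5)
  rev_dec <- manual_posterior(post[nw:1, ])
  fit_rev <- fit_decoded_trajectory(rev_dec)
  expect_equal(fit_rev$slope_deg_s, -fit$slope_deg_s, tolerance = 0.1)
  expect_equal(fit_rev$r2, fit$r2, tolerance = 1e-6)
})

test_that("rotating a posterior rotates its center of mass by the shift", {
  set.seed(14)
  p <- rgamma(90, 0.5); p <- p / sum(p)
  centers <- (1:90 - 0.5) * 4
  com <- circ_mean_deg(centers, p)
  for (k in c(1, 13, 45, 89)) {
    protk <- p[((seq_len(90) - 1 - k) %% 90) + 1]
    expect_equal(circ_mean_deg(centers, protk), wrap_deg(com + k * 4),
                 tolerance = 1e-9)
  }
})

test_that("the circular shuffle test is calibrated at the extremes and deterministic", {
  nw <- 8
  post <- matrix(0, nw, 90)
  for (w in seq_len(nw)) post[w, 3 * w] <- 1     # perfect line, r2 = 1
  fit <- fit_decoded_trajectory(manual_posterior(post))
  p1 <- shuffle_test(fit, n = 400, seed = 99)
  expect_lte(p1, 0.05)
  expect_identical(shuffle_test(fit, n = 400, seed = 99), p1)
  expect_gt(shuffle_test(fit, n = 100, seed = 1), 0)
})

test_that("contiguity breaks at two consecutive spikeless windows", {
  expect_equal(placeseq:::longest_contiguous(c(T, T, F, F, T, T, T)), 5:7)
  expect_equal(placeseq:::longest_contiguous(c(T, F, T, T)), 1:4)     # single gap kept
  expect_equal(placeseq:::longest_contiguous(c(F, T, T, F)), 2:3)     # edges trimmed
  expect_equal(placeseq:::longest_contiguous(c(T, T, T, F, F, T)), 1:3)
  expect_equal(placeseq:::longest_contiguous(rep(FALSE, 4)), integer(0))
})

test_that("scripted within-cycle sweeps are recovered at their slope", {
  gt <- ground_truth(rng_seed = 21)
  set.seed(21)
  ep <- simulate_sweep_run(gt, 25, sweep_slope_deg_s = 600)
  ses <- place_session(
    ep$position,
    lapply(seq_len(gt$n_units), function(j)
      list(unit_id = sprintf("u%02d", j), spike_t = ep$spike_t[[j]])),
    list(list(fs_hz = 2000, samples = ep$lfp_uv, t0 = 0)),
    data.frame(label = "run1", start_s = 0, end_s = 25))
  cfg <- analysis_config(seq_n_shuffle = 0)
  seqs <- detect_theta_sequences(ses, true_tuning_model(gt, peak_hz = 40),
                                 cfg, max_cycles = 40)
  expect_gt(nrow(seqs), 30)
  expect_equal(median(seqs$slope_deg_s), 600, tolerance = 0.15)
  # cycles with too few active cells are skipped
  expect_true(all(seqs$n_active >= cfg$seq_min_cells))
  expect_true(all(seqs$mean_speed_cm_s >= cfg$speed_min))
})
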