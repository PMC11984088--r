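inject_bursts <- function(f0, onsets, amp = 10, dur = 0.1, fs = 2000,
                          total = 30, noise_sd = 1) {
  x <- rnorm(total * fs, 0, noise_sd)
  for (o in onsets) {
    idx <- (o * fs):(o * fs + dur * fs)
    tt <- (idx - idx[1]) / fs
    x[idx] <- x[idx] + amp * sin(pi * tt / dur)^2 * cos(2 * pi * f0 * tt)
  }
  list(fs_hz = fs, samples = x, t0 = 0)
}

test_that("event power is z-scored per frequency and localizes injections", {
  set.seed(18)
  onsets <- c(5, 10, 15, 20, 25)
  pw <- event_power(inject_bursts(200, onsets), onsets)
  allp <- do.call(cbind, pw$per_event)
  expect_lt(max(abs(rowMeans(allp))), 1e-6)
  expect_equal(apply(allp, 1, sd), rep(1, nrow(allp)), tolerance = 1e-6)
  # peak z-power near 200 Hz after onset
  burst_cols <- pw$times_s >= 0 & pw$times_s <= 0.1
  prof <- rowMeans(pw$z_power[, burst_cols])
  expect_equal(pw$freqs_hz[which.max(prof)], 200, tolerance = 3)
  # the injected row dominates every row 20+ Hz away (raw power)
  raw <- rowMeans(pw$per_event_raw[[1]][, burst_cols])
  far <- abs(pw$freqs_hz - 200) >= 20
  expect_gt(raw[pw$freqs_hz == 200], max(raw[far]))
})

test_that("white noise produces no spuriously modulated frequency", {
  set.seed(19)
  fs <- 2000
  lfp <- list(fs_hz = fs, samples = rnorm(30 * fs), t0 = 0)
  pw <- event_power(lfp, seq(2, 28, by = 2))
  n_ev <- pw$n_events
  burst_cols <- pw$times_s >= 0 & pw$times_s <= 0.1
  m <- rowMeans(pw$z_power[, burst_cols])
  # mean z across events: SE ~ 1/sqrt(n_ev * n_indep); 3 SE bound with a
  # conservative effective-sample count
  expect_lt(max(abs(m)), 1)
})

test_that("peak ripple frequency recovers injected tones within 2 Hz", {
  set.seed(20)
  onsets <- c(5, 10, 15, 20, 25)
  for (f0 in c(180, 220)) {
    pw <- event_power(inject_bursts(f0, onsets), onsets)
    tsel <- pw$times_s >= 0 & pw$times_s <= 0.1
    pk <- sapply(pw$per_event_raw, peak_ripple_frequency,
                 freqs_hz = pw$freqs_hz, t_sel = tsel)
    expect_true(all(abs(pk - f0) <= 2))
  }
  # tie-break contract: exactly equal band power -> the lower frequency
  z <- matrix(1, 249, 10)
  expect_equal(peak_ripple_frequency(z, 2:250), 150)
})

test_that("slow gamma power reflects 25-55 Hz injections only", {
  set.seed(21)
  onsets <- c(5, 10, 15, 20, 25)
  # 40 Hz bursts on half the events
  fs <- 2000
  x <- rnorm(30 * fs)
  for (o in onsets[1:3]) {
    idx <- (o * fs):(o * fs + 0.2 * fs)
    tt <- (idx - idx[1]) / fs
    x[idx] <- x[idx] + 5 * sin(pi * tt / 0.2)^2 * cos(2 * pi * 40 * tt)
  }
  pw <- event_power(list(fs_hz = fs, samples = x, t0 = 0), onsets)
  tsel <- pw$times_s >= 0 & pw$times_s <= 0.2
  sg <- sapply(pw$per_event, slow_gamma_power, freqs_hz = pw$freqs_hz,
               t_sel = tsel)
  expect_gt(min(sg[1:3]), max(sg[4:5]))
  expect_gt(mean(sg[1:3]), 0)
  # ripple-band injection leaves slow gamma near baseline
  pwr <- event_power(inject_bursts(200, onsets), onsets)
  sgr <- sapply(pwr$per_event, slow_gamma_power, freqs_hz = pwr$freqs_hz,
                t_sel = pwr$times_s >= 0 & pwr$times_s <= 0.1)
  expect_lt(abs(mean(sgr)), 0.5)
  expect_lt(max(abs(sgr)), 1.5)
  # determinism
  pw2 <- event_power(list(fs_hz = fs, samples = x, t0 = 0), onsets)
  expect_identical(pw$z_power, pw2$z_power)
})

test_that("ripple detection counts injected bursts exactly at high SNR", {
  set.seed(22)
  lfp <- inject_bursts(180, c(4, 9, 14, 19, 24, 27))
  r <- detect_ripples(lfp)
  expect_equal(nrow(r), 6)
  expect_equal(sort(r$start_s), c(4, 9, 14, 19, 24, 27), tolerance = 0.02)
  expect_true(all(r$peak_z >= 3))
  # detection count is monotone nonincreasing in the threshold
  n_by_z <- sapply(c(2, 3, 4, 6), function(z) {
    nrow(detect_ripples(lfp, analysis_config(ripple_z = z)))
  })
  expect_true(all(diff(n_by_z) <= 0))
})

test_that("ripple intervals match an independently coded extraction", {
  set.seed(23)
  lfp <- inject_bursts(190, c(5, 12), amp = 6, total = 20)
  cfg <- analysis_config()
  got <- detect_ripples(lfp, cfg)
  # oracle: same filter/envelope, independent smoothing and interval logic
  bf <- signal::butter(4, c(150, 250) / 1000, type = "pass")
  filt <- signal::filtfilt(bf, lfp$samples)
  env <- Mod(placeseq:::hilbert_analytic(filt))
  k <- dnorm(-64:64, sd = 16); k <- k / sum(k)
  pad <- c(rep(env[1] * 0, 64), env, rep(0, 64))
  sm <- as.numeric(stats::filter(c(rep(0, 64), env, rep(0, 64)), k,
                                 sides = 2))[65:(64 + length(env))]
  den <- as.numeric(stats::filter(c(rep(0, 64), rep(1, length(env)),
                                    rep(0, 64)), k, sides = 2))[
                                      65:(64 + length(env))]
  sm <- sm / den
  z <- (sm - mean(sm)) / sd(sm)
  runs <- rle(z >= 3)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  o_start <- (starts[runs$values] - 1) / 2000
  o_end <- (ends[runs$values] - 1) / 2000
  expect_equal(got$start_s, o_start, tolerance = 1e-9)
  expect_equal(got$end_s, o_end, tolerance = 1e-9)
})

test_that("ripples are counted per overlapping event", {
  set.seed(24)
  lfp <- inject_bursts(180, c(5, 5.3, 12))
  r <- detect_ripples(lfp)
  events <- data.frame(start_s = c(4.9, 11.9, 20), end_s = c(5.5, 12.3, 21))
  counts <- count_ripples_per_event(events, r)
  expect_equal(counts, c(2L, 1L, 0L))
})

test_that("events beyond the LFP extent are dropped with a warning", {
  set.seed(25)
  lfp <- list(fs_hz = 2000, samples = rnorm(6000), t0 = 0)
  expect_warning(pw <- event_power(lfp, c(1.5, 2.9)), "dropped")
  expect_equal(pw$n_events, 1)
  expect_error(suppressWarnings(event_power(lfp, 2.95)), "no events")
})
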