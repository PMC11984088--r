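# Regularly spaced baseline spikes plus scripted bursts, for deterministic
# candidate-detection tests.
burst_session <- function(burst_t, burst_units, duration = 20,
                          n_units = 8, spikes_per_unit = 3,
                          burst_width = 0.08) {
  spikes <- lapply(seq_len(n_units), function(j) {
    base <- seq(0.05 + j * 0.013, duration - 0.05, by = 0.8)
    base <- base[sapply(base, function(b)
      all(abs(b - burst_t) > 0.3))]              # keep-out around bursts
    s <- base
    for (k in seq_along(burst_t)) {
      if (j %in% burst_units[[k]]) {
        s <- c(s, burst_t[k] + seq(0, burst_width,
                                   length.out = spikes_per_unit) +
                 j * 1e-4)
      }
    }
    sort(s)
  })
  make_manual_session(spikes, duration)
}

test_that("the merge rule combines events within 40 ms and not beyond", {
  m <- merge_close_intervals(c(1.00, 1.13), c(1.10, 1.20), 0.04)
  expect_length(m, 1)                             # 30 ms apart -> merged
  expect_equal(m[[1]], c(1.00, 1.20))
  m2 <- merge_close_intervals(c(1.00, 1.15), c(1.10, 1.25), 0.04)
  expect_length(m2, 2)                            # 50 ms apart -> two events
  m3 <- merge_close_intervals(c(1.00, 1.14), c(1.10, 1.25), 0.04)
  expect_length(m3, 1)                            # exactly 40 ms -> merged
})

test_that("candidate detection applies the cell-count threshold", {
  model <- make_tuning(seq(0, 315, by = 45))
  ses4 <- burst_session(5, list(1:4))
  ses6 <- burst_session(5, list(1:6))
  c4 <- detect_candidate_events(ses4, model, "rest1")
  c6 <- detect_candidate_events(ses6, model, "rest1")
  expect_equal(nrow(c4), 0)                       # 4 cells -> excluded
  expect_equal(nrow(c6), 1)
  expect_equal(c6$n_cells, 6)
  expect_equal(c6$start_s, 5, tolerance = 0.02)
  expect_true(c6$duration_s >= 0.05 && c6$duration_s <= 2)
  expect_setequal(c6$participants[[1]], sprintf("u%02d", 1:6))
})

test_that("well-separated bursts stay separate; adjacent bursts merge", {
  model <- make_tuning(seq(0, 315, by = 45))
  two <- burst_session(c(5, 5.5), list(1:6, 1:6))  # 420 ms apart
  c2 <- detect_candidate_events(two, model, "rest1")
  expect_equal(nrow(c2), 2)
  close_by <- burst_session(c(5, 5.05), list(1:5, c(1, 6, 7, 8)),
                            burst_width = 0.02)
  c1 <- detect_candidate_events(close_by, model, "rest1")
  expect_equal(nrow(c1), 1)                       # gap under the merge rule
  expect_equal(c1$n_cells, 8)
})

test_that("detection is translation-invariant", {
  model <- make_tuning(seq(0, 315, by = 45))
  d <- 0.123
  a <- burst_session(c(5, 9), list(1:6, 2:7))
  b <- burst_session(c(5, 9) + d, list(1:6, 2:7))
  ca <- detect_candidate_events(a, model, "rest1")
  cb <- detect_candidate_events(b, model, "rest1")
  expect_equal(nrow(ca), nrow(cb))
  expect_equal(cb$start_s, ca$start_s + d, tolerance = 1e-6)
  expect_equal(cb$end_s, ca$end_s + d, tolerance = 1e-6)
})

test_that("detected events match an independently coded detector", {
  cfg <- analysis_config()
  model <- make_tuning(seq(0, 315, by = 45))
  set.seed(15)
  spikes <- lapply(1:8, function(j) sort(runif(rpois(1, 20 * 6), 0, 20)))
  ses <- make_manual_session(spikes, 20)
  got <- detect_candidate_events(ses, model, "rest1", cfg)
  # independent oracle: own binning, smoothing and interval logic
  pooled <- sort(unlist(spikes))
  edges <- seq(0, 20, by = 0.001)
  counts <- hist(pooled, breaks = edges, plot = FALSE)$counts
  k <- dnorm(-40:40, sd = 10); k <- k / sum(k)
  pad <- c(rep(0, 40), counts / 0.001, rep(0, 40))
  sm <- sapply(seq_along(counts), function(i) sum(pad[i:(i + 80)] * rev(k)))
  edge_w <- sapply(seq_along(counts), function(i) {
    lo <- max(1, 42 - i); hi <- min(81, 81 - (i + 40 - length(counts)))
    sum(k[lo:hi])
  })
  sm <- sm / edge_w
  th <- mean(sm) + 3 * sd(sm)
  above <- sm > th
  events <- list()
  i <- 1
  while (i <= length(sm)) {
    if (above[i]) {
      a <- i; b <- i
      while (a > 1 && sm[a - 1] > mean(sm)) a <- a - 1
      while (b < length(sm) && sm[b + 1] > mean(sm)) b <- b + 1
      events[[length(events) + 1]] <- c(edges[a], edges[b + 1])
      i <- b + 1
    }
    i <- i + 1
  }
  if (length(events)) {
    merged <- merge_close_intervals(sapply(events, `[`, 1),
                                    sapply(events, `[`, 2), 0.04)
    keep <- list()
    for (ev in merged) {
      inside <- pooled[pooled >= ev[1] & pooled <= ev[2]]
      if (!length(inside)) next
      s0 <- min(inside); s1 <- max(inside)
      ncell <- sum(sapply(spikes, function(s) any(s >= s0 & s <= s1)))
      if (s1 - s0 >= 0.05 && s1 - s0 <= 2 && ncell >= 5) {
        keep[[length(keep) + 1]] <- c(s0, s1)
      }
    }
    expect_equal(nrow(got), length(keep))
    for (i in seq_along(keep)) {
      expect_equal(got$start_s[i], keep[[i]][1], tolerance = 1e-9)
      expect_equal(got$end_s[i], keep[[i]][2], tolerance = 1e-9)
    }
  } else {
    expect_equal(nrow(got), 0)
  }
})

test_that("scripted replay classifies with the scripted slope and path", {
  gt <- ground_truth(rng_seed = 23)
  set.seed(23)
  ev <- data.frame(start_s = c(3, 8), duration_s = 0.2,
                   start_angle_deg = c(40, 160), speed_deg_s = 600,
                   direction = c(1, -1))
  ep <- simulate_rest_epoch(gt, 12, events = ev)
  ses <- make_manual_session(ep$spike_t, 12, label = "rest2")
  model <- true_tuning_model(gt)
  cand <- detect_candidate_events(ses, model, "rest2")
  expect_gte(nrow(cand), 2)
  rows <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i) {
    classify_replay(ses, model, cand[i, ])
  }))
  hits <- rows[sapply(rows$start_s, function(s)
    any(abs(s - ev$start_s) < 0.1)), ]
  expect_equal(nrow(hits), 2)
  expect_equal(hits$abs_slope_deg_s, c(600, 600), tolerance = 0.2)
  expect_equal(hits$path_distance_deg, c(120, 120), tolerance = 0.25)
  expect_gt(min(hits$r2), 0.5)
  expect_true(all(hits$is_replay))
  # forward and reverse scripted events have the same absolute slope
  expect_equal(hits$abs_slope_deg_s[1], hits$abs_slope_deg_s[2],
               tolerance = 0.25)
  expect_true(prod(hits$slope_deg_s) < 0)         # opposite signed slopes
})

test_that("trajectories that teleport beyond 25% of the track are rejected", {
  model <- make_tuning(seq(0, 354, by = 6), sigma_deg = 10, peak_hz = 60)
  # field-ordered firing sweeping 0..40 deg, then jumping to 160..200 deg
  t1 <- seq(0.0, 0.08, length.out = 8)
  t2 <- seq(0.12, 0.2, length.out = 8)
  ang <- c(seq(0, 40, length.out = 8), seq(160, 200, length.out = 8))
  spikes <- rep(list(numeric(0)), 60)
  for (i in seq_along(ang)) {
    j <- which.min(circ_dist_deg(seq(0, 354, by = 6), ang[i]))
    spikes[[j]] <- sort(c(spikes[[j]], c(t1, t2)[i] + 5 + c(0, 0.002)))
  }
  ses <- make_manual_session(spikes, 10, label = "rest2")
  ev <- data.frame(start_s = 5, end_s = 5.2, duration_s = 0.2, n_cells = 16,
                   rest_label = "rest2")
  out <- classify_replay(ses, model, ev)
  expect_gt(out$max_jump_frac, 0.25)
  expect_false(out$is_replay)
  # events in rest1 can never be replay
  ev1 <- ev; ev1$rest_label <- "rest1"
  expect_false(classify_replay(ses, model, ev1)$is_replay)
})

test_that("per-unit replay firing statistics follow their definitions", {
  model <- make_tuning(c(0, 90, 180))
  # unit 1 fires exactly 3 spikes in each of its 2 events of 150 ms;
  # unit 2 joins one event with 2 spikes; unit 3 never participates
  spikes <- list(c(1.0, 1.05, 1.1, 3.0, 3.07, 3.14),
                 c(3.02, 3.1),
                 c(5))
  ses <- make_manual_session(spikes, 6, label = "rest2")
  events <- data.frame(start_s = c(1.0, 3.0), end_s = c(1.15, 3.15),
                       duration_s = 0.15, n_cells = 2, rest_label = "rest2",
                       is_replay = TRUE)
  ps <- replay_psth(ses, model, events)
  expect_equal(ps$per_unit$spikes_per_event, c(3, 2, NA))
  expect_equal(ps$per_unit$in_event_rate_hz, c(20, 2 / 0.15, NA))
  expect_equal(ps$per_unit$n_events, c(2L, 1L, 0L))
  expect_true(all(is.na(ps$psth_hz[3, ])))
  # PSTH integrates to the spike count per event over the window
  on_win <- ps$t_s >= 0 & ps$t_s <= 0.15
  expect_equal(sum(ps$psth_hz[1, ] * 0.001), 3, tolerance = 0.05)
})

test_that("event ISIs reproduce their worked examples and closed forms", {
  ev <- data.frame(start_s = 0, end_s = 0.05)
  got <- event_isis(ev, list(c(0, 0.020), c(0.010), c(0.030)))
  expect_equal(got$population_isi_ms, 10)
  got2 <- event_isis(ev, list(c(0, 0.005), c(0.003), c(0.009)))
  expect_equal(got2$first_spike_isi_ms, 4.5)
  # population ISI telescopes to span / (n - 1)
  set.seed(16)
  sp <- lapply(1:5, function(j) sort(runif(6, 0, 0.05)))
  g3 <- event_isis(ev, sp)
  pooled <- sort(unlist(sp))
  expect_equal(g3$population_isi_ms,
               (max(pooled) - min(pooled)) / (length(pooled) - 1) * 1000,
               tolerance = 1e-12)
  firsts <- sort(sapply(sp, min))
  expect_equal(g3$first_spike_isi_ms,
               (max(firsts) - min(firsts)) / (length(firsts) - 1) * 1000,
               tolerance = 1e-12)
  # insufficient spikes -> NA
  expect_true(is.na(event_isis(ev, list(c(0.01)))$population_isi_ms))
})
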