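test_that("rate maps divide spikes by gated occupancy", {
  cfg <- analysis_config()
  tr <- compute_speed(make_trace(180, 8))          # 8 deg/s ~ 7 cm/s, gated in
  # no spikes -> all-zero map
  m0 <- compute_rate_map(numeric(0), tr, c(0, 180), cfg)
  expect_equal(m0$rate_hz, rep(0, 90))
  # two spikes per bin over uniform occupancy -> constant map (smoothing
  # preserves constants)
  spikes <- as.vector(sapply(0:89, function(b) (b * 4 + c(1, 3)) / 8))
  spikes <- sort((rep(spikes, 4) + rep(0:3 * 45, each = 180)))
  m2 <- compute_rate_map(spikes, tr, c(0, 180), cfg)
  expect_equal(sd(m2$rate_hz) / mean(m2$rate_hz), 0, tolerance = 0.05)
  expect_equal(mean(m2$rate_hz), 4, tolerance = 0.1)       # 2 spikes / 0.5 s
  # occupancy sums to the gated epoch duration
  expect_equal(sum(m2$occupancy_s), 180, tolerance = 0.2)
})

test_that("a single spike smooths into a wrapped Gaussian of the kernel SD", {
  cfg <- analysis_config()
  tr <- compute_speed(make_trace(45 * 4, 8))       # exactly 4 passes
  m <- compute_rate_map(1 / 8 / 2, tr, c(0, 180), cfg)  # one spike in bin 1
  raw <- m$raw_rate_hz
  expect_equal(which(raw > 0), 1L)
  expect_equal(m$rate_hz, smooth_circular(raw, 2), tolerance = 1e-12)
  expect_equal(sum(m$rate_hz), sum(raw), tolerance = 1e-9)
  expect_equal(which.max(m$rate_hz), 1L)
})

test_that("rotation of trajectory and spikes rotates the map exactly", {
  cfg <- analysis_config()
  set.seed(2)
  spikes <- sort(runif(200, 0, 120))
  for (kbins in c(5, 23)) {
    tr1 <- compute_speed(make_trace(120, 12))
    tr2 <- tr1
    tr2$angle_deg <- (tr2$angle_deg + kbins * 4) %% 360
    m1 <- compute_rate_map(spikes, tr1, c(0, 120), cfg)
    m2 <- compute_rate_map(spikes, tr2, c(0, 120), cfg)
    rot <- function(x, k) x[((seq_along(x) - 1 - k) %% length(x)) + 1]
    expect_equal(m2$rate_hz, rot(m1$rate_hz, kbins), tolerance = 1e-9)
    expect_equal(m2$occupancy_s, rot(m1$occupancy_s, kbins),
                 tolerance = 1e-9)
  }
})

test_that("day maps pool spikes and occupancy rather than averaging rates", {
  occ1 <- rep(2, 90); occ1[10] <- 1
  occ2 <- rep(2, 90); occ2[10] <- 3
  c1 <- occ1 * 1; c1[10] <- 1
  c2 <- occ2 * 1; c2[10] <- 9
  a <- manual_rate_map(c1 / occ1, occ1, counts = c1)
  b <- manual_rate_map(c2 / occ2, occ2, counts = c2)
  d <- day_average_map(list(a, b))
  expect_equal(d$raw_rate_hz[10], 10 / 4)          # pooled, not mean(1, 3)
  # identical sessions -> day map equals the session map
  d2 <- day_average_map(list(a, a))
  expect_equal(d2$raw_rate_hz, a$raw_rate_hz)
  # inclusion threshold on the day-map peak
  lo <- manual_rate_map(rep(0.9, 90))
  expect_false(day_average_map(list(lo))$include_for_analysis)
  expect_error(day_average_map(list(a, manual_rate_map(rep(1, 45)))),
               "mismatched")
})

test_that("spatial correlation is Pearson on the binned rates", {
  bump <- manual_rate_map(smooth_circular(c(5, rep(0, 89)), 2))
  expect_equal(spatial_correlation(bump, bump), 1.0)
  neg <- manual_rate_map(max(bump$rate_hz) - bump$rate_hz)
  expect_equal(spatial_correlation(bump, neg), -1.0)
  rot <- manual_rate_map(bump$rate_hz[c(46:90, 1:45)])
  # brute-force Pearson oracle
  x <- bump$rate_hz; y <- rot$rate_hz
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(spatial_correlation(bump, rot), oracle, tolerance = 1e-12)
  expect_warning(v <- spatial_correlation(bump, manual_rate_map(rep(2, 90))),
                 "zero-variance")
  expect_true(is.na(v))
})

test_that("rate overlap is the min/max ratio of mean rates", {
  a <- manual_rate_map(rep(2, 90))
  b <- manual_rate_map(rep(4, 90))
  expect_equal(rate_overlap(a, b), 0.5)
  expect_equal(rate_overlap(a, a), 1.0)
  z <- manual_rate_map(rep(0, 90))
  expect_equal(rate_overlap(a, z), 0.0)
  expect_warning(v <- rate_overlap(z, z))
  expect_true(is.na(v))
})

test_that("spatial information matches its closed forms and an explicit sum", {
  expect_equal(spatial_information(manual_rate_map(rep(3.7, 90))), 0)
  one_bin <- rep(0, 90); one_bin[17] <- 12
  expect_equal(spatial_information(manual_rate_map(one_bin)), log2(90),
               tolerance = 1e-12)
  # 5-bin toy map against direct summation
  toy <- manual_rate_map(c(1, 2, 3, 2, 1))
  lam <- mean(c(1, 2, 3, 2, 1))
  oracle <- sum(0.2 * (c(1, 2, 3, 2, 1) / lam) * log2(c(1, 2, 3, 2, 1) / lam))
  expect_equal(spatial_information(toy), oracle, tolerance = 1e-12)
  expect_warning(v <- spatial_information(manual_rate_map(rep(0, 90))))
  expect_true(is.na(v))
})

test_that("spatial information is non-negative and relabeling-invariant", {
  set.seed(4)
  for (i in 1:20) {
    r <- rgamma(90, 2, 1)
    m <- manual_rate_map(r)
    si <- spatial_information(m)
    expect_gte(si, -1e-12)
    perm <- sample(90)
    expect_equal(spatial_information(manual_rate_map(r[perm])), si,
                 tolerance = 1e-12)
    expect_equal(sum(m$occupancy_s / sum(m$occupancy_s)), 1)
  }
})

test_that("place-field detection applies the z thresholds and size rules", {
  cfg <- analysis_config()
  expect_equal(nrow(detect_place_fields(manual_rate_map(rep(2, 90)), cfg)), 0)
  # single wrapped bump: boundaries must match a brute-force bin scan
  bump <- smooth_circular(c(rep(0, 85), 40, rep(0, 4)), 3)
  m <- manual_rate_map(bump)
  f <- detect_place_fields(m, cfg)
  expect_equal(nrow(f), 1)
  z <- (bump - mean(bump)) / sd(bump)
  seed <- which(z >= 2)
  # oracle: grow the seed circularly (wrap-aware walk) until z < 0.5
  lo <- min(seed); hi <- max(seed)
  repeat {
    nxt <- (hi %% 90) + 1
    if (z[nxt] < 0.5 || nxt == lo) break
    hi <- nxt
    if (hi == lo) break
  }
  repeat {
    prv <- ((lo - 2) %% 90) + 1
    if (z[prv] < 0.5 || prv == hi) break
    lo <- prv
  }
  n_oracle <- ((hi - lo) %% 90) + 1
  expect_equal(f$n_bins, n_oracle)
  expect_equal(f$start_deg, (lo - 1) * 4)
  expect_equal(f$peak_rate_hz, max(bump))
  # a bump spanning under 18 degrees is rejected
  narrow <- rep(0.5, 90); narrow[20:22] <- c(3, 6, 3)
  expect_equal(nrow(detect_place_fields(manual_rate_map(narrow), cfg)), 0)
})

test_that("field detection recovers scripted field centers within one kernel SD", {
  maps <- small_maps()
  day <- small_day()
  cfg <- analysis_config()
  centers <- day$ground_truth$field_center_deg
  hits <- 0; total <- 0
  for (j in seq_along(maps$day_maps)) {
    if (!maps$included[j]) next
    f <- detect_place_fields(maps$day_maps[[j]], cfg)
    if (!nrow(f)) next
    total <- total + 1
    best <- f[which.max(f$peak_rate_hz), ]
    if (circ_dist_deg(best$peak_angle_deg, centers[j]) <= 8) hits <- hits + 1
  }
  expect_gt(total, 40)
  expect_gt(hits / total, 0.9)
})
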