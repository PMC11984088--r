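#' Detect candidate population events in a rest epoch
#'
#' Builds the population firing-rate histogram of all active place cells in
#' 1 ms bins, smooths it with a 10 ms SD Gaussian, and takes excursions
#' above mean + `cfg$replay_z` SDs (mean/SD over this rest epoch), bounded
#' by the surrounding crossings of the mean. Events closer than
#' `cfg$replay_merge_s` are merged; bounds are then adjusted inward to the
#' first and last spike; events must last 50-2,000 ms and contain spikes
#' from at least `cfg$replay_min_cells` distinct cells.
#'
#' @param session a `place_session`.
#' @param model a [tuning_model()] (defines the active place cells).
#' @param rest_label which rest epoch to scan, e.g. `"rest2"`.
#' @param cfg an [analysis_config()].
#' @return data.frame of candidates: `start_s`, `end_s`, `duration_s`,
#'   `n_cells`, `rest_label`, and a list-column `participants` of unit ids.
#' @export
detect_candidate_events <- function(session, model, rest_label,
                                    cfg = analysis_config()) {
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0), n_cells = integer(0),
                      rest_label = character(0))
  empty$participants <- list()
  ep <- epoch_bounds(session, rest_label)
  spk <- model_spikes(session, model)
  pooled <- sort(unlist(spk))
  pooled <- pooled[pooled >= ep[1] & pooled < ep[2]]
  if (!length(pooled)) return(empty)
  bw <- cfg$psth_bin_s                       # 1 ms population-rate bins
  edges <- seq(ep[1], ep[2], by = bw)
  counts <- tabulate(findInterval(pooled, edges), length(edges) - 1)
  rate <- smooth_linear(counts / bw, cfg$psth_smooth_s / bw)
  m <- mean(rate); s <- stats::sd(rate)
  if (s == 0) return(empty)
  th <- m + cfg$replay_z * s
  above <- rate > th
  if (!any(above)) return(empty)
  r <- rle(above)
  rends <- cumsum(r$lengths)
  rstarts <- rends - r$lengths + 1L
  seg <- cbind(rstarts[r$values], rends[r$values])
  # extend each excursion outward to the crossings of the mean
  over_mean <- rate > m
  for (k in seq_len(nrow(seg))) {
    i <- seg[k, 1]
    while (i > 1 && over_mean[i - 1]) i <- i - 1
    j <- seg[k, 2]
    while (j < length(rate) && over_mean[j + 1]) j <- j + 1
    seg[k, ] <- c(i, j)
  }
  merged <- merge_close_intervals(edges[seg[, 1]], edges[seg[, 2] + 1L],
                                  cfg$replay_merge_s)
  rows <- list()
  ids <- model$unit_ids
  for (b in merged) {
    inside <- pooled[pooled >= b[1] & pooled <= b[2]]
    if (!length(inside)) next
    s0 <- min(inside); s1 <- max(inside)     # trim inward to spikes
    dur <- s1 - s0
    if (dur < cfg$replay_dur_s[1] || dur > cfg$replay_dur_s[2]) next
    part <- ids[vapply(spk, function(s) any(s >= s0 & s <= s1), logical(1))]
    if (length(part) < cfg$replay_min_cells) next
    row <- data.frame(start_s = s0, end_s = s1, duration_s = dur,
                      n_cells = length(part), rest_label = rest_label)
    row$participants <- list(part)
    rows[[length(rows) + 1]] <- row
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Merge intervals separated by at most a gap
#'
#' Candidate events within `gap_s` of each other are combined into one.
#'
#' @param start_s,end_s interval bounds (any order).
#' @param gap_s maximum gap merged across, s.
#' @return list of merged `c(start, end)` pairs in time order.
#' @export
merge_close_intervals <- function(start_s, end_s, gap_s) {
  o <- order(start_s)
  start_s <- start_s[o]; end_s <- end_s[o]
  ms <- start_s[1]; me <- end_s[1]
  merged <- list()
  for (k in seq_along(start_s)[-1]) {
    if (start_s[k] - me <= gap_s) {
      me <- max(me, end_s[k])
    } else {
      merged[[length(merged) + 1]] <- c(ms, me)
      ms <- start_s[k]; me <- end_s[k]
    }
  }
  merged[[length(merged) + 1]] <- c(ms, me)
  merged
}

#' Classify a candidate event as replay
#'
#' Decodes the event in partially overlapping 20 ms windows advanced by
#' 10 ms, fits the circular-linear regression to the per-window posterior
#' centers of mass, and classifies the event as significant replay when the
#' fit's r-squared reaches `cfg$replay_r2_min`, no adjacent-window decoded
#' jump exceeds `cfg$replay_jump_frac` of the track, and the event occurred
#' in rest sessions 2-5 (after the first run). The slope is reported as an
#' absolute value so forward and reverse replay are treated alike; the path
#' distance is the circular distance between the first and last window
#' centers of mass.
#'
#' @param session a `place_session`.
#' @param model a [tuning_model()].
#' @param event one row of [detect_candidate_events()].
#' @param cfg an [analysis_config()].
#' @return one-row data.frame (`NULL` with a message attribute when the
#'   event is too short to decode in two windows): event bounds plus `r2`,
#'   `slope_deg_s` (signed), `abs_slope_deg_s`, `abs_slope_cm_s`,
#'   `x_span_deg`, `t_span_s`, `path_distance_deg`, `max_jump_frac`,
#'   `n_windows`, `is_replay`.
#' @export
classify_replay <- function(session, model, event, cfg = analysis_config()) {
  win <- make_windows(event$start_s, event$end_s, cfg$replay_win_s,
                      cfg$replay_step_s)
  if (nrow(win) < 2) return(NULL)
  spk <- model_spikes(session, model)
  dec <- decode_posterior(model, spk, win, cfg)
  fit <- fit_decoded_trajectory(dec, cfg,
                                slope_bounds = cfg$replay_slope_bounds,
                                min_windows = 2L,
                                track_circumference_cm =
                                  session$track_circumference_cm)
  if (is.null(fit)) return(NULL)
  jumps <- circ_dist_deg(fit$com_deg[-1], fit$com_deg[-length(fit$com_deg)])
  max_jump <- max(jumps) / 360
  path <- circ_dist_deg(fit$com_deg[length(fit$com_deg)], fit$com_deg[1])
  in_rest_2_5 <- event$rest_label %in% c("rest2", "rest3", "rest4", "rest5")
  data.frame(start_s = event$start_s, end_s = event$end_s,
             duration_s = event$duration_s, n_cells = event$n_cells,
             rest_label = event$rest_label,
             r2 = fit$r2,
             slope_deg_s = fit$slope_deg_s,
             abs_slope_deg_s = abs(fit$slope_deg_s),
             abs_slope_cm_s = abs(fit$slope_cm_s),
             x_span_deg = fit$x_span_deg,
             t_span_s = fit$t_span_s,
             path_distance_deg = path,
             max_jump_frac = max_jump,
             n_windows = fit$n_windows,
             is_replay = fit$r2 >= cfg$replay_r2_min &&
               max_jump <= cfg$replay_jump_frac && in_rest_2_5)
}

#' Detect and classify replay across all rest sessions
#'
#' @param session a `place_session`.
#' @param model a [tuning_model()].
#' @param cfg an [analysis_config()].
#' @param rest_labels rest epochs to scan (default all in the schedule;
#'   events from rest1 are detected but can never classify as replay).
#' @return list with `candidates` (all candidate events) and `events` (one
#'   classified row per decodable candidate).
#' @export
replay_events <- function(session, model, cfg = analysis_config(),
                          rest_labels = NULL) {
  if (is.null(rest_labels)) {
    rest_labels <- session$schedule$label[grepl("^rest",
                                                session$schedule$label)]
  }
  cands <- list(); rows <- list()
  for (lab in rest_labels) {
    cand <- detect_candidate_events(session, model, lab, cfg)
    if (nrow(cand)) cands[[length(cands) + 1]] <- cand
    for (i in seq_len(nrow(cand))) {
      row <- classify_replay(session, model, cand[i, ], cfg)
      if (!is.null(row)) rows[[length(rows) + 1]] <- row
    }
  }
  list(candidates = if (length(cands)) do.call(rbind, cands),
       events = if (length(rows)) do.call(rbind, rows))
}

#' Per-unit firing around replay event onsets
#'
#' Bins each included unit's firing in 1 ms bins around the onsets of the
#' replay events in which that unit participated (fired at least one spike
#' within the event bounds), smooths with a 10 ms SD Gaussian, and averages
#' across those events. Also reports each unit's mean firing rate within
#' its participated events and its mean spike count per participated event.
#'
#' @param session a `place_session`.
#' @param model a [tuning_model()].
#' @param events classified event table (rows where `is_replay` is `TRUE`
#'   are used).
#' @param cfg an [analysis_config()].
#' @return list with `t_s` (PSTH time axis relative to onset), `psth_hz`
#'   (units x bins mean rate matrix, `NA` rows for non-participating
#'   units), and `per_unit` (data.frame `unit_id`, `n_events`,
#'   `in_event_rate_hz`, `spikes_per_event`).
#' @export
replay_psth <- function(session, model, events, cfg = analysis_config()) {
  ev <- events[events$is_replay, , drop = FALSE]
  if (!nrow(ev)) stop("no replay events to average")
  spk <- model_spikes(session, model)
  edges <- seq(cfg$psth_win_s[1], cfg$psth_win_s[2], by = cfg$psth_bin_s)
  t_axis <- edges[-length(edges)] + cfg$psth_bin_s / 2
  psth <- matrix(NA_real_, length(spk), length(t_axis))
  per <- data.frame(unit_id = model$unit_ids, n_events = 0L,
                    in_event_rate_hz = NA_real_, spikes_per_event = NA_real_)
  for (j in seq_along(spk)) {
    s <- spk[[j]]
    counts_tot <- numeric(length(t_axis))
    n_part <- 0L; n_spikes <- 0; t_in <- 0
    for (i in seq_len(nrow(ev))) {
      inside <- s >= ev$start_s[i] & s <= ev$end_s[i]
      if (!any(inside)) next
      n_part <- n_part + 1L
      n_spikes <- n_spikes + sum(inside)
      t_in <- t_in + ev$duration_s[i]
      rel <- s - ev$start_s[i]
      rel <- rel[rel >= edges[1] & rel < edges[length(edges)]]
      counts_tot <- counts_tot +
        tabulate(findInterval(rel, edges), length(t_axis))
    }
    if (n_part > 0) {
      psth[j, ] <- smooth_linear(counts_tot / (n_part * cfg$psth_bin_s),
                                 cfg$psth_smooth_s / cfg$psth_bin_s)
      per$n_events[j] <- n_part
      per$in_event_rate_hz[j] <- n_spikes / t_in
      per$spikes_per_event[j] <- n_spikes / n_part
    }
  }
  list(t_s = t_axis, psth_hz = psth, per_unit = per)
}

#' Interspike intervals within a replay event
#'
#' The population ISI is the mean interval between consecutive spikes
#' pooled over all cells in the event (equal to the event's pooled spike
#' span divided by the number of intervals); the first-spike ISI pools only
#' the first spike each cell fired and averages the intervals between those
#' first-spike times.
#'
#' @param event one classified event row (uses `start_s`, `end_s`).
#' @param spike_t list of spike-time vectors (the model's units).
#' @return list with `population_isi_ms` and `first_spike_isi_ms` (`NA`
#'   when there are fewer than 2 pooled spikes / 2 participating cells).
#' @export
event_isis <- function(event, spike_t) {
  inside <- lapply(spike_t, function(s) s[s >= event$start_s & s <= event$end_s])
  pooled <- sort(unlist(inside))
  pop <- if (length(pooled) >= 2) mean(diff(pooled)) * 1000 else NA_real_
  firsts <- sort(vapply(inside[lengths(inside) > 0], min, numeric(1)))
  fsi <- if (length(firsts) >= 2) mean(diff(firsts)) * 1000 else NA_real_
  list(population_isi_ms = pop, first_spike_isi_ms = fsi)
}
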