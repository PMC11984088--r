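#' Run the full day-level analysis
#'
#' Orchestrates the pipeline in methods order: behavior metrics, rate maps
#' and place-cell properties, phase precession, the Bayesian decoding
#' accuracy gate, then -- only on days that pass the gate -- theta-sequence
#' detection, replay detection/classification (rest sessions 2-5), the
#' replay PSTH and ISIs, and replay-associated LFP measures. Every
#' downstream table is empty when the decoding gate fails. Deterministic
#' given `cfg$rng_seed`.
#'
#' @param session a `place_session`.
#' @param cfg an [analysis_config()].
#' @param max_cycles cap on analyzed theta cycles (passed to
#'   [detect_theta_sequences()]).
#' @return object of class `day_report`: list of result tables plus the
#'   config snapshot.
#' @export
run_day <- function(session, cfg = analysis_config(), max_cycles = Inf) {
  force(session)                 # evaluate before seeding: the argument may
  force(cfg)                     # itself consume RNG (e.g. a generator call)
  set.seed(cfg$rng_seed)
  behavior <- behavior_metrics(session, cfg)
  maps <- day_rate_maps(session, cfg)
  unit_ids <- vapply(session$units, `[[`, character(1), "unit_id")
  runs <- run_labels(session)

  # per-unit place-cell properties on the day-averaged map
  cells <- do.call(rbind, lapply(seq_along(unit_ids), function(j) {
    dm <- maps$day_maps[[j]]
    flds <- if (maps$included[j]) detect_place_fields(dm, cfg) else
      detect_place_fields(dm, cfg)[0, ]
    data.frame(unit_id = unit_ids[j],
               mean_rate_hz = session$units[[j]]$mean_rate_hz,
               is_interneuron = session$units[[j]]$is_interneuron,
               peak_rate_hz = dm$peak_rate_hz,
               included = maps$included[j],
               spatial_info_bits = if (dm$mean_rate_hz > 0)
                 spatial_information(dm) else NA_real_,
               n_fields = nrow(flds),
               field_size_deg = if (nrow(flds))
                 flds$size_deg[which.max(flds$peak_rate_hz)] else NA_real_)
  }))

  # across-session stability for included units
  stability <- list()
  if (length(runs) >= 2) {
    prs <- utils::combn(runs, 2)
    for (j in which(maps$included)) {
      sm <- maps$session_maps[[j]]
      for (k in seq_len(ncol(prs))) {
        a <- sm[[prs[1, k]]]; b <- sm[[prs[2, k]]]
        sc <- suppressWarnings(spatial_correlation(a, b))
        ro <- suppressWarnings(rate_overlap(a, b))
        stability[[length(stability) + 1]] <- data.frame(
          unit_id = unit_ids[j], pair = paste(prs[, k], collapse = "-"),
          spatial_correlation = sc, rate_overlap = ro)
      }
    }
  }
  stability <- if (length(stability)) do.call(rbind, stability) else
    data.frame(unit_id = character(0), pair = character(0),
               spatial_correlation = numeric(0), rate_overlap = numeric(0))

  phase <- theta_filter_phase(session$lfp[[1]], cfg = cfg)
  precession <- phase_precession_table(session, maps, phase, cfg)

  gate_reason <- NULL
  model <- NULL
  accuracy <- NULL
  if (sum(maps$included) < 1) {
    gate_reason <- "no included place cells"
  } else {
    model <- tuning_model(maps)
    accuracy <- decoding_accuracy(session, model, cfg)
    if (!accuracy$passes_criterion) {
      gate_reason <- sprintf(
        "decoding gate failed: median error %.1f deg (criterion < %g deg)",
        accuracy$median_error_deg, cfg$acc_criterion_deg)
    }
  }

  sequences <- NULL; replay <- NULL; psth <- NULL; isis <- NULL
  lfp_table <- NULL
  if (is.null(gate_reason)) {
    sequences <- detect_theta_sequences(session, model, cfg, phase = phase,
                                        max_cycles = max_cycles)
    replay <- replay_events(session, model, cfg)
    ev <- replay$events
    if (!is.null(ev) && any(ev$is_replay)) {
      psth <- replay_psth(session, model, ev, cfg)
      spk <- model_spikes(session, model)
      rep_ev <- ev[ev$is_replay, , drop = FALSE]
      isis <- do.call(rbind, lapply(seq_len(nrow(rep_ev)), function(i) {
        ii <- event_isis(rep_ev[i, ], spk)
        data.frame(start_s = rep_ev$start_s[i],
                   population_isi_ms = ii$population_isi_ms,
                   first_spike_isi_ms = ii$first_spike_isi_ms)
      }))
      lfp_table <- tryCatch(replay_lfp_table(session, ev, cfg),
                            error = function(e) NULL)
    }
  }

  structure(list(
    behavior = behavior,
    cells = cells,
    stability = stability,
    precession = precession,
    n_place_cells = sum(maps$included),
    decoding = accuracy,
    gate_passed = is.null(gate_reason),
    gate_reason = gate_reason,
    sequences = sequences,
    replay = if (!is.null(replay)) replay$events,
    replay_candidates = if (!is.null(replay)) replay$candidates,
    psth = psth,
    isis = isis,
    lfp = lfp_table,
    config = cfg,
    seed = cfg$rng_seed
  ), class = "day_report")
}

#' @export
print.day_report <- function(x, ...) {
  cat("<day_report>\n")
  cat(sprintf("  %d units, %d included place cells\n", nrow(x$cells),
              x$n_place_cells))
  if (!is.null(x$decoding)) {
    cat(sprintf("  decoding median error %.1f deg -> gate %s\n",
                x$decoding$median_error_deg,
                if (x$gate_passed) "passed" else "FAILED"))
  }
  if (!x$gate_passed) cat(sprintf("  (%s)\n", x$gate_reason))
  if (!is.null(x$sequences)) {
    cat(sprintf("  %d fitted theta cycles, %d significant sequences\n",
                nrow(x$sequences), sum(x$sequences$significant, na.rm = TRUE)))
  }
  if (!is.null(x$replay)) {
    cat(sprintf("  %d decoded candidates, %d significant replay events\n",
                nrow(x$replay), sum(x$replay$is_replay)))
  }
  invisible(x)
}

# Significant sequences when the significance machinery ran, otherwise all
# fitted cycles (slope-recovery runs with seq_n_shuffle = 0).
seq_sel <- function(report) {
  s <- report$sequences
  if (is.null(s) || !nrow(s)) return(s)
  sig <- isTRUE_or(s$significant)
  if (any(sig)) s[sig, , drop = FALSE] else s
}

report_metric <- function(report, metric) {
  switch(metric,
    seq_slope = abs(seq_sel(report)$slope_deg_s),
    seq_x_span = seq_sel(report)$x_span_deg,
    seq_t_span = seq_sel(report)$t_span_s,
    replay_duration = report$replay$duration_s[report$replay$is_replay],
    replay_slope = report$replay$abs_slope_deg_s[report$replay$is_replay],
    in_event_rate = report$psth$per_unit$in_event_rate_hz,
    population_isi = report$isis$population_isi_ms,
    first_spike_isi = report$isis$first_spike_isi_ms,
    peak_ripple_hz = report$lfp$peak_ripple_hz,
    stop("unknown metric: ", metric))
}

isTRUE_or <- function(x) if (is.null(x)) logical(0) else !is.na(x) & x

#' Direction-of-effect comparison between two day reports
#'
#' For each sequence/replay metric: the two medians, a Wilcoxon rank-sum
#' test, and the direction of the difference (`"a>b"`, `"a<b"`, `"none"`).
#' Metrics with an empty table on either side are skipped (`NA` direction).
#'
#' @param report_a,report_b `day_report`s (e.g. from the WT-like and
#'   FXS-like presets).
#' @return data.frame: `metric`, `median_a`, `median_b`, `rank_sum_p`,
#'   `direction`.
#' @export
compare_presets <- function(report_a, report_b) {
  metrics <- c("seq_slope", "seq_x_span", "seq_t_span", "replay_duration",
               "replay_slope", "in_event_rate", "population_isi",
               "first_spike_isi", "peak_ripple_hz")
  out <- data.frame(metric = metrics, median_a = NA_real_,
                    median_b = NA_real_, rank_sum_p = NA_real_,
                    direction = NA_character_)
  for (i in seq_along(metrics)) {
    a <- tryCatch(report_metric(report_a, metrics[i]), error = function(e) NULL)
    b <- tryCatch(report_metric(report_b, metrics[i]), error = function(e) NULL)
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (!length(a) || !length(b)) next
    out$median_a[i] <- stats::median(a)
    out$median_b[i] <- stats::median(b)
    out$rank_sum_p[i] <- tryCatch(
      suppressWarnings(stats::wilcox.test(a, b)$p.value),
      error = function(e) NA_real_)
    out$direction[i] <- if (out$median_a[i] > out$median_b[i]) "a>b"
      else if (out$median_a[i] < out$median_b[i]) "a<b" else "none"
  }
  out
}
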