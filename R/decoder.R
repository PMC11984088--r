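# Sliding decoding windows fully contained in [t0, t1].
make_windows <- function(t0, t1, win_s, step_s) {
  if (t1 - t0 < win_s) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      center_s = numeric(0)))
  }
  starts <- seq(t0, t1 - win_s, by = step_s)
  data.frame(start_s = starts, end_s = starts + win_s,
             center_s = starts + win_s / 2)
}

count_in_windows <- function(spike_t, windows) {
  s <- sort(spike_t)
  findInterval(windows$end_s, s, left.open = FALSE) -
    findInterval(windows$start_s, s, left.open = FALSE)
}

#' Position tuning model for Bayesian decoding
#'
#' Stacks the day-averaged rate maps of the included place cells into the
#' decoder's expected-rate matrix (units x position bins).
#'
#' @param maps result of [day_rate_maps()], or a list of day `rate_map`s.
#' @param included optional logical mask overriding `maps$included`.
#' @return object of class `tuning_model`: `unit_ids`, `tuning_hz`
#'   (units x bins matrix), `bin_deg`.
#' @export
tuning_model <- function(maps, included = NULL) {
  day <- if (!is.null(maps$day_maps)) maps$day_maps else maps
  if (is.null(included)) {
    included <- if (!is.null(maps$included)) maps$included else
      rep(TRUE, length(day))
  }
  day <- day[included]
  if (!length(day)) stop("no included units for the tuning model")
  tun <- do.call(rbind, lapply(day, `[[`, "rate_hz"))
  if (all(tun == 0)) stop("all-zero tuning; cannot decode")
  structure(list(unit_ids = vapply(day, `[[`, character(1), "unit_id"),
                 tuning_hz = tun,
                 bin_deg = day[[1]]$bin_deg),
            class = "tuning_model")
}

#' @export
print.tuning_model <- function(x, ...) {
  cat(sprintf("<tuning_model> %d units x %d bins (%g deg)\n",
              nrow(x$tuning_hz), ncol(x$tuning_hz), x$bin_deg))
  invisible(x)
}

#' Bayesian position decoding of population spike counts
#'
#' Memoryless Poisson decoder with a flat position prior: for each window of
#' length tau, `log P(n|x) = sum_j [ n_j log(tau lambda_j(x)) - tau
#' lambda_j(x) ]` (count-factorial terms drop in the normalization), and the
#' posterior is normalized to sum to 1 across position bins. Tuning rates
#' are floored at `cfg$decode_rate_floor_hz` inside the logarithm.
#'
#' @param model a [tuning_model()].
#' @param spike_t list of spike-time vectors, one per model unit, in model
#'   unit order.
#' @param windows data.frame of decoding windows (`start_s`, `end_s`,
#'   optionally `center_s`).
#' @param cfg an [analysis_config()].
#' @return object of class `decoded_posterior`: `windows`,
#'   `window_centers_s`, `posterior` (windows x bins, rows sum to 1),
#'   `n_spikes` (per window), `n_active` (units with at least one spike per
#'   window), `bin_deg`.
#' @export
decode_posterior <- function(model, spike_t, windows,
                             cfg = analysis_config()) {
  stopifnot(nrow(windows) >= 1, length(spike_t) == nrow(model$tuning_hz))
  lam <- pmax(model$tuning_hz, cfg$decode_rate_floor_hz)
  n_counts <- vapply(spike_t, count_in_windows, numeric(nrow(windows)),
                     windows = windows)
  if (nrow(windows) == 1) n_counts <- matrix(n_counts, nrow = 1)
  tau <- windows$end_s - windows$start_s
  ll <- n_counts %*% log(lam) +
    outer(rowSums(n_counts), rep(1, ncol(lam))) * log(tau) -
    outer(tau, colSums(lam))
  ll <- ll - apply(ll, 1, max)
  post <- exp(ll)
  post <- post / rowSums(post)
  if (is.null(windows$center_s)) {
    windows$center_s <- (windows$start_s + windows$end_s) / 2
  }
  structure(list(windows = windows,
                 window_centers_s = windows$center_s,
                 posterior = post,
                 n_spikes = rowSums(n_counts),
                 n_active = rowSums(n_counts > 0),
                 bin_deg = model$bin_deg),
            class = "decoded_posterior")
}

#' @export
print.decoded_posterior <- function(x, ...) {
  cat(sprintf("<decoded_posterior> %d windows x %d bins; %.1f spikes/window\n",
              nrow(x$posterior), ncol(x$posterior), mean(x$n_spikes)))
  invisible(x)
}

# Spike-time list for the model's units, in model order.
model_spikes <- function(session, model) {
  ids <- vapply(session$units, `[[`, character(1), "unit_id")
  lapply(model$unit_ids, function(id) {
    session$units[[match(id, ids)]]$spike_t
  })
}

#' Decoding accuracy over the run sessions
#'
#' Decodes all speed-gated run windows (500 ms windows, 100 ms steps by
#' default), takes the maximum-posterior bin as the decoded position, and
#' measures the shortest-arc error against the rat's actual position. A day
#' passes the inclusion criterion when the cumulative error distribution
#' reaches 50% below `cfg$acc_criterion_deg` -- equivalently, the median
#' error is below it. Also returns the confusion matrix: for each actual
#' position bin, the mean posterior across all windows in which the rat was
#' there.
#'
#' @param session a `place_session`.
#' @param model a [tuning_model()].
#' @param cfg an [analysis_config()].
#' @return object of class `decoding_accuracy`: `windows` (with
#'   `actual_deg`, `decoded_deg`, `error_deg`), `median_error_deg`,
#'   `passes_criterion`, `confusion` (actual-bin x decoded-bin mean
#'   posterior), `error_sorted_deg` (the cumulative error distribution).
#' @export
decoding_accuracy <- function(session, model, cfg = analysis_config()) {
  nb <- ncol(model$tuning_hz)
  spk <- model_spikes(session, model)
  runs <- session$schedule[grepl("^run", session$schedule$label), ]
  all_windows <- list()
  for (i in seq_len(nrow(runs))) {
    w <- make_windows(runs$start_s[i], runs$end_s[i], cfg$acc_win_s,
                      cfg$acc_step_s)
    if (nrow(w)) all_windows[[length(all_windows) + 1]] <- w
  }
  windows <- do.call(rbind, all_windows)
  if (is.null(windows) || !nrow(windows)) stop("no decodable run windows")
  # speed gate: mean speed within the window must clear the gate
  pos <- session$position
  cum_t <- c(0, cumsum(diff(pos$t) *
                         (pos$speed_cm_s[-1] + pos$speed_cm_s[-nrow(pos)]) / 2))
  mean_speed <- (stats::approx(pos$t, cum_t, xout = windows$end_s, rule = 2)$y -
                 stats::approx(pos$t, cum_t, xout = windows$start_s, rule = 2)$y) /
    (windows$end_s - windows$start_s)
  windows <- windows[mean_speed > cfg$speed_min, , drop = FALSE]
  if (!nrow(windows)) stop("no run windows pass the speed gate")
  dec <- decode_posterior(model, spk, windows, cfg)
  decoded_deg <- (max.col(dec$posterior, ties.method = "first") - 0.5) *
    model$bin_deg
  actual_deg <- angle_at_time(pos, windows$center_s)
  err <- circ_dist_deg(actual_deg, decoded_deg)
  windows$actual_deg <- actual_deg
  windows$decoded_deg <- decoded_deg
  windows$error_deg <- err
  actual_bin <- pmin(nb, floor(actual_deg / model$bin_deg) + 1L)
  confusion <- matrix(NA_real_, nb, nb)
  for (b in seq_len(nb)) {
    sel <- actual_bin == b
    if (any(sel)) {
      confusion[b, ] <- colMeans(dec$posterior[sel, , drop = FALSE])
    }
  }
  med <- stats::median(err)
  structure(list(windows = windows,
                 median_error_deg = med,
                 passes_criterion = med < cfg$acc_criterion_deg,
                 confusion = confusion,
                 error_sorted_deg = sort(err)),
            class = "decoding_accuracy")
}

#' @export
print.decoding_accuracy <- function(x, ...) {
  cat(sprintf("<decoding_accuracy> %d windows, median error %.1f deg -> %s\n",
              nrow(x$windows), x$median_error_deg,
              if (x$passes_criterion) "passes criterion" else "fails criterion"))
  invisible(x)
}
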