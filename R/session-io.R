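#' Construct a recording-session object
#'
#' A session bundles the tracked head position on the circular track, the
#' sorted single-unit spike trains, one or more LFP channels, and the
#' run/rest schedule for one recording day. Units with whole-day mean rates
#' above the interneuron threshold are flagged (not removed).
#'
#' @param position data.frame with columns `t` (s, strictly increasing) and
#'   `angle_deg` (degrees in `[0, 360)`); an optional `speed_cm_s` column is
#'   kept, otherwise speed is derived with [compute_speed()].
#' @param units list of spike trains; each element a list with `unit_id` and
#'   sorted `spike_t` (s).
#' @param lfp list of LFP channels; each a list with `fs_hz`, `samples`
#'   (microvolts) and `t0` (s).
#' @param schedule data.frame with `label` (`run1..run4`, `rest1..rest5`),
#'   `start_s`, `end_s`; epochs must be strictly ordered and non-overlapping.
#' @param track_circumference_cm track length; default a 1 m diameter
#'   circle, `100 * pi` cm.
#' @param ground_truth optional [ground_truth()] carried along by the
#'   synthetic generator.
#' @param cfg an [analysis_config()].
#' @return an object of class `place_session`.
#' @export
place_session <- function(position, units, lfp = list(), schedule,
                          track_circumference_cm = 100 * pi,
                          ground_truth = NULL, cfg = analysis_config()) {
  stopifnot(is.data.frame(position), all(c("t", "angle_deg") %in% names(position)))
  stopifnot(is.data.frame(schedule),
            all(c("label", "start_s", "end_s") %in% names(schedule)))
  stopifnot(track_circumference_cm > 0)
  position$angle_deg <- wrap_deg(position$angle_deg)
  if (!"speed_cm_s" %in% names(position)) {
    position <- compute_speed(position, track_circumference_cm)
  }
  dur <- max(schedule$end_s) - min(schedule$start_s)
  units <- lapply(units, function(u) {
    u$spike_t <- sort(as.numeric(u$spike_t))
    u$mean_rate_hz <- length(u$spike_t) / dur
    u$is_interneuron <- u$mean_rate_hz > cfg$interneuron_hz
    u
  })
  s <- structure(
    list(position = position, units = units, lfp = lfp,
         schedule = schedule,
         track_circumference_cm = track_circumference_cm,
         ground_truth = ground_truth),
    class = "place_session"
  )
  problems <- validate_session(s)
  if (length(problems)) {
    stop("invalid session: ", paste(problems, collapse = "; "))
  }
  s
}

#' Validate session invariants
#'
#' Checks timestamp monotonicity, schedule ordering, and that spikes and LFP
#' extents fall inside the scheduled day.
#'
#' @param session a `place_session` (or a candidate list with its fields).
#' @return character vector of problems; empty when valid.
#' @export
validate_session <- function(session) {
  p <- character(0)
  t <- session$position$t
  if (any(diff(t) <= 0)) {
    p <- c(p, sprintf("position timestamps not strictly increasing at index %d",
                      which(diff(t) <= 0)[1] + 1L))
  }
  sch <- session$schedule
  if (nrow(sch) > 1) {
    if (any(diff(sch$start_s) <= 0) ||
        any(sch$start_s[-1] < sch$end_s[-nrow(sch)] - 1e-9)) {
      p <- c(p, "schedule epochs overlap or are out of order")
    }
  }
  if (any(sch$end_s <= sch$start_s)) p <- c(p, "schedule epoch with end <= start")
  t0 <- min(sch$start_s); t1 <- max(sch$end_s)
  for (u in session$units) {
    if (length(u$spike_t) && (min(u$spike_t) < t0 - 1e-9 ||
                              max(u$spike_t) > t1 + 1e-9)) {
      p <- c(p, sprintf("unit %s has spikes outside the schedule", u$unit_id))
    }
    if (is.unsorted(u$spike_t)) {
      p <- c(p, sprintf("unit %s spike times not sorted", u$unit_id))
    }
  }
  for (i in seq_along(session$lfp)) {
    ch <- session$lfp[[i]]
    if (ch$fs_hz <= 0) p <- c(p, sprintf("lfp channel %d has fs <= 0", i))
    tend <- ch$t0 + (length(ch$samples) - 1) / ch$fs_hz
    if (ch$t0 < t0 - 1e-9 || tend > t1 + 1e-6) {
      p <- c(p, sprintf("lfp channel %d extends outside the schedule", i))
    }
  }
  p
}

#' @export
print.place_session <- function(x, ...) {
  sch <- x$schedule
  cat("<place_session>\n")
  cat(sprintf("  %d position samples over %.1f s (%.2f Hz)\n",
              nrow(x$position), diff(range(x$position$t)),
              1 / stats::median(diff(x$position$t))))
  cat(sprintf("  %d units (%d flagged interneuron), %d LFP channel(s)\n",
              length(x$units),
              sum(vapply(x$units, `[[`, logical(1), "is_interneuron")),
              length(x$lfp)))
  cat(sprintf("  schedule: %s\n", paste(sch$label, collapse = " ")))
  if (!is.null(x$ground_truth)) cat("  ground truth attached\n")
  invisible(x)
}

#' Derive running speed from the tracked angle
#'
#' Central difference on the unwrapped angle (shortest-arc increments, so a
#' wrap from 358 to 2 degrees counts as +4, not -356), converted to cm/s via
#' the track circumference, then boxcar-smoothed to suppress tracker jitter.
#'
#' @param trace data.frame with `t` and `angle_deg`.
#' @param circumference_cm track circumference.
#' @param smooth_n boxcar width in samples (default 5, about 167 ms at
#'   29.97 Hz); use 1 for no smoothing.
#' @return `trace` with a `speed_cm_s` column.
#' @export
compute_speed <- function(trace, circumference_cm = 100 * pi, smooth_n = 5L) {
  stopifnot(nrow(trace) >= 2)
  t <- trace$t
  if (any(diff(t) == 0)) stop("duplicate timestamps in position trace")
  u <- unwrap_deg(trace$angle_deg)
  n <- length(u)
  v <- numeric(n)
  v[1] <- (u[2] - u[1]) / (t[2] - t[1])
  v[n] <- (u[n] - u[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) {
    v[2:(n - 1)] <- (u[3:n] - u[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  }
  speed <- abs(v) * circumference_cm / 360
  if (smooth_n > 1 && n >= smooth_n) {
    k <- rep(1 / smooth_n, smooth_n)
    num <- stats::convolve(speed, rev(k), type = "open")
    den <- stats::convolve(rep(1, n), rev(k), type = "open")
    h <- (smooth_n - 1) %/% 2
    idx <- seq.int(h + 1, h + n)
    speed <- num[idx] / den[idx]
  }
  trace$speed_cm_s <- speed
  trace
}

#' Per-run-session behavior metrics
#'
#' Mean running speed (speed-gated, samples faster than `cfg$speed_min` only)
#' and completed lap count for every run epoch of the day. A lap is counted
#' each time the unwrapped angle advances a further full 360 degrees in the
#' running direction.
#'
#' @param session a `place_session`.
#' @param cfg an [analysis_config()].
#' @return data.frame with `label`, `mean_run_speed_cm_s`, `n_laps`.
#' @export
behavior_metrics <- function(session, cfg = analysis_config()) {
  sch <- session$schedule
  runs <- sch[grepl("^run", sch$label), , drop = FALSE]
  out <- data.frame(label = runs$label,
                    mean_run_speed_cm_s = NA_real_,
                    n_laps = NA_integer_)
  for (i in seq_len(nrow(runs))) {
    sel <- session$position$t >= runs$start_s[i] &
      session$position$t <= runs$end_s[i]
    if (!any(sel)) {
      warning(sprintf("run epoch %s contains no position samples", runs$label[i]))
      next
    }
    pos <- session$position[sel, ]
    sp <- pos$speed_cm_s[pos$speed_cm_s > cfg$speed_min]
    out$mean_run_speed_cm_s[i] <- if (length(sp)) mean(sp) else NA_real_
    u <- unwrap_deg(pos$angle_deg)
    disp <- u - u[1]
    dir <- sign(disp[length(disp)])
    if (dir == 0) dir <- 1
    out$n_laps[i] <- as.integer(floor(max(dir * disp, 0) / 360))
  }
  out
}

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

#' Save / load a session directory
#'
#' The on-disk layout is one directory per session-day: `position.csv`
#' (t, angle_deg, speed_cm_s), `spikes.csv` (unit_id, t), `lfp<k>.csv` (one
#' microvolt column per channel), and `metadata.yaml` (schedule, sampling
#' rates, circumference, unit ids, optional generator ground truth) -- flat,
#' language-neutral and diffable.
#'
#' @param session a `place_session`.
#' @param path directory to write (created if needed).
#' @return `save_session` returns `path` invisibly; `load_session` returns a
#'   validated `place_session`.
#' @export
save_session <- function(session, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  pos <- session$position
  utils::write.csv(
    data.frame(t = fmt_num(pos$t), angle_deg = fmt_num(pos$angle_deg),
               speed_cm_s = fmt_num(pos$speed_cm_s)),
    file.path(path, "position.csv"), row.names = FALSE, quote = FALSE)
  sp <- do.call(rbind, lapply(session$units, function(u) {
    if (!length(u$spike_t)) return(NULL)
    data.frame(unit_id = u$unit_id, t = fmt_num(u$spike_t))
  }))
  if (is.null(sp)) sp <- data.frame(unit_id = character(0), t = character(0))
  utils::write.csv(sp, file.path(path, "spikes.csv"),
                   row.names = FALSE, quote = FALSE)
  for (i in seq_along(session$lfp)) {
    utils::write.csv(data.frame(uv = fmt_num(session$lfp[[i]]$samples)),
                     file.path(path, sprintf("lfp%d.csv", i)),
                     row.names = FALSE, quote = FALSE)
  }
  meta <- list(
    track_circumference_cm = session$track_circumference_cm,
    schedule = lapply(seq_len(nrow(session$schedule)), function(i) {
      as.list(session$schedule[i, c("label", "start_s", "end_s")])
    }),
    units = lapply(session$units, function(u) list(unit_id = u$unit_id)),
    lfp = lapply(session$lfp, function(ch) list(fs_hz = ch$fs_hz, t0 = ch$t0))
  )
  if (!is.null(session$ground_truth)) {
    meta$ground_truth <- serialize_ground_truth(session$ground_truth)
  }
  yaml::write_yaml(meta, file.path(path, "metadata.yaml"))
  invisible(path)
}

#' @rdname save_session
#' @param cfg an [analysis_config()] (used to flag interneurons on load).
#' @export
load_session <- function(path, cfg = analysis_config()) {
  need <- c("position.csv", "spikes.csv", "metadata.yaml")
  for (f in need) {
    if (!file.exists(file.path(path, f))) {
      stop(sprintf("missing session file: %s", file.path(path, f)))
    }
  }
  meta <- yaml::read_yaml(file.path(path, "metadata.yaml"))
  pos <- utils::read.csv(file.path(path, "position.csv"),
                         colClasses = "numeric")
  spikes <- utils::read.csv(file.path(path, "spikes.csv"),
                            colClasses = c("character", "numeric"))
  schedule <- do.call(rbind, lapply(meta$schedule, function(e) {
    data.frame(label = e$label, start_s = e$start_s, end_s = e$end_s)
  }))
  units <- lapply(meta$units, function(u) {
    list(unit_id = u$unit_id,
         spike_t = spikes$t[spikes$unit_id == u$unit_id])
  })
  lfp <- list()
  for (i in seq_along(meta$lfp)) {
    f <- file.path(path, sprintf("lfp%d.csv", i))
    if (!file.exists(f)) stop(sprintf("missing session file: %s", f))
    lfp[[i]] <- list(fs_hz = meta$lfp[[i]]$fs_hz,
                     samples = utils::read.csv(f, colClasses = "numeric")$uv,
                     t0 = meta$lfp[[i]]$t0)
  }
  gt <- if (!is.null(meta$ground_truth)) {
    deserialize_ground_truth(meta$ground_truth)
  }
  place_session(position = pos, units = units, lfp = lfp,
                schedule = schedule,
                track_circumference_cm = meta$track_circumference_cm,
                ground_truth = gt, cfg = cfg)
}

# Epoch lookup; label like "run1" or "rest3".
epoch_bounds <- function(session, label) {
  i <- match(label, session$schedule$label)
  if (is.na(i)) stop(sprintf("no epoch labeled %s in schedule", label))
  c(session$schedule$start_s[i], session$schedule$end_s[i])
}

run_labels <- function(session) {
  session$schedule$label[grepl("^run", session$schedule$label)]
}

rest_labels <- function(session) {
  session$schedule$label[grepl("^rest", session$schedule$label)]
}
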