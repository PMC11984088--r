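# Interpolate track angle (via the unwrapped trace, so wraps are safe) and
# speed at arbitrary times.
angle_at_time <- function(position, t) {
  u <- unwrap_deg(position$angle_deg)
  wrap_deg(stats::approx(position$t, u, xout = t, rule = 2)$y)
}

speed_at_time <- function(position, t) {
  stats::approx(position$t, position$speed_cm_s, xout = t, rule = 2)$y
}

#' Occupancy-normalized firing-rate map
#'
#' Divides the circular track into `360 / bin_deg` bins (90 bins of 4
#' degrees by default), counts speed-gated spikes per bin, divides by the
#' speed-gated time spent in each bin, and circularly smooths the result
#' with a wrap-around Gaussian kernel (SD `smooth_deg`). Samples and spikes
#' at speeds at or below `cfg$speed_min` are excluded. Bins with zero gated
#' occupancy are set to 0 Hz before smoothing.
#'
#' @param spike_t spike times of one unit, s.
#' @param position position trace (data.frame `t`, `angle_deg`,
#'   `speed_cm_s`).
#' @param epoch numeric length-2 `(start_s, end_s)`; only samples and spikes
#'   inside it are used.
#' @param cfg an [analysis_config()].
#' @param unit_id,session_label metadata carried on the result.
#' @param smooth set `FALSE` to keep the raw binned rate.
#' @return an object of class `rate_map` with fields `bin_deg`,
#'   `occupancy_s`, `spike_counts`, `rate_hz` (smoothed), `raw_rate_hz`,
#'   `mean_rate_hz` (occupancy-weighted), `peak_rate_hz`.
#' @export
compute_rate_map <- function(spike_t, position, epoch, cfg = analysis_config(),
                             unit_id = NA_character_,
                             session_label = NA_character_, smooth = TRUE) {
  nb <- n_bins_for(cfg)
  sel <- position$t >= epoch[1] & position$t < epoch[2]
  pos <- position[sel, , drop = FALSE]
  if (!nrow(pos)) stop("no position samples in epoch")
  dt <- diff(pos$t)
  dt <- c(dt, stats::median(dt))
  gated <- pos$speed_cm_s > cfg$speed_min
  if (!any(gated)) stop("no qualifying samples (all below the speed gate)")
  bin_of <- function(a) pmin(nb, floor(wrap_deg(a) / cfg$bin_deg) + 1L)
  occ <- numeric(nb)
  tb <- tapply(dt[gated], bin_of(pos$angle_deg[gated]), sum)
  occ[as.integer(names(tb))] <- tb

  st <- spike_t[spike_t >= epoch[1] & spike_t < epoch[2]]
  if (length(st)) {
    st <- st[speed_at_time(pos, st) > cfg$speed_min]
  }
  counts <- numeric(nb)
  if (length(st)) {
    cb <- table(bin_of(angle_at_time(pos, st)))
    counts[as.integer(names(cb))] <- as.numeric(cb)
  }
  raw <- ifelse(occ > 0, counts / pmax(occ, .Machine$double.eps), 0)
  rate <- if (smooth) smooth_circular(raw, cfg$smooth_deg / cfg$bin_deg) else raw
  p <- occ / sum(occ)
  structure(
    list(bin_deg = cfg$bin_deg,
         occupancy_s = occ,
         spike_counts = counts,
         raw_rate_hz = raw,
         rate_hz = rate,
         mean_rate_hz = sum(p * rate),
         peak_rate_hz = max(rate),
         unit_id = unit_id,
         session_label = session_label),
    class = "rate_map")
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf("<rate_map> unit %s session %s: %d bins of %g deg, peak %.2f Hz, mean %.2f Hz\n",
              x$unit_id, x$session_label, length(x$rate_hz), x$bin_deg,
              x$peak_rate_hz, x$mean_rate_hz))
  invisible(x)
}

#' Day-averaged rate map from pooled spikes and occupancy
#'
#' The day map pools spike counts and gated occupancy across run sessions
#' and re-applies the rate definition (it is not the mean of the session
#' maps), then smooths. A unit is flagged for inclusion when the day map's
#' peak reaches `cfg$peak_min_hz`.
#'
#' @param maps list of `rate_map`s for the same unit with identical binning.
#' @param cfg an [analysis_config()].
#' @return a `rate_map` with an extra logical field `include_for_analysis`.
#' @export
day_average_map <- function(maps, cfg = analysis_config()) {
  stopifnot(length(maps) >= 1)
  nb <- length(maps[[1]]$rate_hz)
  if (!all(vapply(maps, function(m) length(m$rate_hz) == nb &&
                  m$bin_deg == maps[[1]]$bin_deg, logical(1)))) {
    stop("rate maps have mismatched binning")
  }
  occ <- Reduce(`+`, lapply(maps, `[[`, "occupancy_s"))
  counts <- Reduce(`+`, lapply(maps, `[[`, "spike_counts"))
  raw <- ifelse(occ > 0, counts / pmax(occ, .Machine$double.eps), 0)
  rate <- smooth_circular(raw, cfg$smooth_deg / cfg$bin_deg)
  p <- occ / sum(occ)
  m <- structure(
    list(bin_deg = maps[[1]]$bin_deg,
         occupancy_s = occ,
         spike_counts = counts,
         raw_rate_hz = raw,
         rate_hz = rate,
         mean_rate_hz = sum(p * rate),
         peak_rate_hz = max(rate),
         unit_id = maps[[1]]$unit_id,
         session_label = "day"),
    class = "rate_map")
  m$include_for_analysis <- m$peak_rate_hz >= cfg$peak_min_hz
  m
}

#' Spatial correlation between two rate maps
#'
#' Pearson correlation of the binned rate vectors, the standard
#' across-session stability measure.
#'
#' @param a,b `rate_map`s with identical binning.
#' @return correlation in `[-1, 1]`, or `NA` (with a warning) if either map
#'   has zero variance.
#' @export
spatial_correlation <- function(a, b) {
  if (length(a$rate_hz) != length(b$rate_hz)) stop("mismatched binning")
  if (stats::sd(a$rate_hz) == 0 || stats::sd(b$rate_hz) == 0) {
    warning("zero-variance rate map; spatial correlation undefined")
    return(NA_real_)
  }
  stats::cor(a$rate_hz, b$rate_hz)
}

#' Rate overlap between two rate maps
#'
#' Ratio of the two mean firing rates with the larger rate as the
#' denominator, so the overlap lies in `[0, 1]`.
#'
#' @param a,b `rate_map`s.
#' @return ratio in `[0, 1]`, or `NA` (with a warning) when both means are 0.
#' @export
rate_overlap <- function(a, b) {
  la <- a$mean_rate_hz; lb <- b$mean_rate_hz
  if (la == 0 && lb == 0) {
    warning("both mean rates are zero; rate overlap undefined")
    return(NA_real_)
  }
  min(la, lb) / max(la, lb)
}

#' Spatial information (bits per spike)
#'
#' Skaggs information of a rate map,
#' `SI = sum_i P_i (lambda_i / lambda) log2(lambda_i / lambda)`, where `P_i`
#' is the occupancy probability of bin `i`, `lambda_i` its firing rate, and
#' `lambda` the occupancy-weighted overall mean rate. Bins with zero rate
#' contribute zero.
#'
#' @param map a `rate_map`.
#' @return bits per spike (non-negative), or `NA` with a warning when the
#'   overall mean rate is zero.
#' @export
spatial_information <- function(map) {
  p <- map$occupancy_s / sum(map$occupancy_s)
  lam_i <- map$rate_hz
  lam <- sum(p * lam_i)
  if (lam == 0) {
    warning("overall mean rate is zero; spatial information undefined")
    return(NA_real_)
  }
  i <- lam_i > 0
  sum(p[i] * (lam_i[i] / lam) * log2(lam_i[i] / lam))
}

#' Detect place fields in a smoothed rate map
#'
#' Rates are z-scored across bins (unweighted mean/SD); bins with z at or
#' above `field_z_enter` seed fields, which extend circularly in both
#' directions to the points where z falls below `field_z_exit`; touching
#' regions merge. Fields must reach `peak_min_hz` at their peak and span at
#' least `field_min_deg`.
#'
#' @param map a smoothed `rate_map`.
#' @param cfg an [analysis_config()].
#' @return data.frame with one row per field: `start_deg`, `end_deg`
#'   (circular interval in the direction of increasing angle), `size_deg`,
#'   `peak_rate_hz`, `peak_angle_deg`, `n_bins`. Zero rows when the map has
#'   no variance or no field survives the thresholds.
#' @export
detect_place_fields <- function(map, cfg = analysis_config()) {
  empty <- data.frame(start_deg = numeric(0), end_deg = numeric(0),
                      size_deg = numeric(0), peak_rate_hz = numeric(0),
                      peak_angle_deg = numeric(0), n_bins = integer(0))
  r <- map$rate_hz
  nb <- length(r)
  if (stats::sd(r) == 0) return(empty)
  z <- (r - mean(r)) / stats::sd(r)
  above <- z >= cfg$field_z_exit
  if (!any(above) || all(above)) return(empty)
  # circular connected components of `above`
  d <- diff(c(above[nb], above))
  starts <- which(d == 1)
  ends <- which(d == -1) - 1L
  ends[ends == 0L] <- nb
  # align each start with its end (wrap-aware)
  fields <- empty
  for (s in starts) {
    e <- ends[ends >= s]
    e <- if (length(e)) min(e) else min(ends) + nb   # wraps past bin nb
    bins <- ((seq.int(s, e) - 1L) %% nb) + 1L
    if (!any(z[bins] >= cfg$field_z_enter)) next     # no seed bin inside
    size <- length(bins) * map$bin_deg
    peak <- max(r[bins])
    if (peak < cfg$peak_min_hz || size < cfg$field_min_deg) next
    fields <- rbind(fields, data.frame(
      start_deg = (s - 1L) * map$bin_deg,
      end_deg = wrap_deg(((e - 1L) %% nb + 1L) * map$bin_deg),
      size_deg = size,
      peak_rate_hz = peak,
      peak_angle_deg = (bins[which.max(r[bins])] - 0.5) * map$bin_deg,
      n_bins = length(bins)))
  }
  fields
}

#' Session and day rate maps for every unit
#'
#' Computes one rate map per unit per run session plus the pooled
#' day-averaged map, and flags units for inclusion (place cells): not a
#' putative interneuron (whole-day mean rate at or below
#' `cfg$interneuron_hz`) and day-map peak at or above `cfg$peak_min_hz`.
#'
#' @param session a `place_session`.
#' @param cfg an [analysis_config()].
#' @return list with `session_maps` (list over units of lists over run
#'   sessions), `day_maps` (list over units), and `included` (logical per
#'   unit).
#' @export
day_rate_maps <- function(session, cfg = analysis_config()) {
  runs <- run_labels(session)
  session_maps <- vector("list", length(session$units))
  day_maps <- vector("list", length(session$units))
  for (j in seq_along(session$units)) {
    u <- session$units[[j]]
    maps <- lapply(runs, function(lab) {
      compute_rate_map(u$spike_t, session$position,
                       epoch_bounds(session, lab), cfg,
                       unit_id = u$unit_id, session_label = lab)
    })
    names(maps) <- runs
    session_maps[[j]] <- maps
    day_maps[[j]] <- day_average_map(maps, cfg)
  }
  included <- vapply(seq_along(session$units), function(j) {
    !session$units[[j]]$is_interneuron &&
      isTRUE(day_maps[[j]]$include_for_analysis)
  }, logical(1))
  names(session_maps) <- names(day_maps) <- names(included) <-
    vapply(session$units, `[[`, character(1), "unit_id")
  list(session_maps = session_maps, day_maps = day_maps, included = included)
}
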