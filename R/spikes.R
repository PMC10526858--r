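#' Detect calcium transients by threshold and rise time
#'
#' Implements the operational spike criterion: a calcium transient is a
#' fast (< `max_rise_s`) increase of the fluorescence signal above
#' `k_sd` standard deviations of the background noise.  Per ROI, the noise
#' scale is 1.4826 x MAD of the background frames (supra-threshold runs
#' and their decay tails are masked by a provisional pass), divided by the
#' known noise attenuation of any recorded median filtering so the
#' threshold stays in unsmoothed-background units.  A run of consecutive
#' supra-threshold frames yields one spike at its maximum (earliest frame
#' on ties); the event counts as fast when the signal rose from background
#' within the step budget implied by `max_rise_s` (one inter-frame step at
#' the defaults, extended by the median filter's half-width) or climbed by
#' the full threshold within that budget.  Later local maxima in the same
#' run are extra spikes only if they bring their own full-size fast climb
#' (bursts riding on a decaying transient); slow ramps are rejected
#' however high they end.  See the package vignette for the full rule.
#'
#' @param tm a [trace_matrix()], background-subtracted and median-filtered
#'   (see [subtract_background()], [median_filter_traces()]).
#' @param k_sd threshold in noise-SD units (default 2).
#' @param max_rise_s maximum rise time in seconds (exclusive bound).
#' @param sd_method `"mad"` for the robust scale (default; transients
#'   inflate the naive SD) or `"sd"` for the plain standard deviation.
#' @param per_roi if `FALSE`, a single global noise scale (pooled over all
#'   ROIs) is used instead of per-ROI scales.
#' @param noise_attenuation factor by which prior smoothing shrank the
#'   background noise; the estimated scale is divided by it so the
#'   threshold stays in units of the unsmoothed background SD.  Defaults
#'   to the theoretical white-noise attenuation of the median filter
#'   recorded by [median_filter_traces()] (1 for unfiltered input).
#' @param sigma optional known noise scale (recycled per ROI); when given,
#'   the per-ROI estimation is skipped entirely.
#' @return A [spike_train_set()] with 0-based frame indices; attribute
#'   `"peak_over_sigma"` holds, per ROI, the peak height in sigma units
#'   for each detected spike.
#' @examples
#' cfg <- sim_config(n_neurons = 5, duration_s = 60, drift_amp = 0, seed = 5)
#' tm <- render_traces(simulate_spike_trains(cfg)$spikes, cfg)
#' det <- detect_spikes(median_filter_traces(subtract_background(tm, 60)))
#' @export
detect_spikes <- function(tm, k_sd = 2, max_rise_s = 0.4,
                          sd_method = c("mad", "sd"), per_roi = TRUE,
                          noise_attenuation = NULL, sigma = NULL) {
  stopifnot(inherits(tm, "trace_matrix"))
  check_number(k_sd, "k_sd", min = 0, strict_min = TRUE)
  check_number(max_rise_s, "max_rise_s", min = 0, strict_min = TRUE)
  sd_method <- match.arg(sd_method)
  if (is.null(noise_attenuation)) {
    mw <- attr(tm, "median_window")
    noise_attenuation <- if (is.null(mw)) 1 else median_attenuation(mw)
  }
  check_number(noise_attenuation, "noise_attenuation", min = 0,
               strict_min = TRUE)
  dt <- tm$meta$frame_interval_s
  max_steps <- max(1L, floor((max_rise_s - 1e-9) / dt))
  # a centred median filter can delay the apparent peak by up to its
  # half-width; the rise-from-background budget allows for that smear
  mw_attr <- attr(tm, "median_window")
  smear <- if (is.null(mw_attr)) 0L else as.integer(mw_attr) %/% 2L
  scale_of <- function(x) if (sd_method == "mad") mad(x) else sd(x)
  # background noise scale: estimated on background frames only, by a
  # two-pass scheme -- a provisional scale flags supra-threshold runs,
  # which are masked together with their decay tails (frames until the
  # trace falls back within one provisional SD of the centre) before the
  # final estimate.  Transient tails otherwise shift the median up and
  # inflate the scale by several percent.
  background_scale <- function(x) {
    s1 <- scale_of(x) / noise_attenuation
    if (!is.finite(s1) || s1 == 0) return(c(s1, median(x)))
    c1 <- median(x)
    mask <- rep(FALSE, length(x))
    above <- (x - c1) >= k_sd * s1
    i <- 1L
    while (i <= length(x)) {
      if (above[i]) {
        j <- i
        while (j <= length(x) && (x[j] - c1) >= s1) j <- j + 1L
        mask[i:min(j, length(x))] <- TRUE
        i <- j + 1L
      } else i <- i + 1L
    }
    xq <- x[!mask]
    if (length(xq) < 10L) return(c(s1, c1))
    c(scale_of(xq) / noise_attenuation, median(xq))
  }
  if (is.null(sigma)) {
    bg <- apply(tm$values, 2L, background_scale)
    sigmas <- bg[1L, ]
    centers <- bg[2L, ]
    if (!per_roi) {
      g <- background_scale(as.numeric(tm$values))
      sigmas[] <- g[1L]
      centers[] <- g[2L]
    }
  } else {
    sigmas <- rep_len(sigma, ncol(tm$values))
    centers <- apply(tm$values, 2L, median)
  }
  trains <- vector("list", ncol(tm$values))
  scores <- vector("list", ncol(tm$values))
  for (j in seq_len(ncol(tm$values))) {
    x <- tm$values[, j]
    sigma_j <- unname(sigmas[j])
    if (!is.finite(sigma_j) || sigma_j == 0) {
      warning(sprintf("ROI '%s': zero noise scale, no spikes detected",
                      tm$roi_ids[j]), call. = FALSE)
      trains[[j]] <- integer(0)
      scores[[j]] <- numeric(0)
      next
    }
    sigma <- sigma_j
    # threshold relative to the robust centre: quiescent segments of a
    # percentile-baseline-subtracted trace sit slightly above zero
    center <- unname(centers[j])
    supra <- (x - center) >= k_sd * sigma
    peaks <- integer(0)
    pk_scores <- numeric(0)
    r <- rle(supra)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (run in which(r$values)) {
      s <- starts[run]; e <- ends[run]
      # local maxima within the run, plateau ties resolved to the earliest
      # frame
      is_max <- vapply(s:e, function(m) {
        (m == e || x[m] >= x[m + 1L]) && (m == s || x[m] > x[m - 1L])
      }, logical(1))
      maxima <- (s:e)[is_max]
      prev <- NA_integer_
      for (m in maxima) {
        if (is.na(prev)) {
          # first event of the run is fast if either
          #  (a) the signal was at background level (within one SD of the
          #      centre) no more than max_steps + smear frames before the
          #      peak -- the rise from background fit the time budget, or
          #  (b) the signal climbed by the full threshold within the step
          #      budget somewhere between onset and peak (strong-jump
          #      evidence even when pre-peak samples sit elevated), or
          #  (c) the rise is clipped by the recording start.
          # noise flickers on the decaying tail of an earlier transient
          # satisfy neither (a) (background lies many frames back) nor
          # (b) (the tail supplies no full-size climb)
          bg <- which((x[seq_len(m - 1L)] - center) <= sigma)
          last_bg <- if (length(bg)) bg[length(bg)] else 0L
          ts <- s:m
          climbs <- x[ts] - x[pmax(1L, ts - max_steps)]
          fast <- (m - last_bg) <= (max_steps + smear) ||
            any(climbs >= k_sd * sigma) || (s - max_steps) < 1L
        } else {
          # further events in the same supra-threshold run (bursts riding
          # on a decaying transient) need their own full-size fast climb;
          # plateau wiggles never supply one and stay merged
          ts <- (prev + 1L):m
          climbs <- x[ts] - x[pmax(prev, ts - max_steps)]
          fast <- any(climbs >= k_sd * sigma)
        }
        if (fast) {
          peaks <- c(peaks, m)
          pk_scores <- c(pk_scores, (x[m] - center) / sigma)
          prev <- m
        }
      }
      # nothing qualified (e.g. a slow ramp): the run yields no spike
    }
    trains[[j]] <- peaks - 1L                  # to 0-based frames
    scores[[j]] <- pk_scores
  }
  names(trains) <- tm$roi_ids
  out <- spike_train_set(trains, n_frames = nrow(tm$values),
                         frame_interval_s = dt)
  attr(out, "peak_over_sigma") <- scores
  out
}

#' Per-recording activity summaries
#'
#' @param spikes a [spike_train_set()].
#' @return An object of class `spike_stats`: `per_roi_rate` (spikes per
#'   minute, one entry per ROI), `active_fraction` (share of ROIs with at
#'   least one spike), `n_rois`, and `duration_s`.
#' @examples
#' st <- spike_train_set(list(a = c(10L, 50L), b = integer(0)),
#'                       n_frames = 900, frame_interval_s = 0.2)
#' spike_stats(st)
#' @export
spike_stats <- function(spikes) {
  stopifnot(inherits(spikes, "spike_train_set"))
  duration_s <- spikes$n_frames * spikes$frame_interval_s
  if (duration_s <= 0) stop_contract("zero-duration recording")
  counts <- lengths(spikes$trains)
  structure(list(
    per_roi_rate = counts / (duration_s / 60),
    active_fraction = mean(counts > 0),
    n_rois = length(counts),
    duration_s = duration_s
  ), class = "spike_stats")
}

#' @export
print.spike_stats <- function(x, ...) {
  cat(sprintf(
    "<spike_stats> %d ROIs over %.1f s: %.2f spikes/min (mean), %.0f%% active\n",
    x$n_rois, x$duration_s, mean(x$per_roi_rate), 100 * x$active_fraction))
  invisible(x)
}

#' Match detected spikes to ground truth
#'
#' Greedy one-to-one matching of detected to true spike frames within a
#' frame tolerance, per ROI; used to score the detector on simulations.
#'
#' @param detected,truth [spike_train_set()]s over the same ROIs (matched
#'   by position).
#' @param tol_frames match tolerance in frames (default 1).
#' @return A list with `sensitivity`, `precision`, `n_true`, `n_detected`,
#'   `n_matched`.
#' @export
match_spikes <- function(detected, truth, tol_frames = 1L) {
  stopifnot(inherits(detected, "spike_train_set"),
            inherits(truth, "spike_train_set"),
            length(detected$trains) == length(truth$trains))
  n_true <- 0L; n_det <- 0L; n_match <- 0L
  for (i in seq_along(truth$trains)) {
    tt <- truth$trains[[i]]
    dd <- detected$trains[[i]]
    n_true <- n_true + length(tt)
    n_det <- n_det + length(dd)
    used <- rep(FALSE, length(dd))
    for (f in tt) {
      cand <- which(!used & abs(dd - f) <= tol_frames)
      if (length(cand)) {
        used[cand[which.min(abs(dd[cand] - f))]] <- TRUE
        n_match <- n_match + 1L
      }
    }
  }
  list(sensitivity = if (n_true) n_match / n_true else NA_real_,
       precision = if (n_det) n_match / n_det else NA_real_,
       n_true = n_true, n_detected = n_det, n_matched = n_match)
}
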