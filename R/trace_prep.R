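# Running lower-percentile baseline of a frames x K matrix, computed at
# anchor frames every `window/4` frames (truncated windows at the edges)
# and linearly interpolated in between.  The anchored evaluation keeps the
# cost independent of the window length; the interpolation error is
# negligible for baselines varying on scales >> window/4 frames.
rolling_quantile <- function(mat, window, p = 0.2) {
  n <- nrow(mat)
  half <- window %/% 2L
  step <- max(1L, window %/% 4L)
  anchors <- unique(c(seq(1L, n, by = step), n))
  qa <- matrix(NA_real_, length(anchors), ncol(mat))
  for (a in seq_along(anchors)) {
    i <- anchors[a]
    rows <- max(1L, i - half):min(n, i + half)
    qa[a, ] <- apply(mat[rows, , drop = FALSE], 2L, quantile,
                     probs = p, names = FALSE, type = 7)
  }
  out <- matrix(NA_real_, n, ncol(mat))
  for (j in seq_len(ncol(mat)))
    out[, j] <- approx(anchors, qa[, j], xout = seq_len(n), rule = 2)$y
  out
}

# Full baseline estimate: a running lower-percentile pass followed by a
# transient-masked running-mean refinement.  The percentile pass tracks
# slow drift but sits below the true baseline by construction (about
# 0.84 sigma for Gaussian noise at the 20th percentile) and lags on
# slopes; the second pass re-centres it on the quiescent mean, excluding
# frames more than 2 robust SD above the provisional baseline so
# transients do not bias it upward.
baseline_estimate <- function(mat, window, p = 0.2) {
  n <- nrow(mat)
  b1 <- rolling_quantile(mat, window, p)
  resid <- mat - b1
  half <- window %/% 2L
  step <- max(1L, window %/% 4L)
  anchors <- unique(c(seq(1L, n, by = step), n))
  b2 <- matrix(0, n, ncol(mat))
  for (j in seq_len(ncol(mat))) {
    r <- resid[, j]
    s <- mad(r)
    quiet <- if (s > 0) r <= median(r) + 2 * s else rep(TRUE, n)
    ra <- vapply(anchors, function(i) {
      rows <- max(1L, i - half):min(n, i + half)
      rq <- r[rows][quiet[rows]]
      if (length(rq)) mean(rq) else NA_real_
    }, numeric(1))
    if (anyNA(ra)) {
      if (all(is.na(ra))) ra[] <- 0
      else ra <- approx(anchors[!is.na(ra)], ra[!is.na(ra)],
                        xout = anchors, rule = 2)$y
    }
    b2[, j] <- approx(anchors, ra, xout = seq_len(n), rule = 2)$y
  }
  b1 + b2
}

#' Subtract a slowly varying baseline
#'
#' Estimates, per ROI trace (or per pixel for an image stack), a running
#' 20th-percentile baseline over a sliding window and subtracts it, so that
#' quiescent segments end up near zero (a transient-masked running-mean
#' refinement re-centres the percentile estimate) while transients much
#' shorter than the window are preserved.  The baseline is attached as attribute
#' `"baseline"`, so `output + baseline` reconstructs the input exactly.
#'
#' @param x a [trace_matrix()] or a height x width x frames array.
#' @param window_frames window length in frames (>= 3, <= recording
#'   length).  The default 150 frames corresponds to 30 s at a 0.2 s frame
#'   interval.
#' @param p percentile used as the baseline estimate, in (0, 1).
#' @return Same type as `x`, baseline-subtracted, with attribute
#'   `"baseline"`.
#' @export
subtract_background <- function(x, window_frames = 150L, p = 0.2) {
  UseMethod("subtract_background")
}

#' @export
subtract_background.trace_matrix <- function(x, window_frames = 150L,
                                             p = 0.2) {
  n <- nrow(x$values)
  check_number(window_frames, "window_frames", min = 3, integerish = TRUE)
  if (window_frames > n)
    stop_contract("window_frames (%d) exceeds recording length (%d)",
                  window_frames, n)
  base <- baseline_estimate(x$values, as.integer(window_frames), p)
  out <- trace_matrix(x$values - base, roi_ids = x$roi_ids, meta = x$meta)
  attr(out, "baseline") <- base
  out
}

#' @export
subtract_background.array <- function(x, window_frames = 150L, p = 0.2) {
  stopifnot(length(dim(x)) == 3L)
  n <- dim(x)[3]
  check_number(window_frames, "window_frames", min = 3, integerish = TRUE)
  if (window_frames > n)
    stop_contract("window_frames (%d) exceeds recording length (%d)",
                  window_frames, n)
  d <- dim(x)
  flat <- t(matrix(x, nrow = d[1] * d[2], ncol = n))   # frames x pixels
  base <- baseline_estimate(flat, as.integer(window_frames), p)
  out <- array(t(flat - base), dim = d)
  attr(out, "baseline") <- array(t(base), dim = d)
  out
}

#' Detect disk-like ROIs in a background-subtracted stack
#'
#' Computes the temporal-mean image, smooths it with a Gaussian,
#' thresholds at `mean + threshold_sd * SD` of the smoothed image, labels
#' connected components and keeps those whose pixel area lies in
#' `[min_area_px, max_area_px]`.  Deterministic; an empty result is not an
#' error.
#'
#' @param stack height x width x frames array (background-subtracted).
#' @param min_area_px,max_area_px component area bounds in pixels.
#' @param threshold_sd threshold in SD units above the mean of the
#'   smoothed mean image.
#' @param smooth_sigma Gaussian smoothing sigma in pixels.
#' @return A [roi_set()]; zero ROIs if nothing passes the filters.
#' @export
detect_rois <- function(stack, min_area_px = 20, max_area_px = 500,
                        threshold_sd = 3, smooth_sigma = 1) {
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  mean_img <- rowMeans(stack, dims = 2L)
  sm <- if (smooth_sigma > 0)
    EBImage::gblur(mean_img, sigma = smooth_sigma) else mean_img
  thr <- mean(sm) + threshold_sd * sd(sm)
  bw <- sm > thr
  if (!any(bw))
    return(roi_set(centroids = matrix(numeric(0), 0, 2),
                   masks = list(), radii = numeric(0)))
  lab <- EBImage::bwlabel(bw)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area_px & areas <= max_area_px)
  if (!length(keep))
    return(roi_set(centroids = matrix(numeric(0), 0, 2),
                   masks = list(), radii = numeric(0)))
  h <- nrow(mean_img)
  masks <- lapply(keep, function(k) which(lab == k))
  centroids <- t(vapply(masks, function(m) {
    r <- (m - 1L) %% h + 1L
    c <- (m - 1L) %/% h + 1L
    c(mean(r), mean(c))
  }, numeric(2)))
  roi_set(centroids = centroids, masks = masks,
          radii = sqrt(lengths(masks) / pi))
}

#' Extract per-ROI mean-intensity traces from a stack
#'
#' @param stack height x width x frames array.
#' @param rois a [roi_set()] with at least one ROI.
#' @param meta a [recording_meta()] for the recording.
#' @return A [trace_matrix()]: `trace[t, i]` is the mean intensity over
#'   ROI `i`'s mask at frame `t`.
#' @export
extract_traces <- function(stack, rois, meta) {
  stopifnot(is.array(stack), length(dim(stack)) == 3L,
            inherits(rois, "roi_set"))
  if (length(rois$masks) == 0L)
    stop_contract("ROI set is empty")
  d <- dim(stack)
  npix <- d[1] * d[2]
  bad <- vapply(rois$masks,
                function(m) any(m < 1L | m > npix), logical(1))
  if (any(bad))
    stop_contract("ROI mask %d extends outside the image", which(bad)[1])
  flat <- matrix(stack, nrow = npix, ncol = d[3])
  vals <- vapply(rois$masks,
                 function(m) colMeans(flat[m, , drop = FALSE]),
                 numeric(d[3]))
  trace_matrix(as.matrix(vals),
               roi_ids = sprintf("roi_%03d", seq_along(rois$masks)),
               meta = meta)
}

shrunken_median <- function(x, half) {
  n <- length(x)
  out <- numeric(n)
  for (t in seq_len(n))
    out[t] <- median(x[max(1L, t - half):min(n, t + half)])
  out
}

#' Median-filter traces over time
#'
#' Replaces each sample with the median of a centered window of odd length
#' (default 3 consecutive frames).  Edges use shrunken, asymmetric windows
#' rather than padding, so no data is invented at the recording boundary.
#'
#' Note that a window-3 median erases 1-frame impulses: transients must
#' outlast a single frame (indicator decay spanning >= 2 frames) to survive
#' filtering, which the default simulator kinetics (tau 0.5 s at 0.2 s
#' frames) satisfy.
#'
#' @param tm a [trace_matrix()].
#' @param window odd window length >= 3.
#' @return A [trace_matrix()] of identical dimensions.
#' @export
median_filter_traces <- function(tm, window = 3L) {
  stopifnot(inherits(tm, "trace_matrix"))
  check_number(window, "window", min = 3, integerish = TRUE)
  if (window %% 2L == 0L)
    stop_contract("'window' must be odd, got %d", window)
  half <- as.integer(window) %/% 2L
  v <- tm$values
  n <- nrow(v)
  out <- v
  if (window == 3L && n >= 3L) {
    # vectorized 3-point median: a+b+c - max - min
    a <- v[1:(n - 2L), , drop = FALSE]
    b <- v[2:(n - 1L), , drop = FALSE]
    c_ <- v[3:n, , drop = FALSE]
    out[2:(n - 1L), ] <- a + b + c_ - pmax(a, b, c_) - pmin(a, b, c_)
    out[1L, ] <- (v[1L, ] + v[2L, ]) / 2        # median of 2 values
    out[n, ] <- (v[n - 1L, ] + v[n, ]) / 2
  } else {
    for (j in seq_len(ncol(v))) out[, j] <- shrunken_median(v[, j], half)
  }
  res <- trace_matrix(out, roi_ids = tm$roi_ids, meta = tm$meta)
  # downstream noise estimation needs to know the smoothing that was
  # applied, because the spike threshold is defined in units of the
  # *unsmoothed* background noise
  attr(res, "median_window") <- as.integer(window)
  res
}

# Standard deviation of the median of `window` i.i.d. standard normal
# variables, by numerical integration of the order-statistic density;
# the factor by which a running median attenuates white Gaussian noise.
median_attenuation <- function(window) {
  w <- as.integer(window)
  if (w <= 1L) return(1)
  k <- (w - 1L) %/% 2L
  dens <- function(m)
    exp(lgamma(w + 1) - 2 * lgamma(k + 1)) *
      pnorm(m)^k * (1 - pnorm(m))^k * stats::dnorm(m)
  v <- stats::integrate(function(m) m^2 * dens(m), -Inf, Inf)$value
  sqrt(v)
}
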