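#' Binarize spike trains into an activity matrix
#'
#' @param spikes a [spike_train_set()].
#' @param bin_frames bin width in frames (>= 1).
#' @return A bins x ROIs 0/1 matrix; an entry is 1 iff the ROI fired at
#'   least once in that bin.
#' @export
binarize_trains <- function(spikes, bin_frames = 1L) {
  stopifnot(inherits(spikes, "spike_train_set"))
  check_number(bin_frames, "bin_frames", min = 1, integerish = TRUE)
  n_bins <- as.integer(ceiling(spikes$n_frames / bin_frames))
  m <- matrix(0L, n_bins, length(spikes$trains),
              dimnames = list(NULL, names(spikes$trains)))
  for (j in seq_along(spikes$trains)) {
    tr <- spikes$trains[[j]]
    if (length(tr)) m[unique(tr %/% bin_frames) + 1L, j] <- 1L
  }
  m
}

#' Zero-lag cross-correlation matrix
#'
#' Pairwise Pearson correlation of activity columns at zero lag.  Columns
#' with zero variance (silent ROIs) are retained: they get correlation 0
#' off-diagonal and 1 on the diagonal, with a warning, so the matrix order
#' always matches the ROI count.
#'
#' @param activity time x ROIs numeric matrix (binary or real), >= 2
#'   columns and >= 2 rows.
#' @param drop_silent if `TRUE`, zero-variance columns are dropped instead
#'   of retained.
#' @return A symmetric `cross_corr_matrix` with unit diagonal.
#' @examples
#' a <- cbind(x = c(0, 1, 0, 1), y = c(0, 1, 0, 1), z = c(1, 0, 1, 0))
#' cross_correlation(a)
#' @export
cross_correlation <- function(activity, drop_silent = FALSE) {
  if (!is.matrix(activity) || !is.numeric(activity + 0))
    stop_contract("'activity' must be a numeric matrix")
  if (ncol(activity) < 2L)
    stop_contract("need at least 2 ROIs to correlate, got %d", ncol(activity))
  if (nrow(activity) < 2L)
    stop_contract("need at least 2 time bins, got %d", nrow(activity))
  v <- apply(activity, 2L, var)
  silent <- v == 0
  if (any(silent)) {
    if (drop_silent) {
      activity <- activity[, !silent, drop = FALSE]
      if (ncol(activity) < 2L)
        stop_contract("fewer than 2 non-silent ROIs remain")
      silent <- rep(FALSE, ncol(activity))
    } else {
      warning(sprintf("%d silent ROI(s): correlation set to 0 off-diagonal",
                      sum(silent)), call. = FALSE)
    }
  }
  C <- suppressWarnings(cor(activity))
  C[is.na(C)] <- 0
  diag(C) <- 1
  C <- (C + t(C)) / 2
  structure(C, class = c("cross_corr_matrix", "matrix", "array"),
            roi_ids = colnames(activity))
}

#' @export
print.cross_corr_matrix <- function(x, ...) {
  n <- nrow(x)
  off <- x[upper.tri(x)]
  cat(sprintf("<cross_corr_matrix> %d x %d; mean off-diagonal r = %.3f\n",
              n, n, mean(off)))
  invisible(x)
}

#' Eigenvalue synchrony of a cross-correlation matrix
#'
#' The eigenvalue spectrum of the N x N correlation matrix summarises
#' network coordination: independent activity gives a flat spectrum near
#' 1, while network-wide co-activation concentrates variance in the
#' leading eigenvalue (up to N for perfect synchrony).  The scalar
#' synchrony index is `lambda_max / N`, in (0, 1].
#'
#' @param C a `cross_corr_matrix` (see [cross_correlation()]), or any
#'   symmetric correlation-like matrix with unit diagonal.
#' @param tol symmetry tolerance.
#' @return An object of class `synchrony_result`: `eigenvalues`
#'   (descending), `lambda_max`, `sync_index`, `n_rois`.
#' @examples
#' C <- cross_correlation(cbind(a = c(0, 1, 1, 0), b = c(0, 1, 0, 1),
#'                              c = c(1, 1, 0, 0)))
#' synchrony_spectrum(C)
#' @export
synchrony_spectrum <- function(C, tol = 1e-8) {
  M <- unclass(C)
  if (!is.matrix(M) || nrow(M) != ncol(M))
    stop_contract("'C' must be a square matrix")
  if (max(abs(M - t(M))) > tol)
    stop_contract("matrix is not symmetric within tolerance %g", tol)
  if (max(abs(diag(M) - 1)) > tol)
    stop_contract("correlation matrix must have unit diagonal")
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  n <- nrow(M)
  structure(list(eigenvalues = ev, lambda_max = ev[1L],
                 sync_index = ev[1L] / n, n_rois = n),
            class = "synchrony_result")
}

#' @export
print.synchrony_result <- function(x, ...) {
  cat(sprintf(
    "<synchrony_result> N = %d; lambda_max = %.3f; sync index = %.4f\n",
    x$n_rois, x$lambda_max, x$sync_index))
  invisible(x)
}

# simulate -> render -> background-subtract -> median-filter -> detect ->
# binarize -> correlate -> spectrum; one field of view end to end.
pipeline_sync_index <- function(cfg, k_sd = 2, max_rise_s = 0.4,
                                window_frames = 150L, median_window = 3L,
                                bin_frames = 1L) {
  sim <- simulate_spike_trains(cfg)
  tm <- render_traces(sim$spikes, cfg)
  tm <- subtract_background(tm, window_frames = window_frames)
  tm <- median_filter_traces(tm, window = median_window)
  det <- suppressWarnings(detect_spikes(tm, k_sd = k_sd,
                                        max_rise_s = max_rise_s))
  act <- binarize_trains(det, bin_frames = bin_frames)
  C <- suppressWarnings(cross_correlation(act))
  list(sync = synchrony_spectrum(C), spikes = det, truth = sim$spikes)
}

#' Synchrony as a function of the shared-event participation probability
#'
#' Runs the full analysis chain (simulate, render, background-subtract,
#' median-filter, detect spikes, binarize, correlate, eigen-decompose) on
#' a grid of `sync_p` values, several seeds per grid point, and summarises
#' the synchrony index per grid point.
#'
#' @param sync_p_grid numeric vector of participation probabilities, >= 2
#'   points.
#' @param n_seeds seeds per grid point (>= 3).
#' @param base_cfg a [sim_config()] providing all other parameters; its
#'   seed is the root from which per-run seeds are derived.
#' @param ... passed to the detection stage (`k_sd`, `max_rise_s`,
#'   `window_frames`, `median_window`, `bin_frames`).
#' @return A data frame with columns `sync_p`, `mean_sync_index`,
#'   `sd_sync_index`, `n_seeds`; attribute `"per_seed"` holds the full
#'   grid x seed matrix of indices.
#' @export
sync_curve <- function(sync_p_grid = c(0, 0.3, 0.6, 1.0), n_seeds = 5L,
                       base_cfg = sim_config(), ...) {
  if (length(sync_p_grid) < 2L)
    stop_contract("need at least 2 grid points")
  check_number(n_seeds, "n_seeds", min = 3, integerish = TRUE)
  per_seed <- matrix(NA_real_, length(sync_p_grid), n_seeds)
  for (g in seq_along(sync_p_grid)) {
    for (s in seq_len(n_seeds)) {
      cfg <- base_cfg
      cfg$sync_p <- sync_p_grid[g]
      cfg$seed <- child_seed(base_cfg$seed, sprintf("curve_%d_%d", g, s))
      per_seed[g, s] <- pipeline_sync_index(cfg, ...)$sync$sync_index
    }
  }
  out <- data.frame(sync_p = sync_p_grid,
                    mean_sync_index = rowMeans(per_seed),
                    sd_sync_index = apply(per_seed, 1L, sd),
                    n_seeds = n_seeds)
  attr(out, "per_seed") <- per_seed
  out
}

#' Circular-shift permutation null for the synchrony index
#'
#' Destroys inter-neuron timing while preserving each train's spike count
#' and autostructure: every train is circularly shifted by an independent
#' uniform offset, and the synchrony index of the shifted data is
#' recomputed.  The observed index of genuinely synchronous data should
#' exceed this null.
#'
#' @param spikes a [spike_train_set()].
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param bin_frames bin width for [binarize_trains()].
#' @return Numeric vector of `n_perm` null synchrony indices.
#' @export
sync_permutation_null <- function(spikes, n_perm = 100L, seed = 1,
                                  bin_frames = 1L) {
  stopifnot(inherits(spikes, "spike_train_set"))
  check_number(n_perm, "n_perm", min = 1, integerish = TRUE)
  nf <- spikes$n_frames
  with_seed(child_seed(seed, "sync_null"), {
    vapply(seq_len(n_perm), function(p) {
      shifted <- lapply(spikes$trains, function(tr) {
        if (!length(tr)) return(tr)
        sort((tr + sample.int(nf, 1L)) %% nf)
      })
      st <- spike_train_set(shifted, n_frames = nf,
                            frame_interval_s = spikes$frame_interval_s)
      act <- binarize_trains(st, bin_frames = bin_frames)
      C <- suppressWarnings(cross_correlation(act))
      synchrony_spectrum(C)$sync_index
    }, numeric(1))
  })
}
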