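#' Simulation configuration for synthetic calcium recordings
#'
#' Bundles every parameter of the forward model: per-neuron Poisson spiking
#' with optional shared network events, a linear-rise / exponential-decay
#' indicator kernel, slow sinusoidal baseline drift and i.i.d. Gaussian
#' noise, sampled on a regular frame grid.  Defaults reproduce the recording
#' geometry the pipeline targets: 1000 frames at 0.2 s intervals (about
#' 3 min per field).
#'
#' @param n_neurons number of simulated neurons (ROIs).
#' @param duration_s recording length in seconds.
#' @param frame_interval_s sampling interval in seconds.
#' @param rate_hz private (per-neuron) Poisson spike rate in Hz.
#' @param sync_p probability, in \[0, 1\], that a neuron joins any given
#'   shared network event; the single synchrony knob.
#' @param sync_rate_hz rate of shared network events in Hz.
#' @param amplitude peak fluorescence change per spike (arbitrary units).
#' @param tau_decay_s exponential decay constant of the indicator, seconds.
#' @param rise_frames frames from transient onset to peak.
#' @param baseline constant fluorescence offset.
#' @param drift_amp amplitude of a slow sinusoidal baseline drift (one full
#'   cycle over the recording).
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param seed integer root seed; all stochastic stages derive named
#'   substreams from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_neurons = 10, duration_s = 60, seed = 1)
#' @export
sim_config <- function(n_neurons = 50, duration_s = 200, frame_interval_s = 0.2,
                       rate_hz = 0.05, sync_p = 0, sync_rate_hz = 0.2,
                       amplitude = 6, tau_decay_s = 0.5, rise_frames = 1,
                       baseline = 100, drift_amp = 2, noise_sd = 1, seed = 1) {
  check_number(n_neurons, "n_neurons", min = 1, integerish = TRUE)
  check_number(duration_s, "duration_s", min = 0, strict_min = TRUE)
  check_number(frame_interval_s, "frame_interval_s", min = 0, strict_min = TRUE)
  check_number(rate_hz, "rate_hz", min = 0)
  check_number(sync_p, "sync_p", min = 0, max = 1)
  check_number(sync_rate_hz, "sync_rate_hz", min = 0)
  check_number(amplitude, "amplitude", min = 0)
  check_number(tau_decay_s, "tau_decay_s", min = 0, strict_min = TRUE)
  check_number(rise_frames, "rise_frames", min = 1, integerish = TRUE)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(drift_amp, "drift_amp", min = 0)
  check_number(seed, "seed", integerish = TRUE)
  cfg <- list(
    n_neurons = as.integer(n_neurons), duration_s = duration_s,
    frame_interval_s = frame_interval_s, rate_hz = rate_hz, sync_p = sync_p,
    sync_rate_hz = sync_rate_hz, amplitude = amplitude,
    tau_decay_s = tau_decay_s, rise_frames = as.integer(rise_frames),
    baseline = baseline, drift_amp = drift_amp, noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  cfg$n_frames <- as.integer(floor(duration_s / frame_interval_s))
  if (cfg$n_frames < 2)
    stop_contract("configuration yields fewer than 2 frames")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate spike trains with tunable shared-event synchrony
#'
#' Each neuron fires private spikes as a homogeneous Poisson process at
#' `rate_hz`; in addition, shared network events occur as a Poisson process
#' at `sync_rate_hz`, and each neuron independently joins each event with
#' probability `sync_p`.  Spike times are quantized to frames; multiple
#' spikes landing on one frame are merged.
#'
#' @param cfg a [sim_config()].
#' @return A list with `spikes`, a [spike_train_set()] (frame indices are
#'   0-based), and `shared_event_frames`, the sorted frames of the shared
#'   events (regardless of participation).
#' @examples
#' sim <- simulate_spike_trains(sim_config(n_neurons = 5, seed = 2))
#' lengths(sim$spikes$trains)
#' @export
simulate_spike_trains <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n_frames <- cfg$n_frames
  with_seed(child_seed(cfg$seed, "spikes"), {
    n_events <- rpois(1L, cfg$sync_rate_hz * cfg$duration_s)
    event_frames <- sort(unique(floor(runif(n_events) * n_frames)))
    trains <- vector("list", cfg$n_neurons)
    for (i in seq_len(cfg$n_neurons)) {
      n_priv <- rpois(1L, cfg$rate_hz * cfg$duration_s)
      priv <- floor(runif(n_priv) * n_frames)
      joins <- if (length(event_frames))
        event_frames[runif(length(event_frames)) < cfg$sync_p] else integer(0)
      trains[[i]] <- sort(unique(as.integer(c(priv, joins))))
    }
    names(trains) <- sprintf("roi_%03d", seq_len(cfg$n_neurons))
    list(
      spikes = spike_train_set(trains, n_frames = n_frames,
                               frame_interval_s = cfg$frame_interval_s),
      shared_event_frames = as.integer(event_frames)
    )
  })
}

# Indicator kernel sampled on the frame grid: linear rise over `rise_frames`
# frames to `amplitude`, peaking AT the spike frame (offset 0), then
# exponential decay with time constant `tau_decay_s`.  Anchoring the peak
# on the spike frame keeps detected peak frames aligned with ground truth.
indicator_kernel <- function(cfg, n_frames) {
  decay_len <- min(n_frames, ceiling(10 * cfg$tau_decay_s / cfg$frame_interval_s))
  rise <- cfg$amplitude * seq_len(cfg$rise_frames) / cfg$rise_frames
  decay <- cfg$amplitude *
    exp(-(seq_len(decay_len)) * cfg$frame_interval_s / cfg$tau_decay_s)
  structure(c(rise, decay), peak_offset = cfg$rise_frames)
}

#' Render fluorescence traces from spike trains
#'
#' Each trace is `baseline + drift + sum of spike kernels + noise`.  The
#' kernel rises linearly over `rise_frames` frames to `amplitude` (peaking
#' at the spike frame, with the rise preceding it) and then decays
#' exponentially with constant `tau_decay_s`; overlapping transients sum.
#' Drift is one sinusoidal cycle of amplitude `drift_amp` over the
#' recording; noise is i.i.d. Gaussian.
#'
#' @param spikes a [spike_train_set()], e.g. from [simulate_spike_trains()].
#' @param cfg the [sim_config()] the trains were generated under.
#' @return A [trace_matrix()] of dimension frames x neurons.
#' @examples
#' cfg <- sim_config(n_neurons = 3, duration_s = 40, seed = 3)
#' tm <- render_traces(simulate_spike_trains(cfg)$spikes, cfg)
#' dim(tm$values)
#' @export
render_traces <- function(spikes, cfg) {
  stopifnot(inherits(spikes, "spike_train_set"), inherits(cfg, "sim_config"))
  n_frames <- spikes$n_frames
  if (n_frames != cfg$n_frames)
    stop_contract("spike trains have %d frames but cfg implies %d",
                  n_frames, cfg$n_frames)
  n <- length(spikes$trains)
  kern <- indicator_kernel(cfg, n_frames)
  klen <- length(kern)
  t_s <- (seq_len(n_frames) - 1L) * cfg$frame_interval_s
  drift <- cfg$drift_amp * sin(2 * pi * t_s / cfg$duration_s)
  vals <- matrix(cfg$baseline + drift, nrow = n_frames, ncol = n)
  peak_off <- attr(kern, "peak_offset")
  for (i in seq_len(n)) {
    for (f0 in spikes$trains[[i]]) {
      idx <- (f0 + 1L) - peak_off + seq_len(klen)   # peak at the spike frame
      keep <- idx >= 1L & idx <= n_frames
      if (any(keep))
        vals[idx[keep], i] <- vals[idx[keep], i] + kern[keep]
    }
  }
  if (cfg$noise_sd > 0) {
    vals <- vals + with_seed(
      child_seed(cfg$seed, "trace_noise"),
      matrix(rnorm(n_frames * n, sd = cfg$noise_sd), n_frames, n)
    )
  }
  trace_matrix(vals, roi_ids = names(spikes$trains),
               meta = recording_meta(frame_interval_s = cfg$frame_interval_s,
                                     n_frames = n_frames,
                                     source = "synthetic"))
}

#' Render a synthetic movie of disk-shaped ROIs
#'
#' Places non-overlapping disk ROIs at random positions; every pixel of a
#' disk follows that ROI's trace (plus optional pixel noise), background
#' pixels are zero-mean noise.  Intensities are quantized to 16-bit
#' integers so TIFF round trips are lossless.
#'
#' @param traces a [trace_matrix()]; one ROI per column.
#' @param image_hw height/width of the frames in pixels, length-2 integer.
#' @param roi_radius disk radius in pixels.
#' @param seed integer seed for placement and pixel noise.
#' @param pixel_noise_sd standard deviation of per-pixel Gaussian noise.
#' @return A list with `stack` (height x width x frames integer array),
#'   and `rois`, a [roi_set()] holding the true centroids and masks.
#' @examples
#' cfg <- sim_config(n_neurons = 3, duration_s = 20, seed = 4)
#' tm <- render_traces(simulate_spike_trains(cfg)$spikes, cfg)
#' mv <- render_movie(tm, image_hw = c(48, 48), roi_radius = 4, seed = 4)
#' dim(mv$stack)
#' @export
render_movie <- function(traces, image_hw = c(128L, 128L), roi_radius = 5,
                         seed = 1, pixel_noise_sd = 0) {
  stopifnot(inherits(traces, "trace_matrix"), length(image_hw) == 2L)
  h <- as.integer(image_hw[1]); w <- as.integer(image_hw[2])
  n_rois <- ncol(traces$values)
  n_frames <- nrow(traces$values)
  r <- roi_radius
  if (h < 2 * r + 3 || w < 2 * r + 3)
    stop_contract("image too small for ROI radius %g", r)
  with_seed(child_seed(seed, "movie"), {
    centers <- matrix(NA_real_, n_rois, 2)
    for (i in seq_len(n_rois)) {
      placed <- FALSE
      for (try in seq_len(2000L)) {
        cand <- c(runif(1, r + 1, h - r), runif(1, r + 1, w - r))
        if (i == 1L ||
            all(sqrt(rowSums((centers[seq_len(i - 1L), , drop = FALSE] -
                              matrix(cand, i - 1L, 2, byrow = TRUE))^2)) >
                2 * r + 2)) {
          centers[i, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop_contract(
          "could not place %d non-overlapping ROIs of radius %g in %dx%d",
          n_rois, r, h, w)
    }
    px_row <- matrix(rep(seq_len(h), w), h, w)
    px_col <- matrix(rep(seq_len(w), each = h), h, w)
    masks <- lapply(seq_len(n_rois), function(i) {
      which((px_row - centers[i, 1])^2 + (px_col - centers[i, 2])^2 <= r^2)
    })
    stack <- array(0, dim = c(h, w, n_frames))
    if (pixel_noise_sd > 0)
      stack[] <- rnorm(length(stack), sd = pixel_noise_sd)
    for (i in seq_len(n_rois)) {
      npix <- length(masks[[i]])
      for (t in seq_len(n_frames)) {
        stack[masks[[i]] + (t - 1L) * h * w] <-
          stack[masks[[i]] + (t - 1L) * h * w] + traces$values[t, i]
      }
    }
    storage <- round(pmin(pmax(stack, 0), 65535))
    list(
      stack = storage,
      rois = roi_set(centroids = centers, masks = masks,
                     radii = rep(r, n_rois))
    )
  })
}

#' Configuration for synthetic single-cell count matrices
#'
#' Negative-binomial UMI-like counts for a conditions x cell-types design
#' with a chosen fraction of genes carrying a planted log2 fold change in
#' one random (cell type, non-reference condition) group.  The first
#' condition label is the reference.
#'
#' @param n_genes number of genes.
#' @param cells_per_group cells in each (condition, cell type) group.
#' @param conditions condition labels; first is the reference.
#' @param cell_types cell-type labels.
#' @param baseline_mean negative-binomial mean of unperturbed genes.
#' @param dispersion negative-binomial size parameter; variance is
#'   `mean + mean^2 / dispersion`, so large values approach Poisson.
#' @param de_fraction fraction of genes with a planted effect.
#' @param planted_log2fc log2 fold change planted in affected groups.
#' @param seed integer seed.
#' @return An object of class `count_sim_config`.
#' @export
count_sim_config <- function(n_genes = 2000, cells_per_group = 200,
                             conditions = c("control", "APPWT", "APPV717L"),
                             cell_types = c("astrocyte", "glutamatergic",
                                            "GABAergic", "NPC"),
                             baseline_mean = 5, dispersion = 2,
                             de_fraction = 0.1, planted_log2fc = 1,
                             seed = 1) {
  check_number(n_genes, "n_genes", min = 1, integerish = TRUE)
  check_number(cells_per_group, "cells_per_group", min = 3, integerish = TRUE)
  check_number(baseline_mean, "baseline_mean", min = 0, strict_min = TRUE)
  check_number(dispersion, "dispersion", min = 0, strict_min = TRUE)
  check_number(de_fraction, "de_fraction", min = 0, max = 1)
  check_number(planted_log2fc, "planted_log2fc")
  check_number(seed, "seed", integerish = TRUE)
  if (length(conditions) < 2L)
    stop_contract("'conditions' needs at least 2 labels")
  if (anyDuplicated(conditions) || anyDuplicated(cell_types))
    stop_contract("condition and cell-type labels must be unique")
  structure(list(
    n_genes = as.integer(n_genes),
    cells_per_group = as.integer(cells_per_group),
    conditions = as.character(conditions),
    cell_types = as.character(cell_types),
    baseline_mean = baseline_mean, dispersion = dispersion,
    de_fraction = de_fraction, planted_log2fc = planted_log2fc,
    seed = as.integer(seed)
  ), class = "count_sim_config")
}

#' Simulate a single-cell count matrix with planted effects
#'
#' @param cfg a [count_sim_config()].
#' @return A list with `counts` (genes x cells integer matrix), `meta` (a
#'   data frame with `cell_id`, `condition`, `cell_type`), and `truth`, a
#'   data frame listing each planted gene with its affected cell type,
#'   condition and true log2 fold change (empty when `de_fraction = 0`).
#' @examples
#' sim <- simulate_counts(count_sim_config(n_genes = 50, cells_per_group = 5))
#' dim(sim$counts)
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "count_sim_config"))
  with_seed(child_seed(cfg$seed, "counts"), {
    groups <- expand.grid(condition = cfg$conditions,
                          cell_type = cfg$cell_types,
                          stringsAsFactors = FALSE)
    n_cells <- nrow(groups) * cfg$cells_per_group
    meta <- data.frame(
      cell_id = sprintf("cell_%05d", seq_len(n_cells)),
      condition = rep(groups$condition, each = cfg$cells_per_group),
      cell_type = rep(groups$cell_type, each = cfg$cells_per_group),
      stringsAsFactors = FALSE
    )
    n_de <- floor(cfg$de_fraction * cfg$n_genes)
    truth <- if (n_de > 0) {
      tr <- data.frame(
        gene = sprintf("gene_%05d", sort(sample.int(cfg$n_genes, n_de))),
        cell_type = sample(cfg$cell_types, n_de, replace = TRUE),
        condition = sample(cfg$conditions[-1L], n_de, replace = TRUE),
        true_log2fc = rep(abs(cfg$planted_log2fc), n_de),
        stringsAsFactors = FALSE
      )
      # mix up- and down-regulated genes within each affected group in the
      # linear-space proportion that leaves the group's expected library
      # size unchanged: planted effects must not leak compositional fold
      # changes into null genes through per-cell total-count scaling
      L <- abs(cfg$planted_log2fc)
      if (L > 0) {
        up_share <- (1 - 2^-L) / (2^L - 2^-L)
        for (grp in split(seq_len(n_de),
                          paste(tr$cell_type, tr$condition))) {
          n_up <- round(length(grp) * up_share)
          dn <- sample(grp, length(grp) - n_up)
          tr$true_log2fc[dn] <- -L
        }
      }
      tr
    } else {
      data.frame(gene = character(0), cell_type = character(0),
                 condition = character(0), true_log2fc = numeric(0))
    }
    gene_ids <- sprintf("gene_%05d", seq_len(cfg$n_genes))
    counts <- matrix(0L, cfg$n_genes, n_cells,
                     dimnames = list(gene_ids, meta$cell_id))
    for (g in seq_len(nrow(groups))) {
      cols <- which(meta$condition == groups$condition[g] &
                    meta$cell_type == groups$cell_type[g])
      mu <- rep(cfg$baseline_mean, cfg$n_genes)
      hit <- truth$condition == groups$condition[g] &
             truth$cell_type == groups$cell_type[g]
      if (any(hit)) {
        gi <- match(truth$gene[hit], gene_ids)
        mu[gi] <- mu[gi] * 2^truth$true_log2fc[hit]
      }
      counts[, cols] <- rnbinom(cfg$n_genes * length(cols),
                                mu = mu, size = cfg$dispersion)
    }
    storage.mode(counts) <- "integer"
    list(counts = counts, meta = meta, truth = truth)
  })
}
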