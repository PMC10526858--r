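test_that("a constant trace has zero background-subtracted residual", {
  tm <- trace_matrix(matrix(7, 200, 2), meta = flat_meta(200))
  out <- subtract_background(tm, window_frames = 50)
  expect_equal(max(abs(out$values)), 0, tolerance = 1e-9)
})

test_that("adding the baseline back reconstructs the input exactly", {
  cfg <- sim_config(n_neurons = 4, duration_s = 60, seed = 31)
  tm <- render_traces(simulate_spike_trains(cfg)$spikes, cfg)
  out <- subtract_background(tm, window_frames = 100)
  expect_equal(out$values + attr(out, "baseline"), tm$values,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("short transients survive baseline subtraction", {
  # constant 10 plus one kernel-shaped transient of height 8, window much
  # wider than the transient
  x <- rep(10, 400)
  x[200:206] <- 10 + 8 * exp(-(0:6) * 0.4)
  tm <- trace_matrix(matrix(x, ncol = 1), meta = flat_meta(400))
  out <- subtract_background(tm, window_frames = 150)
  expect_gt(max(out$values), 0.95 * 8)
  expect_lt(max(out$values), 1.05 * 8)
})

test_that("linear drift leaves a residual below the per-window drift", {
  n <- 500; slope <- 0.02
  tm <- trace_matrix(matrix(slope * seq_len(n), ncol = 1),
                     meta = flat_meta(n))
  out <- subtract_background(tm, window_frames = 100)
  expect_lt(max(abs(out$values)), slope * 100)
})

test_that("median filtering matches its defining arithmetic", {
  tm <- trace_matrix(matrix(c(0, 0, 10, 0, 0), ncol = 1),
                     meta = flat_meta(5))
  expect_equal(as.numeric(median_filter_traces(tm)$values),
               c(0, 0, 0, 0, 0))
  const <- trace_matrix(matrix(3, 10, 2), meta = flat_meta(10))
  expect_equal(median_filter_traces(const)$values, const$values,
               ignore_attr = TRUE)
  mono <- trace_matrix(matrix(cumsum(runif(50)), ncol = 1),
                       meta = flat_meta(50))
  mf <- median_filter_traces(mono)
  expect_equal(mf$values[2:49, 1], mono$values[2:49, 1])
  expect_error(median_filter_traces(const, window = 4), "odd")
})

test_that("the window-3 median filter is idempotent on piecewise-constant signals", {
  x <- rep(c(0, 5, 5, 5, 2, 2, 2, 2, 8, 8, 8), each = 4)
  tm <- trace_matrix(matrix(x, ncol = 1), meta = flat_meta(length(x)))
  once <- median_filter_traces(tm)
  twice <- median_filter_traces(once)
  expect_equal(twice$values, once$values, ignore_attr = TRUE)
})

test_that("disk ROIs are recovered with matching centroids", {
  cfg <- sim_config(n_neurons = 10, duration_s = 60, noise_sd = 0,
                    drift_amp = 0, seed = 32)
  tm <- render_traces(simulate_spike_trains(cfg)$spikes, cfg)
  mv <- render_movie(tm, image_hw = c(96, 96), roi_radius = 4, seed = 32)
  rois <- detect_rois(mv$stack, min_area_px = 10, max_area_px = 200)
  expect_equal(length(rois), 10)
  d <- vapply(seq_len(length(rois)), function(i) {
    min(sqrt(rowSums(sweep(mv$rois$centroids, 2,
                           rois$centroids[i, ])^2)))
  }, numeric(1))
  expect_true(all(d <= 2))
})

test_that("ROI detection recall and precision hold across noise levels", {
  for (noise in c(0, 1, 2)) {
    cfg <- sim_config(n_neurons = 8, duration_s = 40, noise_sd = noise,
                      seed = 33)
    tm <- render_traces(simulate_spike_trains(cfg)$spikes, cfg)
    mv <- render_movie(tm, image_hw = c(80, 80), roi_radius = 4, seed = 33,
                       pixel_noise_sd = 2 * noise)
    rois <- detect_rois(mv$stack, min_area_px = 10, max_area_px = 200)
    matched <- vapply(seq_len(length(rois)), function(i) {
      min(sqrt(rowSums(sweep(mv$rois$centroids, 2,
                             rois$centroids[i, ])^2))) <= 3
    }, logical(1))
    expect_gte(sum(matched) / 8, 0.95)            # recall
    expect_gte(mean(matched), 0.95)               # precision
  }
})

test_that("blank and sub-threshold-size movies yield empty ROI sets", {
  blank <- array(0, dim = c(32, 32, 10))
  expect_equal(length(detect_rois(blank)), 0)
  cfg <- sim_config(n_neurons = 2, duration_s = 10, seed = 34)
  tm <- render_traces(simulate_spike_trains(cfg)$spikes, cfg)
  mv <- render_movie(tm, image_hw = c(48, 48), roi_radius = 2, seed = 34)
  # disks of radius 2 have ~13 px, below min_area_px = 20
  expect_equal(length(detect_rois(mv$stack, min_area_px = 20,
                                  max_area_px = 500)), 0)
})

test_that("trace extraction is exact for single-pixel masks and equivariant", {
  stack <- array(runif(6 * 6 * 20), dim = c(6, 6, 20))
  rois <- roi_set(centroids = rbind(c(2, 3), c(5, 5)),
                  masks = list(2L + (3L - 1L) * 6L, 5L + (5L - 1L) * 6L))
  tm <- extract_traces(stack, rois, flat_meta(20))
  expect_equal(tm$values[, 1], stack[2, 3, ])
  expect_equal(tm$values[, 2], stack[5, 5, ])
  swapped <- roi_set(rois$centroids[2:1, ], rois$masks[2:1])
  tm2 <- extract_traces(stack, swapped, flat_meta(20))
  expect_equal(unname(tm2$values), unname(tm$values[, 2:1]))
  bad <- roi_set(rbind(c(1, 1)), list(37L))
  expect_error(extract_traces(stack, bad, flat_meta(20)), "outside")
  expect_error(subtract_background(trace_matrix(matrix(1, 10, 1),
                                                meta = flat_meta(10)),
                                   window_frames = 11), "exceeds")
})
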