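test_that("zero-rate configurations yield empty spike trains", {
  cfg <- sim_config(n_neurons = 8, duration_s = 60, rate_hz = 0,
                    sync_rate_hz = 0, seed = 1)
  sim <- simulate_spike_trains(cfg)
  expect_true(all(lengths(sim$spikes$trains) == 0))
  expect_length(sim$shared_event_frames, 0)
})

test_that("full participation makes every train equal the shared events", {
  cfg <- sim_config(n_neurons = 6, duration_s = 120, rate_hz = 0,
                    sync_p = 1, sync_rate_hz = 0.3, seed = 2)
  sim <- simulate_spike_trains(cfg)
  expect_gt(length(sim$shared_event_frames), 0)
  for (tr in sim$spikes$trains)
    expect_identical(tr, sim$shared_event_frames)
})

test_that("private spike counts match the Poisson expectation", {
  # analytic oracle: mean count = rate * duration = 20; Monte-Carlo CI
  # over 1000 neurons is 20 +/- 3*sqrt(20/1000)
  cfg <- sim_config(n_neurons = 1000, duration_s = 200, rate_hz = 0.1,
                    sync_rate_hz = 0, seed = 3)
  counts <- lengths(simulate_spike_trains(cfg)$spikes$trains)
  expect_lt(abs(mean(counts) - 20), 3 * sqrt(20 / 1000))
})

test_that("spike counts are Poisson distributed when synchrony is off", {
  cfg <- sim_config(n_neurons = 1000, duration_s = 100, rate_hz = 0.1,
                    sync_rate_hz = 0, seed = 4)
  counts <- lengths(simulate_spike_trains(cfg)$spikes$trains)
  lambda <- 0.1 * 100
  # chi-square goodness of fit with tail bins pooled to expected >= 5
  brk <- qpois(c(0.001, seq(0.1, 0.9, by = 0.1), 0.999), lambda)
  brk <- sort(unique(c(-1, brk, Inf)))
  obs <- table(cut(counts, brk))
  pr <- diff(ppois(ifelse(is.finite(brk), brk, 1e9), lambda))
  res <- suppressWarnings(chisq.test(as.numeric(obs), p = pr,
                                     rescale.p = TRUE))
  expect_gt(res$p.value, 0.01)
})

test_that("pairwise train correlation is monotone in the synchrony knob", {
  mean_corr <- vapply(c(0, 0.3, 0.6, 1.0), function(p) {
    cfg <- sim_config(n_neurons = 30, duration_s = 200, rate_hz = 0.05,
                      sync_p = p, sync_rate_hz = 0.2, seed = 11)
    act <- binarize_trains(simulate_spike_trains(cfg)$spikes)
    C <- quiet_corr(act)
    mean(C[upper.tri(C)])
  }, numeric(1))
  expect_true(all(diff(mean_corr) > 0))
})

test_that("rendered kernel follows the closed-form rise and decay", {
  cfg <- sim_config(n_neurons = 1, duration_s = 40, rate_hz = 0,
                    sync_rate_hz = 0, amplitude = 6, tau_decay_s = 0.5,
                    baseline = 100, drift_amp = 0, noise_sd = 0, seed = 5)
  st <- spike_train_set(list(a = 100L), n_frames = cfg$n_frames,
                        frame_interval_s = 0.2)
  tm <- render_traces(st, cfg)
  x <- tm$values[, 1]
  expect_equal(x[101], 100 + 6)               # peak at the spike frame
  for (k in 1:5)
    expect_equal(x[101 + k], 100 + 6 * exp(-k * 0.2 / 0.5), tolerance = 1e-12)
  expect_equal(x[99], 100)                    # flat before the onset
})

test_that("a spikeless noiseless render is exactly the baseline", {
  cfg <- sim_config(n_neurons = 3, duration_s = 30, rate_hz = 0,
                    sync_rate_hz = 0, drift_amp = 0, noise_sd = 0,
                    baseline = 50, seed = 6)
  tm <- render_traces(simulate_spike_trains(cfg)$spikes, cfg)
  expect_true(all(tm$values == 50))
})

test_that("rendering is linear in the spike set", {
  cfg <- sim_config(n_neurons = 1, duration_s = 60, drift_amp = 0,
                    noise_sd = 0, baseline = 10, seed = 7)
  nf <- cfg$n_frames
  a <- spike_train_set(list(x = c(40L, 120L)), nf, 0.2)
  b <- spike_train_set(list(x = c(80L, 200L)), nf, 0.2)
  ab <- spike_train_set(list(x = sort(c(40L, 120L, 80L, 200L))), nf, 0.2)
  fa <- render_traces(a, cfg)$values - 10
  fb <- render_traces(b, cfg)$values - 10
  fab <- render_traces(ab, cfg)$values - 10
  expect_equal(fab, fa + fb, tolerance = 1e-12)
})

test_that("generators are bit-identical under a fixed seed", {
  cfg <- sim_config(n_neurons = 5, duration_s = 40, sync_p = 0.5, seed = 8)
  s1 <- simulate_spike_trains(cfg); s2 <- simulate_spike_trains(cfg)
  expect_identical(s1, s2)
  t1 <- render_traces(s1$spikes, cfg); t2 <- render_traces(s2$spikes, cfg)
  expect_identical(t1$values, t2$values)
  m1 <- render_movie(t1, image_hw = c(48, 48), roi_radius = 3, seed = 8)
  m2 <- render_movie(t2, image_hw = c(48, 48), roi_radius = 3, seed = 8)
  expect_identical(m1$stack, m2$stack)
  ccfg <- count_sim_config(n_genes = 50, cells_per_group = 4, seed = 8)
  expect_identical(simulate_counts(ccfg), simulate_counts(ccfg))
})

test_that("movie ROIs reproduce their generating traces", {
  cfg <- sim_config(n_neurons = 4, duration_s = 30, noise_sd = 0,
                    drift_amp = 0, seed = 9)
  tm <- render_traces(simulate_spike_trains(cfg)$spikes, cfg)
  mv <- render_movie(tm, image_hw = c(64, 64), roi_radius = 4, seed = 9)
  for (i in seq_len(4)) {
    roi_trace <- vapply(seq_len(dim(mv$stack)[3]), function(t) {
      fr <- mv$stack[, , t]
      mean(fr[mv$rois$masks[[i]]])
    }, numeric(1))
    expect_gt(cor(roi_trace, tm$values[, i]), 0.99)
  }
})

test_that("impossible ROI packings raise a placement error", {
  cfg <- sim_config(n_neurons = 40, duration_s = 10, seed = 10)
  tm <- render_traces(simulate_spike_trains(cfg)$spikes, cfg)
  expect_error(render_movie(tm, image_hw = c(32, 32), roi_radius = 6,
                            seed = 1),
               "non-overlapping")
})

test_that("count simulation honours the null configuration", {
  sim <- simulate_counts(count_sim_config(n_genes = 100, cells_per_group = 5,
                                          de_fraction = 0, seed = 12))
  expect_equal(nrow(sim$truth), 0)
  expect_equal(dim(sim$counts), c(100L, 5L * 3L * 4L))
  expect_true(all(sim$counts >= 0))
  expect_setequal(sim$meta$cell_id, colnames(sim$counts))
})

test_that("counts approach the Poisson limit at large dispersion", {
  sim <- simulate_counts(count_sim_config(
    n_genes = 400, cells_per_group = 500, conditions = c("a", "b"),
    cell_types = "t", baseline_mean = 5, dispersion = 1e6,
    de_fraction = 0, seed = 13))
  v <- apply(sim$counts, 1L, var)
  m <- rowMeans(sim$counts)
  # variance = mean + mean^2/size ~ mean; ratio concentrates around 1
  expect_lt(abs(mean(v / m) - 1), 0.05)
})

test_that("planted fold changes are recovered by group-mean ratios", {
  sim <- simulate_counts(count_sim_config(
    n_genes = 500, cells_per_group = 200, conditions = c("ctrl", "trt"),
    cell_types = "t", baseline_mean = 5, de_fraction = 0.2,
    planted_log2fc = 1, seed = 14))
  trt <- sim$meta$cell_id[sim$meta$condition == "trt"]
  ctl <- sim$meta$cell_id[sim$meta$condition == "ctrl"]
  est <- log2(rowMeans(sim$counts[sim$truth$gene, trt]) /
              rowMeans(sim$counts[sim$truth$gene, ctl]))
  # estimator concentrates: mean error inside the 0.15 band, no gross
  # outliers
  expect_lt(mean(abs(est - sim$truth$true_log2fc)), 0.15)
  expect_true(all(abs(est - sim$truth$true_log2fc) < 0.5))
})

test_that("invalid configurations name the offending field", {
  expect_error(sim_config(sync_p = 1.5), "sync_p")
  expect_error(sim_config(rate_hz = -1), "rate_hz")
  expect_error(sim_config(tau_decay_s = 0), "tau_decay_s")
  expect_error(count_sim_config(dispersion = 0), "dispersion")
  expect_error(count_sim_config(cells_per_group = 2), "cells_per_group")
  expect_error(count_sim_config(de_fraction = 2), "de_fraction")
})
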