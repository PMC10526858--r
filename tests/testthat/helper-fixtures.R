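# small shared fixtures; everything is generated in code at test time

quiet_detect <- function(tm, ...) suppressWarnings(detect_spikes(tm, ...))

quiet_corr <- function(activity, ...)
  suppressWarnings(cross_correlation(activity, ...))

# the standard recording geometry used throughout: 1000 frames at 0.2 s
std_cfg <- function(...) {
  args <- list(...)
  do.call(sim_config, args)
}

# full trace-domain chain: render -> background-subtract -> median-filter
prep_traces <- function(sim, cfg, window = 150L) {
  median_filter_traces(subtract_background(render_traces(sim$spikes, cfg),
                                           window_frames = window))
}

flat_meta <- function(n_frames, dt = 0.2) recording_meta(dt, n_frames)
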