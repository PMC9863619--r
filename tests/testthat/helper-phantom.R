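# Small phantom used by unit tests (full default size is exercised in the
# acceptance suite).

small_phantom_spec <- function(...) {
  args <- list(width = 96L, height = 96L, n_frames = 24L,
               base_axes = c(30, 30), cycles = 2L, seed = 7L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantom_spec, args)
}

# In-memory pipeline over phantom frames: segment with truth-derived
# scribbles, refine, score.
segment_phantom <- function(ph, params = graph_cut_params(),
                            erode_radius = 1L, scribble_seed = 11L) {
  lapply(seq_along(ph$frames), function(i) {
    seeds <- scribbles_from_truth(ph$truth$masks[[i]], seed = scribble_seed + i)
    refine_mask(segment_graph_cut(ph$frames[[i]], seeds, params), erode_radius)
  })
}
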