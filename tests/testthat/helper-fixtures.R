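# Shared in-code fixtures: tiny stacks, layouts and campaigns built at test
# time. Nothing is stored on disk beyond tempdir().

const_stack <- function(value, n_frames = 3L, dims = c(32L, 32L), ...) {
  frame_stack(array(as.integer(value), c(n_frames, dims)), ...)
}

tiny_layout <- function(side = 5L, dims = c(32L, 32L)) {
  surface_layout(data.frame(
    surface_name = c("sample", "reference"),
    role = c("sample", "reference"),
    roi_center_row = c(15, 15),
    roi_center_col = c(7, 23),
    roi_side_pixels = as.integer(side)
  ))
}

# A small campaign design that keeps image generation in tests fast.
mini_design <- function(...) {
  campaign_design(
    n_locations = 3L, samplers_per_location = 2L,
    sampling_times = c(0, 33, 55, 90), n_frames = 5L,
    frame_dim = c(96, 96), roi_side = 15L,
    include_replacement = FALSE, ...
  )
}

# Straight-line delta series: delta_pi = rate * t.
line_series <- function(id, rate, times = c(0, 33, 55, 90), loc = "L1", ...) {
  delta_series(id, loc, times, rate * times, ...)
}
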