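# Shared fixtures: coarse phantoms keep routine tests fast; the
# full-resolution study conditions are exercised in test-acceptance.R.

coarse_spec <- function(spacing = 0.8, ...) {
  args <- list(...)
  defaults <- list(spacing = spacing, cortical_thickness = 2.5 * spacing,
                   blur_sigma = 0.5, noise_sd = 15)
  defaults[names(args)] <- args
  do.call(phantom_spec, defaults)
}

# memoised small voxelized dataset reused across test files
.fixture_env <- new.env(parent = emptyenv())

small_dataset <- function() {
  if (is.null(.fixture_env$small_ds))
    .fixture_env$small_ds <- generate_dataset(coarse_spec(), deviation_model(),
                                              n_patients = 2, n_levels = 1,
                                              seed = 101)
  .fixture_env$small_ds
}

# exact lattice of points on a cylinder's lateral surface
cylinder_lattice <- function(entry, direction, length, radius,
                             n_axial = 40, n_circ = 36, jitter_sd = 0) {
  d <- direction / sqrt(sum(direction^2))
  fr <- spineacc:::make_frame(d)
  tt <- rep(seq(0, length, length.out = n_axial), times = n_circ)
  ph <- rep(seq(0, 2 * pi, length.out = n_circ + 1)[-(n_circ + 1)], each = n_axial)
  P <- outer(tt, d) + radius * (outer(cos(ph), fr$u) + outer(sin(ph), fr$v))
  P <- sweep(P, 2, entry, "+")
  if (jitter_sd > 0) P <- P + matrix(rnorm(length(P), 0, jitter_sd), nrow(P), 3)
  P
}

# smallest angle between two undirected axes
axis_angle <- function(u, v) {
  a <- angle_between(u, v)
  min(a, 180 - a)
}
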