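# Shared fixtures, built lazily and cached for the session. Grids are
# desk-scale (the mm-scale physics -- radii, motion amplitudes, activities --
# is unchanged; only the field of view shrinks) to keep the suite fast.

.fix <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fix[[name]])) .fix[[name]] <- force(expr)
  .fix[[name]]
}

small_spec <- function(...) phantom_spec(shape = c(48L, 48L, 24L), ...)
mid_spec <- function(...) phantom_spec(shape = c(64L, 64L, 32L), ...)

ref_frame_small <- function() cached("ref_small", render_phantom_frame(small_spec(), 0, 0))

# anti-aliased disk (4x4 subpixel sampling): the projector's continuous-object
# oracle needs a fixture without hard pixel edges
aa_disk <- function(n, spacing, radius, centre = (n - 1) / 2 * spacing) {
  sub <- (0:3 + 0.5) / 4 - 0.5
  disk <- matrix(0, n, n)
  for (dx in sub) for (dy in sub) {
    x <- (seq_len(n) - 1 + dx) * spacing
    y <- (seq_len(n) - 1 + dy) * spacing
    disk <- disk + outer(x, y, function(a, b) {
      as.numeric((a - centre)^2 + (b - centre)^2 <= radius^2)
    })
  }
  disk / 16
}

# default seeded study at desk scale, shared by registration/acceptance tests
default_study <- function() {
  cached("study", {
    sp <- mid_spec()
    tr <- generate_respiratory_trace(600, seed = 301)
    tg <- generate_cardiac_triggers(max(tr$time_s), seed = 302)
    simulate_gated_study(sp, tr, tg, seed = 303)
  })
}

# the full default pipeline at desk scale (expensive; run once per session)
default_pipeline_result <- function() {
  cached("pipeline", {
    cfg <- default_pipeline_config(seed = 7, shape = c(64L, 64L, 32L))
    suppressMessages(suppressWarnings(run_pipeline(cfg)))
  })
}

expect_volume_equal <- function(a, b, tol = 1e-12) {
  expect_equal(unclass(a), unclass(b), tolerance = tol, ignore_attr = TRUE)
}
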