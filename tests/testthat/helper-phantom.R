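# Shared phantom fixtures, memoised so expensive renders happen once per
# test run.

.phantom_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .phantom_cache)) {
    assign(key, force(expr), envir = .phantom_cache)
  }
  get(key, envir = .phantom_cache)
}

# Small-field configuration for fast unit tests: a 41-scan structural block
# over a 2 mm field and a 110-scan angiographic block.
mini_config <- function(...) {
  phantom_config(
    structural_protocol = scan_protocol(
      n_scans = 41, scan_spacing = 11, lateral_pitch = 6, axial_pitch = 3.9,
      field_width = 2000, n_averaged_frames = 100),
    angio_protocol = scan_protocol(
      n_scans = 110, scan_spacing = 5.9, lateral_pitch = 6, axial_pitch = 3.9,
      field_width = 3000, n_averaged_frames = 7),
    n_capillaries = 3, n_granules_inl = 2, n_granules_onl = 1,
    n_superficial_vessels = 1, fraction_nonperfused = 0,
    lateral_range = c(540, 900), scanaxis_range = c(-130, 130),
    onl_lateral_range = c(-600, 600),
    ...
  )
}

mini_phantom <- function() {
  memo("mini", simulate_phantom(mini_config(seed = 3)))
}

# Full study-scale phantom (default configuration, seed 0) plus the whole
# pipeline run on it; reused by several test files.
default_phantom <- function() {
  memo("default0", simulate_phantom(phantom_config(seed = 0)))
}

default_pipeline <- function() {
  memo("default0_pipeline", {
    ph <- default_phantom()
    run_pipeline(ph$structural, ph$angio, ph$layers)
  })
}

# Tiny synthetic detection table for tracing tests: one dot per scan at
# fixed position over consecutive scans.
fake_detections <- function(scans, lateral = 800, depth = 180,
                            diameter = 15, location = "inside_INL",
                            layer = "INL", spacing = 11) {
  d <- data.frame(
    scan_index = as.integer(scans),
    scan_um = scans * spacing,
    lateral = rep_len(lateral, length(scans)),
    depth = rep_len(depth, length(scans)),
    axial_diameter = rep_len(diameter, length(scans)),
    peak_contrast = 2.5,
    layer = layer,
    location = rep_len(location, length(scans)),
    distance_to_nearest_boundary = 10,
    diameter_capped = FALSE
  )
  attr(d, "stack_uid") <- "fake"
  attr(d, "scan_spacing") <- spacing
  d
}

fake_protocol <- function(spacing = 11) {
  scan_protocol(n_scans = 131, scan_spacing = spacing, lateral_pitch = 6,
                axial_pitch = 3.9, field_width = 4500, n_averaged_frames = 100)
}
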