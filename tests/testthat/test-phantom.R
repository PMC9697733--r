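test_that("layer geometry is ordered, deterministic, and pitted at the fovea", {
  cfg <- phantom_config(seed = 5)
  lay <- make_layer_geometry(cfg)
  lay2 <- make_layer_geometry(cfg)
  expect_identical(lay, lay2)
  # strict depth ordering of boundaries over the field
  xs <- seq(-2200, 2200, by = 110)
  for (y in c(-600, 0, 450)) {
    B <- vapply(c("ipl_inner", "ipl_inl", "inl_opl", "opl_onl", "onl_outer"),
                function(b) boundary_depth(lay, b, xs, y), numeric(length(xs)))
    expect_true(all(apply(B, 1, diff) > 0))
  }
  # INL thins toward the foveal pit
  inl_at <- function(x) boundary_depth(lay, "inl_opl", x, 0) -
    boundary_depth(lay, "ipl_inl", x, 0)
  expect_lt(inl_at(0), inl_at(1000))
  # layer model JSON round trip
  path <- file.path(tempdir(), "layers.json")
  write_layers(lay, path)
  expect_equal(boundary_depth(read_layers(path), "inl_opl", 700, -100),
               boundary_depth(lay, "inl_opl", 700, -100))
})

test_that("object planting respects layer rules and class separability", {
  cfg <- phantom_config(seed = 2)
  lay <- make_layer_geometry(cfg)
  tr <- plant_objects(lay, cfg)
  expect_false(anyDuplicated(tr$id) > 0)
  caps <- tr[tr$kind == "capillary", ]
  gran <- tr[tr$kind == "granule", ]
  # planted kinds recoverable from their own geometry via the class rules
  expect_true(all(caps$length >= 33))
  expect_true(all(gran$length < 44))
  expect_true(all(caps$length >= 51 & caps$length <= 183))
  # no vessels in the outer nuclear layer; ONL capillaries are rejected
  expect_true(all(caps$layer_attachment != "ONL"))
  expect_error(plant_objects(lay, phantom_config(n_onl_capillaries = 1)),
               "no vessels")
  # forcing full perfusion
  cfg0 <- phantom_config(seed = 2, fraction_nonperfused = 0)
  tr0 <- plant_objects(lay, cfg0)
  expect_true(all(tr0$perfused[tr0$kind == "capillary"]))
  # attachment geometry: near-boundary dots touch within half an axial pixel
  for (k in which(tr$kind != "superficial_vessel" & tr$layer_attachment == "near_IPL")) {
    b2 <- boundary_depth(lay, "ipl_inl", tr$x[k], tr$y[k])
    expect_lt(tr$z[k] - tr$diameter[k] / 2 - b2, 3.9 / 2)
  }
})

test_that("planting is deterministic and truth export round-trips", {
  cfg <- phantom_config(seed = 9)
  lay <- make_layer_geometry(cfg)
  expect_identical(plant_objects(lay, cfg), plant_objects(lay, cfg))
  tr <- plant_objects(lay, cfg)
  path <- file.path(tempdir(), "truth.csv")
  export_truth(tr, path)
  rt <- read_truth(path)
  expect_equal(rt$x, tr$x)
  expect_equal(rt$perfused, tr$perfused)
  expect_equal(rt$layer_attachment, tr$layer_attachment)
  # empty list gives a header-only file
  export_truth(tr[0, ], path)
  expect_equal(nrow(read_truth(path)), 0)
})

test_that("frame averaging sets the speckle variance of the rendered stacks", {
  cfg <- mini_config(seed = 6, n_capillaries = 0, n_granules_inl = 0,
                     n_granules_onl = 0, n_superficial_vessels = 0)
  lay <- make_layer_geometry(cfg)
  tr <- plant_objects(lay, cfg)
  clean <- render_structural(lay, tr, cfg$structural_protocol, cfg, noise = FALSE)
  p7 <- cfg$structural_protocol
  p7$n_averaged_frames <- 7
  n100 <- render_structural(lay, tr, cfg$structural_protocol, cfg, seed = 21)
  n7 <- render_structural(lay, tr, p7, cfg, seed = 22)
  # multiplicative ratio on >= 1e4 homogeneous background voxels
  sel <- clean$reflectivity > 0.1
  expect_gt(sum(sel), 1e4)
  v100 <- var(n100$reflectivity[sel] / clean$reflectivity[sel])
  v7 <- var(n7$reflectivity[sel] / clean$reflectivity[sel])
  expect_equal(v7 / v100, 100 / 7, tolerance = 0.2)
})

test_that("rendered geometry follows the planted objects", {
  cfg <- mini_config(seed = 1, n_capillaries = 0, n_granules_inl = 0,
                     n_granules_onl = 0, n_superficial_vessels = 0)
  lay <- make_layer_geometry(cfg)
  # a single capillary of length 88 um along the scan axis appears in >= 8
  # consecutive scans at its lateral position (88 / 11 = 8 transitions)
  obj <- data.frame(id = 1L, kind = "capillary", x = 700, y = 0,
                    z = boundary_depth(lay, "ipl_inl", 700, 0) + 12,
                    diameter = 16, length = 88, ux = 0, uy = 1, uz = 0,
                    perfused = TRUE, layer_attachment = "inside_INL",
                    branch_of = NA_integer_, length_axis = 72)
  st <- render_structural(lay, obj, cfg$structural_protocol, cfg, noise = FALSE)
  # hyperreflectivity (intensity clearly above the INL background) present
  # in >= 8 consecutive scans: 88 um / 11 um = 8 inter-scan intervals
  xs <- lateral_positions(st); zs <- depth_positions(st)
  cols <- which(abs(xs - 700) < 12); rows <- which(abs(zs - obj$z) < 12)
  lvl <- cfg$reflectivity["inl"] +
    0.25 * (cfg$object_reflectivity - cfg$reflectivity["inl"])
  present <- vapply(seq_len(st$protocol$n_scans), function(i) {
    max(st$reflectivity[i, rows, cols]) > lvl
  }, logical(1))
  runs <- rle(present)
  expect_gte(max(runs$lengths[runs$values]), 8)
  # an empty scene yields no INL detections on noiseless rendering
  st0 <- render_structural(lay, obj[0, ], cfg$structural_protocol, cfg, noise = FALSE)
  expect_equal(nrow(detect_dots(suppress_background(st0), lay,
                                classification_params(), roi = "inl")), 0)
})

test_that("phantom rendering is deterministic for a fixed seed", {
  cfg <- mini_config(seed = 4)
  ph1 <- simulate_phantom(cfg)
  ph2 <- simulate_phantom(cfg)
  expect_identical(ph1$structural$reflectivity, ph2$structural$reflectivity)
  expect_identical(ph1$angio$motion_contrast, ph2$angio$motion_contrast)
})

test_that("motion-contrast geometry marks perfusion and projection, independent of speckle seed", {
  cfg <- mini_config(seed = 8, n_capillaries = 2, fraction_nonperfused = 0.5,
                     n_granules_inl = 1, n_granules_onl = 0,
                     n_superficial_vessels = 1)
  lay <- make_layer_geometry(cfg)
  tr <- plant_objects(lay, cfg)
  ang <- render_angiographic(lay, tr, cfg$angio_protocol, c(0, 0, 0), cfg, seed = 1)
  xa <- lateral_positions(ang); za <- depth_positions(ang); ya <- scan_positions(ang)
  motion_at <- function(o, pad = 2) {
    js <- which(abs(ya - o$y) < (o$length_axis * abs(o$uy) + o$diameter) / 2 - pad)
    vals <- c()
    for (j in js) {
      cols <- which(abs(xa - o$x) <= o$diameter / 2)
      rows <- which(abs(za - o$z) <= o$diameter / 2)
      vals <- c(vals, max(ang$motion_contrast[j, rows, cols]))
    }
    vals
  }
  caps <- tr[tr$kind == "capillary", ]
  perf <- caps[caps$perfused, ][1, ]
  nonp <- caps[!caps$perfused, ][1, ]
  expect_true(all(motion_at(perf) >= cfg$motion_flow))
  expect_true(all(motion_at(nonp) < 0.2))
  # granule footprint carries no flow signal
  g <- tr[tr$kind == "granule" & tr$layer_attachment != "ONL", ][1, ]
  gi <- which.min(abs(ya - g$y))
  cols <- which(abs(xa - g$x) <= g$diameter / 2)
  rows <- which(abs(za - g$z) <= g$diameter / 2)
  expect_lt(max(ang$motion_contrast[gi, rows, cols]), 0.2)
  # projection artifact: motion signal in the INL band under a superficial
  # vessel with no structural object there
  v <- tr[tr$kind == "superficial_vessel", ][1, ]
  vj <- which.min(abs(ya - v$y))
  vc <- which.min(abs(xa - v$x))
  b2 <- boundary_depth(lay, "ipl_inl", v$x, ya[vj])
  b3 <- boundary_depth(lay, "inl_opl", v$x, ya[vj])
  inl_rows <- which(za > b2 & za < b3)
  expect_gt(max(ang$motion_contrast[vj, inl_rows, vc]), 0.2)
  # structural-channel speckle seed does not alter flow geometry
  ang2 <- render_angiographic(lay, tr, cfg$angio_protocol, c(0, 0, 0), cfg, seed = 99)
  expect_identical(ang$motion_contrast >= cfg$motion_flow,
                   ang2$motion_contrast >= cfg$motion_flow)
})
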