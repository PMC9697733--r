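test_that("speckle suppression preserves structure and removes noise maxima", {
  cfg <- mini_config(seed = 12, n_capillaries = 2, n_granules_inl = 1,
                     n_granules_onl = 0, n_superficial_vessels = 0)
  lay <- make_layer_geometry(cfg)
  tr <- plant_objects(lay, cfg)
  clean <- render_structural(lay, tr, cfg$structural_protocol, cfg, noise = FALSE)
  f <- suppress_background(clean)
  # no-noise limit: peak-to-background ratio of every planted dot within 10%
  params <- classification_params()
  xs <- lateral_positions(clean); zs <- depth_positions(clean)
  ys <- scan_positions(clean)
  for (k in which(tr$kind != "superficial_vessel" & tr$layer_attachment != "ONL")) {
    o <- tr[k, ]
    i <- which.min(abs(ys - o$y))
    cols <- which(abs(xs - o$x) < 10); rows <- which(abs(zs - o$z) < 10)
    bgc <- which(abs(xs - o$x) > 40 & abs(xs - o$x) < 80)
    ratio_raw <- max(clean$reflectivity[i, rows, cols]) /
      median(clean$reflectivity[i, rows, bgc])
    ratio_f <- max(f$reflectivity[i, rows, cols]) /
      median(f$reflectivity[i, rows, bgc])
    expect_equal(ratio_f, ratio_raw, tolerance = 0.1)
  }
  # pure-noise stack: count of band maxima above threshold drops
  noisy <- render_structural(lay, tr[0, ], cfg$structural_protocol, cfg, seed = 5)
  count_maxima <- function(stack) {
    img <- stack$reflectivity[21, , ]
    b2 <- boundary_depth(lay, "ipl_inl", xs, ys[21])
    b3 <- boundary_depth(lay, "inl_opl", xs, ys[21])
    n <- 0
    for (c2 in seq(5, ncol(img) - 4)) {
      rr <- max(1, ceiling(b2[c2] / 3.9)):min(nrow(img), floor(b3[c2] / 3.9))
      v <- img[rr, c2]
      bg <- median(v)
      n <- n + sum(v > 1.5 * bg)
    }
    n
  }
  expect_lt(count_maxima(suppress_background(noisy)), count_maxima(noisy))
  # approximate idempotence
  f2 <- suppress_background(f)
  expect_lt(mean(abs(f2$reflectivity - f$reflectivity)),
            0.25 * mean(abs(f$reflectivity - noisy$reflectivity)) +
              mean(abs(f$reflectivity)) * 0.02)
})

test_that("noiseless detection finds exactly the planted cross-sections in the ROI", {
  cfg <- mini_config(seed = 13, n_superficial_vessels = 0, n_granules_onl = 0)
  lay <- make_layer_geometry(cfg)
  tr <- plant_objects(lay, cfg)
  st <- render_structural(lay, tr, cfg$structural_protocol, cfg, noise = FALSE)
  det <- detect_dots(suppress_background(st), lay, classification_params(), "inl")
  # every detection lies on a planted object (dilated capsule)
  on_object <- vapply(seq_len(nrow(det)), function(k) {
    any(vapply(seq_len(nrow(tr)), function(j) {
      o <- tr[j, ]
      ef <- hrdot:::enface_segment_dist(det$lateral[k], det$scan_um[k], o)
      sqrt(ef^2 + (det$depth[k] - o$z)^2) <= o$diameter / 2 + 15
    }, logical(1)))
  }, logical(1))
  expect_true(all(on_object))
  # every interior cross-section of a planted object is detected
  ys <- scan_positions(st)
  for (j in seq_len(nrow(tr))) {
    o <- tr[j, ]
    core <- (o$length_axis * abs(o$uy) + o$diameter) / 2 - 4
    for (i in which(abs(ys - o$y) <= core)) {
      hit <- det$scan_index == (i - 1) &
        abs(det$lateral - o$x) < 25 + o$length_axis * abs(o$ux) / 2 &
        abs(det$depth - o$z) < 20
      expect_true(any(hit),
                  label = sprintf("object %d detected on scan %d", o$id, i - 1))
    }
  }
})

test_that("the parafoveal ROI excludes dots outside 500-1500 um temporal", {
  cfg <- mini_config(seed = 14, n_capillaries = 0, n_granules_inl = 0,
                     n_granules_onl = 0, n_superficial_vessels = 0)
  lay <- make_layer_geometry(cfg)
  mk <- function(x) data.frame(id = 1L, kind = "granule", x = x, y = 0,
                               z = boundary_depth(lay, "ipl_inl", x, 0) + 14,
                               diameter = 18, length = 18, ux = 0, uy = 1, uz = 0,
                               perfused = NA, layer_attachment = "inside_INL",
                               branch_of = NA_integer_, length_axis = 0)
  st_in <- render_structural(lay, mk(800), cfg$structural_protocol, cfg, noise = FALSE)
  st_out <- render_structural(lay, mk(400), cfg$structural_protocol, cfg, noise = FALSE)
  expect_gt(nrow(detect_dots(suppress_background(st_in), lay,
                             classification_params(), "inl")), 0)
  expect_equal(nrow(detect_dots(suppress_background(st_out), lay,
                                classification_params(), "inl")), 0)
  expect_error(detect_dots(suppress_background(st_in), NULL), "layer")
})

test_that("axial diameter is measured as FWHM and respects the planted sizes", {
  cfg <- mini_config(seed = 15, n_capillaries = 0, n_granules_inl = 0,
                     n_granules_onl = 0, n_superficial_vessels = 0)
  lay <- make_layer_geometry(cfg)
  p <- cfg$structural_protocol
  # 20 um sphere, mid-INL: recovered within one axial pixel
  b2 <- boundary_depth(lay, "ipl_inl", 750, 0)
  b3 <- boundary_depth(lay, "inl_opl", 750, 0)
  obj <- data.frame(id = 1L, kind = "granule", x = 750, y = 0,
                    z = (b2 + b3) / 2, diameter = 20, length = 20,
                    ux = 0, uy = 1, uz = 0, perfused = NA,
                    layer_attachment = "inside_INL", branch_of = NA_integer_,
                    length_axis = 0)
  st <- render_structural(lay, obj, p, cfg, noise = FALSE)
  det <- detect_dots(suppress_background(st), lay, classification_params(), "inl")
  mid <- det[which.min(abs(det$scan_um - 0)), ]
  expect_equal(mid$axial_diameter, 20, tolerance = (p$axial_pitch + 1) / 20)
  # symmetric profile: depth at profile center
  expect_equal(mid$depth, (b2 + b3) / 2, tolerance = 2.5)
  # planted [10, 25] um diameters come back in range, allowing blur broadening
  ph <- mini_phantom()
  det2 <- detect_dots(suppress_background(ph$structural),
                      ph$layers, classification_params(), "inl")
  interior <- det2[det2$location == "inside_INL" & !det2$diameter_capped, ]
  if (nrow(interior)) {
    expect_true(all(interior$axial_diameter >= 10 - 4 &
                      interior$axial_diameter <= 25 + 6))
  }
})

test_that("location labels follow the attachment rule", {
  lay <- make_layer_geometry(phantom_config(seed = 1))
  b2 <- boundary_depth(lay, "ipl_inl", 800, 0)
  b3 <- boundary_depth(lay, "inl_opl", 800, 0)
  mkdet <- function(depth, d) data.frame(scan_index = 0L, scan_um = 0,
                                         lateral = 800, depth = depth,
                                         axial_diameter = d, peak_contrast = 2,
                                         layer = "INL", location = NA,
                                         distance_to_nearest_boundary = NA,
                                         diameter_capped = FALSE)
  # centered, small: free of both boundaries
  expect_equal(assign_location(mkdet((b2 + b3) / 2, 10), lay), "inside_INL")
  # lower edge on the INL/OPL boundary
  expect_equal(assign_location(mkdet(b3 - 6, 12), lay), "near_OPL")
  # upper edge on the IPL/INL boundary
  expect_equal(assign_location(mkdet(b2 + 5, 10), lay), "near_IPL")
  # touching both: assigned to the nearer boundary
  big <- mkdet((b2 + b3) / 2 + 1, b3 - b2 + 2)
  expect_equal(assign_location(big, lay), "near_OPL")
})

test_that("planted attachment labels are recovered at default SNR", {
  res <- default_pipeline()
  ph <- default_phantom()
  ev <- evaluate_recovery(res$classified, ph$truth, ph$structural$protocol)
  expect_gte(mean(ev$location_ok), 0.9)
})

test_that("the ONL filter applies the diameter and clearance rules", {
  mk <- function(d, dist) {
    x <- data.frame(scan_index = 0L, scan_um = 0, lateral = 0, depth = 250,
                    axial_diameter = d, peak_contrast = 2, layer = "ONL",
                    location = "not_applicable",
                    distance_to_nearest_boundary = dist,
                    diameter_capped = FALSE)
    x
  }
  dets <- rbind(mk(14, 40), mk(18, 15), mk(18, 25), mk(16, 30), mk(25, 20))
  out <- filter_onl(dets, classification_params())
  # 14 um: too small; 18/15: clearance not greater than width; rest kept
  expect_equal(out$axial_diameter, c(18, 16))
  expect_equal(out$distance_to_nearest_boundary, c(25, 30))
  # subset, order-preserving, idempotent
  expect_identical(filter_onl(out, classification_params()), out)
})

test_that("detection count is monotone in the contrast threshold", {
  ph <- mini_phantom()
  sf <- suppress_background(ph$structural)
  n <- vapply(c(1.3, 1.5, 1.8, 2.2), function(th) {
    nrow(detect_dots(sf, ph$layers, classification_params(contrast_threshold = th), "inl"))
  }, numeric(1))
  expect_true(all(diff(n) <= 0))
})
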