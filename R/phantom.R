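#' Phantom configuration
#'
#' Parameters of the synthetic OCT phantom: paired structural and
#' angiographic acquisition protocols, counts and size distributions of the
#' planted hyperreflective objects, the non-perfused capillary fraction,
#' the rigid misregistration between the two stacks, per-layer background
#' reflectivities, and the speckle model.
#'
#' The defaults emulate the graded study conditions: a 131-scan structural
#' block at 11 um spacing with 100-frame averaging, an angiographic block
#' at 5.9 um spacing with 7-frame averaging over a concentric 3 x 3 mm
#' field, 12 capillary segments (2 of them non-perfused) and 4 granules in
#' the parafoveal INL, 2 granules in the ONL, capillary diameters 10-25 um
#' and lengths 51-183 um oriented predominantly along the scan axis
#' (within a 20 degree in-plane cone), and a small misregistration of
#' (15 um lateral, 8 um scan-axis, 0.5 degrees) between the stacks.
#'
#' Speckle is multiplicative gamma noise with mean 1 and shape
#' `speckle_shape_per_frame * n_averaged_frames`, so frame averaging shrinks
#' the speckle variance linearly. Motion-contrast values are ~1 inside
#' perfused vessels; projection artifacts cast by superficial vessels carry
#' a weaker signal (`motion_projection`) than in-situ flow.
#'
#' @param ... named overrides of any default listed below.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(...) {
  cfg <- list(
    structural_protocol = structural_protocol(),
    angio_protocol = angio_protocol(n_scans = 256),
    depth_extent = 400,
    n_capillaries = 12,
    fraction_nonperfused = 1 / 6,
    n_granules_inl = 4,
    n_granules_onl = 2,
    n_superficial_vessels = 2,
    n_onl_capillaries = 0,
    capillary_diameter_range = c(10, 25),
    capillary_length_range = c(51, 183),
    granule_diameter_range = c(10, 25),
    onl_granule_diameter_range = c(16, 22),
    attachment_probs = c(near_IPL = 0.3, inside_INL = 0.15, near_OPL = 0.55),
    capillary_cone_deg = 20,
    branch_fraction = 0,
    branch_angle_deg = 45,
    lateral_range = c(550, 1350),
    scanaxis_range = c(-450, 450),
    onl_lateral_range = c(-1200, 1200),
    min_separation = 35,
    boundary_embed = 1,
    interior_clearance = 7,
    misregistration = c(lateral = 15, scanaxis = 8, rotation = 0.5),
    speckle_shape_per_frame = 1,
    noise = TRUE,
    reflectivity = c(vitreous = 0.02, inner_retina = 0.35, ipl = 0.50,
                     inl = 0.22, opl = 0.50, onl = 0.15, outer = 0.65),
    object_reflectivity = 0.9,
    vessel_reflectivity = 0.65,
    superficial_diameter_range = c(30, 45),
    motion_flow = 1.0,
    motion_projection = 0.35,
    motion_noise_density = 3e-4,
    edge_sigma = 3,
    seed = 0
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown phantom_config field(s): ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  if (cfg$fraction_nonperfused < 0 || cfg$fraction_nonperfused > 1) {
    stop("fraction_nonperfused must be in [0, 1]")
  }
  structure(cfg, class = "phantom_config")
}

#' Generate the layer geometry of a phantom
#'
#' Builds a [layer_model()] with a central foveal pit (the INL thins toward
#' the fovea) and a seeded smooth undulation. Deterministic for a fixed
#' seed.
#'
#' @param config a [phantom_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return a [layer_model()].
#' @export
make_layer_geometry <- function(config = phantom_config(), seed = config$seed) {
  set.seed(subseed(seed, 1))
  layer_model(phases = matrix(stats::runif(14), 2, 7))
}

in_plane_dir <- function(angle_from_scan_axis) {
  c(ux = sin(angle_from_scan_axis), uy = cos(angle_from_scan_axis), uz = 0)
}

# En-face distance from points (px, py) to the segment of an object row.
enface_segment_dist <- function(px, py, obj) {
  hl <- obj$length_axis / 2
  p0x <- obj$x - obj$ux * hl; p0y <- obj$y - obj$uy * hl
  t <- clamp((px - p0x) * obj$ux + (py - p0y) * obj$uy, 0, obj$length_axis)
  sqrt((px - (p0x + t * obj$ux))^2 + (py - (p0y + t * obj$uy))^2)
}

# Axis length of the cylindrical part (0 for spheres). Total planted
# "length" of a capillary includes the hemispherical caps.
axis_length <- function(kind, length, diameter) {
  if (kind == "capillary" || kind == "superficial_vessel") {
    max(length - diameter, 0)
  } else 0
}

new_truth_row <- function(id, kind, x, y, z, diameter, length, dir,
                          perfused, attachment, branch_of = NA_integer_) {
  data.frame(id = id, kind = kind, x = x, y = y, z = z,
             diameter = diameter, length = length,
             ux = dir[1], uy = dir[2], uz = dir[3],
             perfused = perfused, layer_attachment = attachment,
             branch_of = branch_of,
             length_axis = axis_length(kind, length, diameter))
}

#' Plant ground-truth objects into the phantom scene
#'
#' Samples granules and capillary segments in the inner nuclear layer,
#' granules in the outer nuclear layer, and superficial vessels anterior to
#' the IPL. Capillaries are placed touching the IPL/INL or INL/OPL boundary
#' or fully interior according to `attachment_probs`; a configured fraction
#' is flagged non-perfused. The outer nuclear layer contains no vessels, so
#' requesting ONL capillaries is an error. Placement enforces a minimum
#' en-face separation between objects; infeasible configurations raise a
#' placement error.
#'
#' @param layers a [layer_model()].
#' @param config a [phantom_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return a data.frame of ground-truth objects, one row per object, with
#'   columns `id`, `kind`, `x`, `y`, `z` (center, um), `diameter`, `length`
#'   (um), `ux`, `uy`, `uz` (unit axis direction), `perfused`,
#'   `layer_attachment`, `branch_of`.
#' @export
plant_objects <- function(layers, config = phantom_config(), seed = config$seed) {
  if (config$n_onl_capillaries > 0) {
    stop("placement error: the outer nuclear layer contains no vessels; ONL capillaries cannot be planted")
  }
  set.seed(subseed(seed, 2))
  rows <- list()
  accepted_sep <- function(x, y) {
    if (!length(rows)) return(TRUE)
    for (r in rows) {
      if (r$kind == "superficial_vessel") next
      if (enface_segment_dist(x, y, r) < config$min_separation) return(FALSE)
    }
    TRUE
  }
  id <- 0L
  emb <- config$boundary_embed
  clr <- config$interior_clearance

  place_inl <- function(kind, diameter, length, dir, attachment, perfused) {
    for (try in 1:400) {
      x <- stats::runif(1, config$lateral_range[1], config$lateral_range[2])
      y <- stats::runif(1, config$scanaxis_range[1], config$scanaxis_range[2])
      if (!accepted_sep(x, y)) next
      r <- diameter / 2
      b2 <- boundary_depth(layers, "ipl_inl", x, y)
      b3 <- boundary_depth(layers, "inl_opl", x, y)
      # near-boundary dots sit just inside the boundary with ~1 um of
      # clearance: they read as attached within half an axial pixel, and
      # their blurred maximum stays separable from the brighter plexiform
      # layers instead of merging into the boundary ramp
      z <- switch(attachment,
        near_IPL = b2 + r + emb,
        near_OPL = b3 - r - emb,
        inside_INL = {
          lo <- b2 + r + clr; hi <- b3 - r - clr
          if (hi <= lo) next
          stats::runif(1, lo, hi)
        })
      return(c(x = x, y = y, z = z))
    }
    stop("placement error: could not place ", kind, " (", attachment,
         ") within the available inner nuclear layer volume")
  }

  # capillaries
  n_cap <- config$n_capillaries
  n_nonperf <- round(config$fraction_nonperfused * n_cap)
  nonperf_idx <- if (n_nonperf > 0) sample(seq_len(n_cap), n_nonperf) else integer(0)
  cone <- config$capillary_cone_deg * pi / 180
  for (i in seq_len(n_cap)) {
    d <- stats::runif(1, config$capillary_diameter_range[1], config$capillary_diameter_range[2])
    L <- stats::runif(1, config$capillary_length_range[1], config$capillary_length_range[2])
    if (L < 33) stop("capillary length below the elongated class boundary (33 um)")
    ang <- stats::runif(1, -cone, cone)
    dir <- in_plane_dir(ang)
    att <- sample(names(config$attachment_probs), 1, prob = config$attachment_probs)
    pos <- place_inl("capillary", d, L, dir, att, TRUE)
    id <- id + 1L
    rows[[length(rows) + 1]] <- new_truth_row(
      id, "capillary", pos["x"], pos["y"], pos["z"], d, L, dir,
      perfused = !(i %in% nonperf_idx), attachment = att)
  }

  # optional branch children sharing a point on the parent axis
  if (config$branch_fraction > 0) {
    cap_rows <- which(vapply(rows, function(r) r$kind == "capillary", logical(1)))
    for (j in cap_rows) {
      if (stats::runif(1) >= config$branch_fraction) next
      p <- rows[[j]]
      # branch point at 60% of the parent axis, measured from its start
      bp <- c(p$x, p$y) + c(p$ux, p$uy) * (0.1 * p$length_axis)
      phi <- atan2(p$ux, p$uy) + sample(c(-1, 1), 1) * config$branch_angle_deg * pi / 180
      dirc <- in_plane_dir(phi)
      Lc <- max(40, 0.45 * p$length)
      axc <- axis_length("capillary", Lc, p$diameter)
      center <- bp + c(dirc[1], dirc[2]) * axc / 2
      id <- id + 1L
      rows[[length(rows) + 1]] <- new_truth_row(
        id, "capillary", center[1], center[2], p$z, p$diameter, Lc, dirc,
        perfused = p$perfused, attachment = p$layer_attachment,
        branch_of = p$id)
    }
  }

  # INL granules
  for (i in seq_len(config$n_granules_inl)) {
    d <- stats::runif(1, config$granule_diameter_range[1], config$granule_diameter_range[2])
    if (d >= 44) stop("granule size above the granule class boundary (44 um)")
    att <- sample(names(config$attachment_probs), 1, prob = config$attachment_probs)
    pos <- place_inl("granule", d, d, c(0, 1, 0), att, NA)
    id <- id + 1L
    rows[[length(rows) + 1]] <- new_truth_row(
      id, "granule", pos["x"], pos["y"], pos["z"], d, d, c(0, 1, 0),
      perfused = NA, attachment = att)
  }

  # ONL granules, kept clear of the bounding layers by more than their width
  for (i in seq_len(config$n_granules_onl)) {
    d <- stats::runif(1, config$onl_granule_diameter_range[1], config$onl_granule_diameter_range[2])
    placed <- FALSE
    for (try in 1:400) {
      x <- stats::runif(1, config$onl_lateral_range[1], config$onl_lateral_range[2])
      y <- stats::runif(1, config$scanaxis_range[1], config$scanaxis_range[2])
      if (!accepted_sep(x, y)) next
      b4 <- boundary_depth(layers, "opl_onl", x, y)
      b5 <- boundary_depth(layers, "onl_outer", x, y)
      lo <- b4 + d / 2 + d + 6; hi <- b5 - d / 2 - d - 6
      if (hi <= lo) next
      z <- stats::runif(1, lo, hi)
      id <- id + 1L
      rows[[length(rows) + 1]] <- new_truth_row(
        id, "granule", x, y, z, d, d, c(0, 1, 0),
        perfused = NA, attachment = "ONL")
      placed <- TRUE
      break
    }
    if (!placed) stop("placement error: could not place ONL granule clear of the bounding layers")
  }

  # superficial vessels (anterior to the IPL), random en-face orientation
  for (i in seq_len(config$n_superficial_vessels)) {
    d <- stats::runif(1, config$superficial_diameter_range[1], config$superficial_diameter_range[2])
    x <- stats::runif(1, 400, 1400)
    y <- stats::runif(1, -300, 300)
    phi <- stats::runif(1, 0, pi)
    dirv <- in_plane_dir(phi)
    z <- boundary_depth(layers, "ipl_inner", x, y) - 30
    id <- id + 1L
    rows[[length(rows) + 1]] <- new_truth_row(
      id, "superficial_vessel", x, y, z, d, 1500, dirv,
      perfused = TRUE, attachment = "near_IPL")
  }

  if (!length(rows)) {
    truth <- new_truth_row(1L, "granule", 0, 0, 0, 1, 1, c(0, 1, 0), NA, "ONL")[0, ]
    return(truth)
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  # class separability by construction
  gr <- truth$kind == "granule"
  stopifnot(all(truth$length[gr] < 44), all(truth$length[!gr & truth$kind == "capillary"] >= 33))
  truth
}

# Rigid en-face misregistration: maps angiographic-frame coordinates into
# the scene (structural) frame. `misreg = c(lateral, scanaxis, rotation_deg)`.
misreg_apply <- function(xp, yp, misreg) {
  th <- misreg[3] * pi / 180
  list(x = cos(th) * xp - sin(th) * yp + misreg[1],
       y = sin(th) * xp + cos(th) * yp + misreg[2])
}

misreg_invert <- function(x, y, misreg) {
  th <- misreg[3] * pi / 180
  dx <- x - misreg[1]; dy <- y - misreg[2]
  list(x = cos(th) * dx + sin(th) * dy,
       y = -sin(th) * dx + cos(th) * dy)
}

REFL_LAYER_ORDER <- c("vitreous", "inner_retina", "ipl", "inl", "opl", "onl", "outer")

# Render one B-scan: scene en-face coordinates per lateral column (xs, ys),
# depth grid zs. Returns the reflectivity matrix [depth, lateral] and,
# when asked, the motion-contrast matrix.
render_scan <- function(layers, objects, xs, ys, zs, config, motion = FALSE) {
  C <- length(xs); D <- length(zs)
  B <- boundary_matrix(layers, xs, ys)   # C x 6
  L <- matrix(1L, D, C)
  for (k in seq_len(ncol(B))) L <- L + outer(zs, B[, k], ">=")
  img <- matrix(config$reflectivity[REFL_LAYER_ORDER][L], D, C)
  mot <- if (motion) matrix(0, D, C) else NULL
  se <- config$edge_sigma
  for (j in seq_len(nrow(objects))) {
    obj <- objects[j, ]
    r <- obj$diameter / 2
    e <- enface_segment_dist(xs, ys, obj)
    cols <- which(e <= r + 4 * se)
    if (!length(cols)) next
    zrows <- which(abs(zs - obj$z) <= r + 4 * se)
    if (!length(zrows)) next
    d3 <- sqrt(outer((zs[zrows] - obj$z)^2, e[cols]^2, "+"))
    occ <- stats::pnorm((r - d3) / se)
    A <- if (obj$kind == "superficial_vessel") config$vessel_reflectivity else config$object_reflectivity
    img[zrows, cols] <- img[zrows, cols] * (1 - occ) + A * occ
    if (motion) {
      if (isTRUE(obj$perfused) && obj$kind %in% c("capillary", "superficial_vessel")) {
        mot[zrows, cols][d3 <= r] <- pmax(mot[zrows, cols][d3 <= r], config$motion_flow)
      }
      if (obj$kind == "superficial_vessel") {
        pcols <- which(e <= r)
        if (length(pcols)) {
          tail_top <- obj$z + r + 2
          tail_bot <- B[pcols, 5] + 10   # through to just past OPL/ONL
          pr <- outer(zs, rep(1, length(pcols))) > tail_top &
            sweep(matrix(zs, D, length(pcols)), 2, tail_bot, "<=")
          mot[, pcols][pr] <- pmax(mot[, pcols][pr], config$motion_projection)
        }
      }
    }
  }
  list(img = img, mot = mot)
}

render_stack_impl <- function(layers, objects, protocol, config, seed,
                              origin, motion, misreg = c(0, 0, 0),
                              noise = config$noise) {
  D <- ceiling(config$depth_extent / protocol$axial_pitch)
  C <- round(protocol$field_width / protocol$lateral_pitch)
  S <- protocol$n_scans
  zs <- (seq_len(D) - 1) * protocol$axial_pitch
  xp <- origin[1] + (seq_len(C) - 1) * protocol$lateral_pitch
  yp <- origin[2] + (seq_len(S) - 1) * protocol$scan_spacing
  sig_ax <- (protocol$axial_resolution / 2.355) / protocol$axial_pitch
  sig_lat <- (protocol$lateral_resolution / 2.355) / protocol$lateral_pitch
  refl <- array(0, c(S, D, C))
  mot <- if (motion) array(0, c(S, D, C)) else NULL
  set.seed(subseed(seed, 10))
  shape <- config$speckle_shape_per_frame * protocol$n_averaged_frames
  for (i in seq_len(S)) {
    sc <- misreg_apply(xp, rep(yp[i], C), misreg)
    rs <- render_scan(layers, objects, sc$x, sc$y, zs, config, motion = motion)
    img <- blur_scan(rs$img, sig_ax, sig_lat)
    if (noise) img <- img * matrix(stats::rgamma(D * C, shape = shape, rate = shape), D, C)
    refl[i, , ] <- img
    if (motion) mot[i, , ] <- rs$mot
  }
  if (motion && noise && config$motion_noise_density > 0) {
    # sparse decorrelation speckles, seeded independently of the
    # structural-channel noise so they never alter flow geometry
    set.seed(subseed(seed, 11))
    n <- length(mot)
    idx <- which(stats::runif(n) < config$motion_noise_density)
    mot[idx] <- pmax(mot[idx], stats::runif(length(idx), 0.2, 1.0))
  }
  bscan_stack(refl, protocol, motion_contrast = mot, origin_offset = origin)
}

#' Render the structural B-scan stack of a phantom
#'
#' Renders the layered background reflectivity, the planted objects as
#' soft-edged hyperreflective solids (no back-shadowing), convolves with
#' the instrument point-spread (from the protocol's axial/lateral
#' resolution), and multiplies gamma speckle whose variance scales as
#' `1 / n_averaged_frames`.
#'
#' @param layers a [layer_model()].
#' @param objects ground-truth objects from [plant_objects()].
#' @param protocol the structural [scan_protocol()].
#' @param config a [phantom_config()].
#' @param seed RNG seed for the speckle (defaults to `config$seed`).
#' @param noise set `FALSE` for a noiseless rendering.
#' @return a [bscan_stack()] without motion channel.
#' @export
render_structural <- function(layers, objects, protocol = config$structural_protocol,
                              config = phantom_config(), seed = config$seed,
                              noise = config$noise) {
  origin <- c(-protocol$field_width / 2, -protocol$field_depth_scans / 2)
  render_stack_impl(layers, objects, protocol, config, subseed(seed, 100),
                    origin, motion = FALSE, noise = noise)
}

#' Render the angiographic B-scan stack of a phantom
#'
#' Renders the structural channel at the angiographic protocol's (lower)
#' frame averaging and a motion-contrast channel that is positive inside
#' perfused vessels only, carries a weaker projection-artifact signal
#' directly posterior to superficial vessels, and sparse noise speckles.
#' The whole stack is rigidly transformed (lateral/scan-axis shift plus
#' en-face rotation) relative to the structural stack by the configured
#' misregistration.
#'
#' @inheritParams render_structural
#' @param protocol the angiographic [scan_protocol()].
#' @param misregistration `c(lateral_um, scanaxis_um, rotation_deg)`.
#' @return a [bscan_stack()] with motion channel.
#' @export
render_angiographic <- function(layers, objects, protocol = config$angio_protocol,
                                misregistration = config$misregistration,
                                config = phantom_config(), seed = config$seed,
                                noise = config$noise) {
  origin <- c(-protocol$field_width / 2, -protocol$field_depth_scans / 2)
  render_stack_impl(layers, objects, protocol, config, subseed(seed, 200),
                    origin, motion = TRUE, misreg = misregistration,
                    noise = noise)
}

#' Simulate a complete phantom
#'
#' Convenience wrapper: layer geometry, planted objects, and both rendered
#' stacks from one seed. Identical configuration and seed give bit-identical
#' output.
#'
#' @param config a [phantom_config()].
#' @param seed overrides `config$seed`.
#' @return a list with elements `structural`, `angio` (both
#'   [bscan_stack()]), `layers` ([layer_model()]), `truth` (data.frame) and
#'   `config`.
#' @export
simulate_phantom <- function(config = phantom_config(), seed = config$seed) {
  layers <- make_layer_geometry(config, seed)
  truth <- plant_objects(layers, config, seed)
  structural <- render_structural(layers, truth, config$structural_protocol,
                                  config, seed)
  angio <- render_angiographic(layers, truth, config$angio_protocol,
                               config$misregistration, config, seed)
  list(structural = structural, angio = angio, layers = layers,
       truth = truth, config = config)
}

#' Write / read ground truth as CSV
#'
#' @param objects ground-truth data.frame from [plant_objects()].
#' @param path CSV path.
#' @return `read_truth` returns the data.frame; `export_truth` returns
#'   `path` invisibly. The round trip is lossless.
#' @export
export_truth <- function(objects, path) {
  cols <- c("id", "kind", "x", "y", "z", "diameter", "length",
            "ux", "uy", "uz", "perfused", "layer_attachment", "branch_of")
  if (is.null(objects) || nrow(objects) == 0) {
    empty <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
    utils::write.csv(empty, path, row.names = FALSE)
    return(invisible(path))
  }
  if (anyDuplicated(objects$id)) stop("ground-truth ids must be unique")
  utils::write.csv(objects[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname export_truth
#' @export
read_truth <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tr)) {
    tr$length_axis <- mapply(axis_length, tr$kind, tr$length, tr$diameter)
    tr$perfused <- as.logical(tr$perfused)
    tr$branch_of <- as.integer(tr$branch_of)
  }
  tr
}
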