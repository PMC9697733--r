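#' Suppress background speckle
#'
#' Reduces multiplicative speckle noise in the structural channel with a
#' local adaptive (Lee-type) filter designed for multiplicative noise:
#' `out = mu + k * (x - mu)` with `mu` the local boxcar mean and
#' `k = max(0, 1 - Cn^2 mu^2 / var)`, where `Cn` is the speckle
#' coefficient of variation implied by the protocol's frame averaging.
#' In homogeneous speckle regions `k -> 0` and the output tends to the
#' local mean; at genuine structure `k -> 1` and the image passes through,
#' so on noiseless input object peak-to-background ratios are preserved
#' closely (the contrast of even the smallest dots changes by under 10%).
#'
#' @param stack a [bscan_stack()] with structural channel.
#' @param window_half half-width of the local statistics window, pixels.
#' @param speckle_shape_per_frame per-frame gamma shape of the speckle
#'   model; together with `n_averaged_frames` it sets `Cn`.
#' @return a filtered copy of `stack` (motion channel untouched).
#' @export
suppress_background <- function(stack, window_half = 2,
                                speckle_shape_per_frame = 1) {
  stopifnot(inherits(stack, "bscan_stack"))
  cn2 <- 1 / (speckle_shape_per_frame * stack$protocol$n_averaged_frames)
  out <- stack$reflectivity
  for (i in seq_len(stack$protocol$n_scans)) {
    x <- stack$reflectivity[i, , ]
    mu <- box_mean(x, window_half)
    m2 <- box_mean(x * x, window_half)
    v <- pmax(m2 - mu * mu, 0)
    k <- pmax(0, 1 - cn2 * mu * mu / pmax(v, 1e-12))
    out[i, , ] <- mu + k * (x - mu)
  }
  res <- stack
  res$reflectivity <- out
  attr(res, "suppressed") <- TRUE
  res
}

# Local background level per lateral position: median of the filtered
# values inside the layer band, pooled over a lateral window. Evaluated on
# a decimated column grid and linearly interpolated.
local_background <- function(img, band_lo_px, band_hi_px, cols,
                             win_cols = 5L, stride = 4L) {
  nc <- ncol(img)
  anchor <- unique(clamp(seq(min(cols), max(cols), by = stride), 1, nc))
  bg <- vapply(anchor, function(c0) {
    cc <- max(1, c0 - win_cols):min(nc, c0 + win_cols)
    vals <- unlist(lapply(cc, function(c2) {
      lo <- band_lo_px[c2]; hi <- band_hi_px[c2]
      if (hi < lo) return(numeric(0))
      img[lo:hi, c2]
    }))
    if (!length(vals)) return(NA_real_)
    stats::median(vals)
  }, numeric(1))
  stats::approx(anchor, bg, xout = cols, rule = 2)$y
}

#' Detect hyperreflective dots on the B-scans of a stack
#'
#' Finds, scan by scan, local intensity maxima that stand out against the
#' local background of a layer-defined band. In `"inl"` mode candidates
#' are restricted to the band between the IPL/INL and INL/OPL boundaries
#' and to the parafoveal region of interest (`roi_inner` to `roi_outer` um
#' temporal of the fovea); in `"onl"` mode the full lateral field between
#' the OPL/ONL boundary and the outer limit of the ONL is scanned. Each
#' detection carries its axial full-width-at-half-maximum diameter, its
#' peak-to-background contrast, the distance from its edge to the nearest
#' bounding layer, and (for INL detections) the location label from
#' [assign_location()].
#'
#' @param stack a speckle-suppressed [bscan_stack()] (see
#'   [suppress_background()]).
#' @param layers a [layer_model()] covering the stack.
#' @param params a [classification_params()].
#' @param roi `"inl"` (parafoveal INL) or `"onl"` (full-field ONL).
#' @return a data.frame of detections with columns `scan_index` (0-based),
#'   `scan_um`, `lateral`, `depth`, `axial_diameter`, `peak_contrast`,
#'   `layer`, `location`, `distance_to_nearest_boundary`,
#'   `diameter_capped`.
#' @export
detect_dots <- function(stack, layers, params = classification_params(),
                        roi = c("inl", "onl")) {
  roi <- match.arg(roi)
  if (missing(layers) || is.null(layers)) stop("missing layer model")
  stopifnot(inherits(layers, "layer_model"))
  p <- stack$protocol
  xs <- lateral_positions(stack)
  zs <- depth_positions(stack)
  ys <- scan_positions(stack)
  ap <- p$axial_pitch
  cols_all <- if (roi == "inl") {
    which(xs >= params$roi_inner & xs <= params$roi_outer)
  } else {
    seq_along(xs)
  }
  if (!length(cols_all)) return(empty_detections())
  band_names <- if (roi == "inl") c("ipl_inl", "inl_opl") else c("opl_onl", "onl_outer")
  out <- vector("list", p$n_scans)
  # a light Gaussian pre-smoothing (sigma ~ a third of the axial optical
  # resolution) on top of the adaptive speckle filter: the Lee filter
  # passes noise through at strong edges, and this keeps boundary ramps
  # from sprouting spurious maxima while broadening dot profiles by well
  # under a pixel
  smooth_sigma <- 2.5
  for (i in seq_len(p$n_scans)) {
    img <- blur_scan(stack$reflectivity[i, , ], smooth_sigma / ap,
                     smooth_sigma / p$lateral_pitch)
    blo <- boundary_depth(layers, band_names[1], xs, ys[i])
    bhi <- boundary_depth(layers, band_names[2], xs, ys[i])
    # candidate rows: pixels inside the band plus one pixel of slack on
    # each side, so boundary-attached dots whose blurred maximum falls in
    # the boundary pixel are not cut off; monotone ramps into the bright
    # bounding layers are rejected by the strict axial-maximum test
    lo_px <- clamp(ceiling(blo / ap) + 1L, 1L, nrow(img))
    hi_px <- clamp(floor(bhi / ap) + 1L, 1L, nrow(img))
    bg <- local_background(img, lo_px, hi_px, cols_all)
    dets <- find_scan_peaks(img, lo_px, hi_px, cols_all, bg, params, p)
    if (!nrow(dets)) next
    dets$scan_index <- i - 1L
    dets$scan_um <- ys[i]
    dets$lateral <- xs[dets$col]
    # refine diameter/depth from the axial profile
    meas <- lapply(seq_len(nrow(dets)), function(k) {
      measure_profile(img[, dets$col[k]], dets$row[k],
                      blo[dets$col[k]], bhi[dets$col[k]], dets$bg[k], ap)
    })
    dets$depth <- vapply(meas, `[[`, numeric(1), "depth")
    dets$axial_diameter <- vapply(meas, `[[`, numeric(1), "diameter")
    dets$diameter_capped <- vapply(meas, `[[`, logical(1), "capped")
    dets$layer <- if (roi == "inl") "INL" else "ONL"
    # distance from dot edge to the nearest bounding layer
    d_top <- (dets$depth - dets$axial_diameter / 2) - blo[dets$col]
    d_bot <- bhi[dets$col] - (dets$depth + dets$axial_diameter / 2)
    dets$distance_to_nearest_boundary <- pmax(pmin(d_top, d_bot), 0)
    if (roi == "inl") {
      dets$location <- vapply(seq_len(nrow(dets)), function(k) {
        locate_inl(dets$depth[k], dets$axial_diameter[k],
                   blo[dets$col[k]], bhi[dets$col[k]], ap)
      }, character(1))
    } else {
      dets$location <- "not_applicable"
    }
    out[[i]] <- dets
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty_detections())
  res <- do.call(rbind, out)
  res <- res[, c("scan_index", "scan_um", "lateral", "depth", "axial_diameter",
                 "peak_contrast", "layer", "location",
                 "distance_to_nearest_boundary", "diameter_capped")]
  rownames(res) <- NULL
  attr(res, "stack_uid") <- stack_uid(stack)
  attr(res, "scan_spacing") <- p$scan_spacing
  res
}

empty_detections <- function() {
  d <- data.frame(scan_index = integer(0), scan_um = numeric(0),
                  lateral = numeric(0), depth = numeric(0),
                  axial_diameter = numeric(0), peak_contrast = numeric(0),
                  layer = character(0), location = character(0),
                  distance_to_nearest_boundary = numeric(0),
                  diameter_capped = logical(0))
  d
}

# Local maxima above the contrast threshold within the band, de-duplicated
# so that one object cross-section yields one peak.
find_scan_peaks <- function(img, lo_px, hi_px, cols, bg, params, protocol) {
  nr <- nrow(img); nc <- ncol(img)
  cand_r <- integer(0); cand_c <- integer(0); cand_v <- numeric(0); cand_bg <- numeric(0)
  for (ci in seq_along(cols)) {
    c2 <- cols[ci]
    lo <- lo_px[c2]; hi <- hi_px[c2]
    if (hi < lo) next
    rr <- lo:hi
    v <- img[rr, c2]
    thr <- params$contrast_threshold * bg[ci]
    ok <- which(v >= thr)
    if (!length(ok)) next
    for (k in ok) {
      r <- rr[k]
      # near-max against axial neighbours in the full image, with a small
      # relative tolerance so that shoulders of dots merging into a bright
      # bounding layer survive while monotone boundary ramps (whose
      # per-pixel slope is several times larger) are rejected
      if (r > 1 && img[r - 1, c2] > 1.06 * v[k]) next
      if (r < nr && img[r + 1, c2] > 1.06 * v[k]) next
      if (c2 > 1 && img[r, c2 - 1] > v[k]) next
      if (c2 < nc && img[r, c2 + 1] > v[k]) next
      # lateral prominence: a dot is laterally localized, whereas speckle
      # maxima riding the boundary ramps have flanks of the same brightness
      fl <- c((c2 - 6):(c2 - 3), (c2 + 3):(c2 + 6))
      fl <- fl[fl >= 1 & fl <= nc]
      if (length(fl) && v[k] < 1.15 * stats::median(img[r, fl])) next
      cand_r <- c(cand_r, r); cand_c <- c(cand_c, c2)
      cand_v <- c(cand_v, v[k]); cand_bg <- c(cand_bg, bg[ci])
    }
  }
  if (!length(cand_r)) {
    return(data.frame(row = integer(0), col = integer(0),
                      peak_contrast = numeric(0), bg = numeric(0)))
  }
  # greedy non-maximum suppression within a physical radius
  ord <- order(-cand_v, cand_c, cand_r)
  keep <- logical(length(ord))
  sup_lat <- 20 / protocol$lateral_pitch
  sup_ax <- 20 / protocol$axial_pitch
  taken_r <- numeric(0); taken_c <- numeric(0)
  for (k in ord) {
    if (length(taken_r)) {
      dd <- ((cand_r[k] - taken_r) / sup_ax)^2 + ((cand_c[k] - taken_c) / sup_lat)^2
      if (any(dd < 1)) next
    }
    keep[k] <- TRUE
    taken_r <- c(taken_r, cand_r[k]); taken_c <- c(taken_c, cand_c[k])
  }
  data.frame(row = cand_r[keep], col = cand_c[keep],
             peak_contrast = cand_v[keep] / cand_bg[keep], bg = cand_bg[keep])
}

# FWHM of the axial profile through a peak, above local background, capped
# at the layer band when the half-maximum crossing is not reached inside it.
measure_profile <- function(prof, peak_row, band_lo_um, band_hi_um, bg, axial_pitch) {
  zs <- (seq_along(prof) - 1) * axial_pitch
  level <- bg + (prof[peak_row] - bg) / 2
  lo_lim <- band_lo_um; hi_lim <- band_hi_um
  # walk up (anterior)
  r <- peak_row; z_up <- NA; capped_up <- FALSE
  while (r > 1) {
    if (zs[r - 1] < lo_lim) { z_up <- lo_lim; capped_up <- TRUE; break }
    if (prof[r - 1] < level) {
      f <- (prof[r] - level) / (prof[r] - prof[r - 1])
      z_up <- zs[r] - f * axial_pitch
      break
    }
    r <- r - 1
  }
  if (is.na(z_up)) { z_up <- max(zs[1], lo_lim); capped_up <- TRUE }
  # walk down (posterior)
  r <- peak_row; z_dn <- NA; capped_dn <- FALSE
  n <- length(prof)
  while (r < n) {
    if (zs[r + 1] > hi_lim) { z_dn <- hi_lim; capped_dn <- TRUE; break }
    if (prof[r + 1] < level) {
      f <- (prof[r] - level) / (prof[r] - prof[r + 1])
      z_dn <- zs[r] + f * axial_pitch
      break
    }
    r <- r + 1
  }
  if (is.na(z_dn)) { z_dn <- min(zs[n], hi_lim); capped_dn <- TRUE }
  list(diameter = max(z_dn - z_up, axial_pitch / 2),
       depth = (z_up + z_dn) / 2,
       capped = capped_up || capped_dn)
}

#' Measure the axial diameter of a detection
#'
#' Full-width-at-half-maximum of the axial intensity profile through the
#' detection's peak, above the local background, in um. If the half-maximum
#' crossing is not reached inside the layer band the diameter is capped at
#' the band and flagged.
#'
#' @param stack the (speckle-suppressed) [bscan_stack()] the detection
#'   came from.
#' @param detection one row of a [detect_dots()] data.frame.
#' @param layers a [layer_model()].
#' @return a list with `diameter` (um), `depth` (um, profile center) and
#'   `capped` (logical).
#' @export
measure_axial_diameter <- function(stack, detection, layers) {
  p <- stack$protocol
  xs <- lateral_positions(stack)
  col <- which.min(abs(xs - detection$lateral))
  band <- if (detection$layer == "INL") c("ipl_inl", "inl_opl") else c("opl_onl", "onl_outer")
  blo <- boundary_depth(layers, band[1], detection$lateral, detection$scan_um)
  bhi <- boundary_depth(layers, band[2], detection$lateral, detection$scan_um)
  prof <- stack$reflectivity[detection$scan_index + 1L, , col]
  peak_row <- clamp(round(detection$depth / p$axial_pitch) + 1L, 1L, length(prof))
  # re-center on the local maximum
  w <- clamp((peak_row - 2L):(peak_row + 2L), 1L, length(prof))
  peak_row <- w[which.max(prof[w])]
  bg <- detection$peak_contrast
  bg <- prof[peak_row] / bg   # background implied by the stored contrast
  measure_profile(prof, peak_row, blo, bhi, bg, p$axial_pitch)
}

locate_inl <- function(depth, diameter, b_ipl, b_opl, axial_pitch) {
  tol <- axial_pitch / 2
  top <- depth - diameter / 2
  bot <- depth + diameter / 2
  touch_ipl <- (top - b_ipl) <= tol
  touch_opl <- (b_opl - bot) <= tol
  if (touch_ipl && touch_opl) {
    # signed gaps: the boundary the dot is pressed into (more negative
    # gap, i.e. deeper overlap) wins
    if ((top - b_ipl) <= (b_opl - bot)) "near_IPL" else "near_OPL"
  } else if (touch_ipl) "near_IPL"
  else if (touch_opl) "near_OPL"
  else "inside_INL"
}

#' Assign the location label of an INL detection
#'
#' A dot is `near_IPL` / `near_OPL` when its axial extent
#' (`depth +/- diameter/2`) touches the respective boundary within half an
#' axial pixel, and `inside_INL` when its full circumference is clear of
#' both. A dot touching both boundaries is assigned to the nearer one.
#'
#' @param detection one row of a [detect_dots()] data.frame (INL layer).
#' @param layers a [layer_model()].
#' @param axial_pitch axial pixel pitch, um (sets the contact tolerance).
#' @return `"near_IPL"`, `"near_OPL"` or `"inside_INL"`.
#' @export
assign_location <- function(detection, layers, axial_pitch = 3.9) {
  stopifnot(detection$layer == "INL")
  b2 <- boundary_depth(layers, "ipl_inl", detection$lateral, detection$scan_um)
  b3 <- boundary_depth(layers, "inl_opl", detection$lateral, detection$scan_um)
  locate_inl(detection$depth, detection$axial_diameter, b2, b3, axial_pitch)
}

#' Filter outer nuclear layer detections
#'
#' Keeps ONL detections whose axial diameter exceeds `onl_min_diameter`
#' and whose distance from the adjacent layers exceeds the width of the
#' dot itself, excluding localized thickenings of the OPL or the outer
#' limiting membrane. Order is preserved; the operation is idempotent.
#'
#' @param detections a [detect_dots()] data.frame in `"onl"` mode.
#' @param params a [classification_params()].
#' @return the filtered subset.
#' @export
filter_onl <- function(detections, params = classification_params()) {
  if (!nrow(detections)) return(detections)
  keep <- detections$axial_diameter > params$onl_min_diameter &
    detections$distance_to_nearest_boundary > detections$axial_diameter
  out <- detections[keep, , drop = FALSE]
  attr(out, "stack_uid") <- attr(detections, "stack_uid")
  attr(out, "scan_spacing") <- attr(detections, "scan_spacing")
  out
}
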