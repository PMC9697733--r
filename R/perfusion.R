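#' Align a structural and an angiographic B-scan stack
#'
#' Estimates the rigid en-face transform (lateral shift, scan-axis shift,
#' rotation) between the two stacks by maximizing the normalized
#' cross-correlation of their depth-projected structural channels over a
#' coarse-to-fine search, then refines it and reports a landmark residual:
#' bright en-face features of the angiographic projection are mapped into
#' the structural frame and matched to their nearest local maxima, and the
#' RMS of the offsets is returned. The per-scan mapping from structural to
#' angiographic B-scan index is built from physical position along the
#' scan axis and is monotone.
#'
#' @param structural structural [bscan_stack()].
#' @param angio angiographic [bscan_stack()].
#' @param search `c(shift_um, rotation_deg)` half-widths of the search.
#' @param grid_um en-face sampling pitch of the correlation grid.
#' @param cor_floor minimum acceptable correlation peak; below it the
#'   alignment is declared failed.
#' @return an object of class `alignment_transform` with fields
#'   `lateral_shift`, `scanaxis_shift` (um), `rotation` (degrees),
#'   `residual` (um), `correlation`, and `matched_scan_index` (one 0-based
#'   angiographic index per structural scan, `NA` outside the overlap).
#' @export
align_stacks <- function(structural, angio, search = c(30, 1.5),
                         grid_um = 25, cor_floor = 0.2) {
  Es <- enface_projection(structural)
  Ea <- enface_projection(angio)
  # sample points in the angiographic frame, kept off the field edge
  xa <- lateral_positions(angio); ya <- scan_positions(angio)
  gx <- seq(min(xa) + 150, max(xa) - 150, by = grid_um)
  gy <- seq(min(ya) + 100, max(ya) - 100, by = grid_um)
  pts <- expand.grid(x = gx, y = gy)
  av <- bilinear(Ea, (pts$y - ya[1]) / angio$protocol$scan_spacing + 1,
                 (pts$x - xa[1]) / angio$protocol$lateral_pitch + 1)
  ok0 <- !is.na(av)
  pts <- pts[ok0, ]; av <- av[ok0]
  xs0 <- lateral_positions(structural)[1]; ys0 <- scan_positions(structural)[1]
  score <- function(tx, ty, th) {
    sc <- misreg_apply(pts$x, pts$y, c(tx, ty, th))
    sv <- bilinear(Es, (sc$y - ys0) / structural$protocol$scan_spacing + 1,
                   (sc$x - xs0) / structural$protocol$lateral_pitch + 1)
    ok <- !is.na(sv)
    if (sum(ok) < 50) return(-Inf)
    stats::cor(sv[ok], av[ok])
  }
  best <- c(tx = 0, ty = 0, th = 0); best_s <- -Inf
  run_grid <- function(txs, tys, ths) {
    for (th in ths) for (ty in tys) for (tx in txs) {
      s <- score(tx, ty, th)
      if (s > best_s) { best_s <<- s; best <<- c(tx = tx, ty = ty, th = th) }
    }
  }
  run_grid(seq(-search[1], search[1], by = 5),
           seq(-search[1], search[1], by = 5),
           seq(-search[2], search[2], by = 0.1))
  run_grid(seq(best["tx"] - 4, best["tx"] + 4, by = 1),
           seq(best["ty"] - 4, best["ty"] + 4, by = 1),
           seq(best["th"] - 0.1, best["th"] + 0.1, by = 0.02))
  run_grid(seq(best["tx"] - 1.5, best["tx"] + 1.5, by = 0.5),
           seq(best["ty"] - 1.5, best["ty"] + 1.5, by = 0.5),
           seq(best["th"] - 0.03, best["th"] + 0.03, by = 0.01))
  if (best_s < cor_floor) {
    stop("alignment failure: correlation peak ", signif(best_s, 3),
         " below floor ", cor_floor)
  }
  residual <- landmark_residual(Es, Ea, structural, angio, best)
  # structural scan i -> angiographic scan index at the fovea's lateral
  # position, by physical position
  ys <- scan_positions(structural)
  inv <- misreg_invert(rep(0, length(ys)), ys, best)
  idx <- round((inv$y - ya[1]) / angio$protocol$scan_spacing)
  idx[idx < 0 | idx > (angio$protocol$n_scans - 1)] <- NA
  structure(list(
    lateral_shift = unname(best["tx"]),
    scanaxis_shift = unname(best["ty"]),
    rotation = unname(best["th"]),
    residual = residual,
    correlation = best_s,
    matched_scan_index = as.integer(idx),
    angio_origin = angio$origin_offset,
    angio_protocol = angio$protocol
  ), class = "alignment_transform")
}

#' @export
print.alignment_transform <- function(x, ...) {
  cat(sprintf("<alignment_transform> shift (%.1f, %.1f) um, rotation %.2f deg, r = %.3f, residual %.1f um\n",
              x$lateral_shift, x$scanaxis_shift, x$rotation, x$correlation, x$residual))
  invisible(x)
}

# Depth-mean en-face projection of the structural channel, z-scored.
enface_projection <- function(stack) {
  E <- apply(stack$reflectivity, c(1, 3), mean)
  (E - mean(E)) / stats::sd(E)
}

landmark_residual <- function(Es, Ea, structural, angio, tr, n_landmarks = 8) {
  xa <- lateral_positions(angio); ya <- scan_positions(angio)
  xs <- lateral_positions(structural); ys <- scan_positions(structural)
  # brightest well-separated angiographic en-face features
  ord <- order(-as.vector(Ea))
  sel <- matrix(numeric(0), 0, 2)
  for (k in ord) {
    i <- (k - 1) %% nrow(Ea) + 1; j <- (k - 1) %/% nrow(Ea) + 1
    p <- c(xa[j], ya[i])
    if (nrow(sel) && any((sel[, 1] - p[1])^2 + (sel[, 2] - p[2])^2 < 150^2)) next
    sel <- rbind(sel, p)
    if (nrow(sel) >= n_landmarks) break
  }
  offs <- numeric(0)
  for (k in seq_len(nrow(sel))) {
    sc <- misreg_apply(sel[k, 1], sel[k, 2], tr)
    ci <- round((sc$x - xs[1]) / structural$protocol$lateral_pitch) + 1
    ri <- round((sc$y - ys[1]) / structural$protocol$scan_spacing) + 1
    if (is.na(ci) || ci < 4 || ci > ncol(Es) - 3 || ri < 3 || ri > nrow(Es) - 2) next
    w_r <- (ri - 2):(ri + 2); w_c <- (ci - 3):(ci + 3)
    sub <- Es[w_r, w_c]
    m <- arrayInd(which.max(sub), dim(sub))
    dx <- (w_c[m[2]] - ci) * structural$protocol$lateral_pitch
    dy <- (w_r[m[1]] - ri) * structural$protocol$scan_spacing
    offs <- c(offs, dx^2 + dy^2)
  }
  if (!length(offs)) return(NA_real_)
  sqrt(mean(offs))
}

#' Map structural-frame coordinates into the angiographic frame
#'
#' @param transform an [align_stacks()] result.
#' @param x,y structural-frame en-face positions, um.
#' @return list with `x`, `y` (angiographic-frame um) and `scan`
#'   (continuous 0-based angiographic scan index).
#' @export
map_to_angio <- function(transform, x, y) {
  tr <- c(transform$lateral_shift, transform$scanaxis_shift, transform$rotation)
  inv <- misreg_invert(x, y, tr)
  scan <- (inv$y - transform$angio_origin[2]) / transform$angio_protocol$scan_spacing
  list(x = inv$x, y = inv$y, scan = scan)
}

#' Assess the perfusion evidence for one element
#'
#' Maps the element's per-scan footprints into the angiographic frame and,
#' for each occupied structural scan, examines the mapped angiographic
#' B-scan and its +/- `alignment_tolerance_scans` neighbours: a scan shows
#' an interior signal when at least `min_voxels` motion-contrast voxels
#' above `motion_threshold` fall inside the footprint, and an adjacent
#' signal when such voxels fall within `adjacency_window` of the footprint
#' but not inside it. A projection risk is flagged when motion signal sits
#' directly anterior to the element within its lateral window. The element
#' is not retrievable when it falls outside the (narrower) angiographic
#' field or when its structural correlate cannot be found in the
#' angiographic structural channel on at least half of its scans.
#'
#' @param element a [new_element()].
#' @param angio angiographic [bscan_stack()] with motion channel; pass the
#'   speckle-suppressed version for a more reliable structural correlate
#'   check.
#' @param transform an [align_stacks()] result.
#' @param params a [classification_params()].
#' @param motion_threshold motion-contrast value counting as flow signal.
#' @param min_voxels voxels above threshold needed inside a footprint.
#' @param footprint_margin um added around the dot radius.
#' @return a list with `overlap_fraction`, `adjacent_signal`,
#'   `projection_risk`, `retrievable` and the per-scan detail matrix.
#' @export
assess_perfusion <- function(element, angio, transform,
                             params = classification_params(),
                             motion_threshold = 0.5, min_voxels = 2,
                             footprint_margin = 6) {
  stopifnot(!is.null(angio$motion_contrast))
  p <- angio$protocol
  xa <- lateral_positions(angio)
  za <- depth_positions(angio)
  det <- element$detections
  n <- nrow(det)
  interior <- logical(n); adjacent <- logical(n)
  retr <- logical(n); proj <- logical(n); infield <- logical(n)
  tol <- params$alignment_tolerance_scans
  for (k in seq_len(n)) {
    m <- map_to_angio(transform, det$lateral[k], det$scan_um[k])
    r <- det$axial_diameter[k] / 2 + footprint_margin
    if (m$x < min(xa) + r || m$x > max(xa) - r ||
        m$scan < 0 || m$scan > p$n_scans - 1) {
      infield[k] <- FALSE
      next
    }
    infield[k] <- TRUE
    j0 <- round(m$scan)
    js <- clamp((j0 - tol):(j0 + tol), 0, p$n_scans - 1)
    cols <- which(abs(xa - m$x) <= r)
    rows <- which(abs(za - det$depth[k]) <= r)
    ring_cols <- which(abs(xa - m$x) <= r + params$adjacency_window)
    ring_rows <- which(abs(za - det$depth[k]) <= r + params$adjacency_window)
    ant_rows <- which(za < det$depth[k] - r - 2)
    for (j in unique(js)) {
      mot <- angio$motion_contrast[j + 1, , ]
      inside <- sum(mot[rows, cols] >= motion_threshold)
      if (inside >= min_voxels) interior[k] <- TRUE
      ring <- sum(mot[ring_rows, ring_cols] >= motion_threshold) - inside
      if (!interior[k] && ring >= min_voxels) adjacent[k] <- TRUE
      # structural correlate in the angiographic structural channel:
      # the dot must stand out against its lateral flanks at its own depth
      # (a ring median would be inflated by the bright plexiform layers
      # right next to boundary-attached dots)
      st <- angio$reflectivity[j + 1, , ]
      flank_cols <- setdiff(ring_cols, cols)
      if (length(flank_cols)) {
        bg <- stats::quantile(st[rows, flank_cols], 0.25, names = FALSE)
        if (max(st[rows, cols]) / max(bg, 1e-9) >= 1.4) retr[k] <- TRUE
      }
      if (length(ant_rows) &&
          sum(angio$motion_contrast[j + 1, ant_rows, cols] >= 0.2) >= min_voxels) {
        proj[k] <- TRUE
      }
    }
  }
  any_in <- any(infield)
  list(
    overlap_fraction = if (any_in) mean(interior[infield]) else 0,
    adjacent_signal = any_in &&
      mean(adjacent[infield] & !interior[infield]) >= params$perfusion_overlap_fraction,
    projection_risk = any(proj),
    retrievable = any_in && mean(retr[infield]) >= 0.5 && mean(infield) >= 0.5,
    per_scan = data.frame(scan_index = det$scan_index, in_field = infield,
                          interior = interior, adjacent = adjacent,
                          retrievable = retr, projection = proj)
  )
}

#' Assign the final perfusion-based class of an element
#'
#' An element is `unclassifiable` when it cannot be retrieved on the
#' angiographic scans or when its spatial and flow characteristics
#' disagree between the two frames (a granule-shaped element overlaid by a
#' motion signal). Otherwise a granule-shaped element without interior
#' flow is a `granule`; an elongated element with interior signal in at
#' least `perfusion_overlap_fraction` of its scans is a
#' `perfused_filiform` element; an elongated element whose motion signal
#' is absent or consistently adjacent is a `nonperfused_filiform` element.
#' Projection-artifact susceptibility is carried as a flag, never a class.
#'
#' @param element a [new_element()].
#' @param assessment an [assess_perfusion()] result.
#' @param params a [classification_params()].
#' @return an object of class `classified_element` with fields `element`,
#'   `final_class`, `motion_overlap_fraction`, `adjacent_signal`,
#'   `projection_risk`, `retrievable`, `shape_class`.
#' @export
classify_element <- function(element, assessment, params = classification_params()) {
  shape <- classify_shape(element, params)
  thr <- params$perfusion_overlap_fraction
  ov <- assessment$overlap_fraction
  final <- if (!assessment$retrievable) {
    "unclassifiable"
  } else if (shape == "granule") {
    if (ov < thr) "granule" else "unclassifiable"
  } else {
    if (ov >= thr) "perfused_filiform" else "nonperfused_filiform"
  }
  structure(list(
    element = element,
    shape_class = shape,
    final_class = final,
    motion_overlap_fraction = ov,
    adjacent_signal = assessment$adjacent_signal,
    projection_risk = assessment$projection_risk,
    retrievable = assessment$retrievable
  ), class = "classified_element")
}

#' Classify all elements of a stack pair
#'
#' @param elements list of [new_element()] objects.
#' @param angio angiographic [bscan_stack()] with motion channel.
#' @param transform an [align_stacks()] result.
#' @param params a [classification_params()].
#' @param suppress speckle-suppress the angiographic structural channel
#'   before assessing (recommended).
#' @return list of [classify_element()] results, one per element.
#' @export
classify_elements <- function(elements, angio, transform,
                              params = classification_params(),
                              suppress = TRUE) {
  if (suppress) angio <- suppress_background(angio)
  lapply(elements, function(e) {
    classify_element(e, assess_perfusion(e, angio, transform, params), params)
  })
}

#' Tabulate classified elements
#'
#' @param classified list of [classify_element()] results.
#' @param protocol structural [scan_protocol()].
#' @param params a [classification_params()].
#' @return data.frame with one row per element.
#' @export
classified_table <- function(classified, protocol, params = classification_params()) {
  base <- elements_table(lapply(classified, `[[`, "element"), protocol, params)
  base$final_class <- vapply(classified, `[[`, character(1), "final_class")
  base$overlap_fraction <- vapply(classified, `[[`, numeric(1), "motion_overlap_fraction")
  base$adjacent_signal <- vapply(classified, `[[`, logical(1), "adjacent_signal")
  base$projection_risk <- vapply(classified, `[[`, logical(1), "projection_risk")
  base$retrievable <- vapply(classified, `[[`, logical(1), "retrievable")
  base
}
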