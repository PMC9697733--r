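#' B-scan stack
#'
#' A volume of OCT reflectivity values, dimensioned `[scan, depth, lateral]`
#' (the scan axis is the slow axis), with an optional motion-contrast
#' channel of identical shape, the acquisition protocol, and the physical
#' position of the stack's corner relative to the fovea center.
#'
#' Coordinate contract: indices are 0-based half-open pixel boxes at the
#' interface level; a pixel index `i` sits at physical position
#' `origin + i * pitch`. Lateral positions are um temporal from the fovea
#' center (positive temporal); scan-axis positions are um from the fovea
#' center along the slow axis; depth is um from the top of the image.
#'
#' @param reflectivity 3D numeric array `[scan, depth, lateral]`, non-negative.
#' @param protocol a [scan_protocol()].
#' @param motion_contrast optional 3D array, same shape, non-negative.
#' @param origin_offset length-2 numeric `(lateral um, scan-axis um)` of the
#'   first pixel / first scan relative to the fovea center. Defaults to a
#'   fovea-centered stack.
#' @return an object of class `bscan_stack`.
#' @export
bscan_stack <- function(reflectivity, protocol, motion_contrast = NULL,
                        origin_offset = NULL) {
  stopifnot(inherits(protocol, "scan_protocol"))
  d <- dim(reflectivity)
  if (length(d) != 3) stop("reflectivity must be a 3D array [scan, depth, lateral]")
  if (d[1] != protocol$n_scans) {
    stop(sprintf("shape/protocol mismatch in field 'n_scans': %d scans in volume, %d in protocol",
                 d[1], protocol$n_scans))
  }
  if (any(reflectivity < 0)) stop("reflectivity must be non-negative")
  if (!is.null(motion_contrast)) {
    if (!identical(dim(motion_contrast), d)) {
      stop("shape mismatch in field 'motion_contrast': must equal reflectivity shape")
    }
    if (any(motion_contrast < 0)) stop("motion_contrast must be non-negative")
  }
  if (is.null(origin_offset)) {
    origin_offset <- c(-protocol$field_width / 2, -protocol$field_depth_scans / 2)
  }
  stopifnot(length(origin_offset) == 2, all(is.finite(origin_offset)))
  structure(list(
    reflectivity = reflectivity,
    motion_contrast = motion_contrast,
    protocol = protocol,
    origin_offset = as.numeric(origin_offset)
  ), class = "bscan_stack")
}

#' @export
print.bscan_stack <- function(x, ...) {
  d <- dim(x$reflectivity)
  cat(sprintf("<bscan_stack> %d x %d x %d [scan, depth, lateral]%s\n",
              d[1], d[2], d[3],
              if (is.null(x$motion_contrast)) "" else " + motion contrast"))
  print(x$protocol)
  invisible(x)
}

#' Physical positions of the pixel grid of a stack
#'
#' @param stack a [bscan_stack()].
#' @return numeric vector of positions, um.
#' @export
scan_positions <- function(stack) {
  stack$origin_offset[2] + (seq_len(stack$protocol$n_scans) - 1) * stack$protocol$scan_spacing
}

#' @rdname scan_positions
#' @export
lateral_positions <- function(stack) {
  stack$origin_offset[1] + (seq_len(dim(stack$reflectivity)[3]) - 1) * stack$protocol$lateral_pitch
}

#' @rdname scan_positions
#' @export
depth_positions <- function(stack) {
  (seq_len(dim(stack$reflectivity)[2]) - 1) * stack$protocol$axial_pitch
}

# Identifier tying detections to the stack they came from.
stack_uid <- function(stack) {
  p <- stack$protocol
  paste(p$n_scans, p$scan_spacing, p$lateral_pitch, p$axial_pitch,
        stack$origin_offset[1], stack$origin_offset[2],
        dim(stack$reflectivity)[2], dim(stack$reflectivity)[3], sep = "/")
}

sidecar_path <- function(path) {
  sub("\\.tiff?$", "", path, ignore.case = TRUE) |> paste0(".json")
}

#' Write a B-scan stack to disk
#'
#' Persists the stack as a multi-page TIFF (one 32-bit float page per
#' B-scan per channel, channels interleaved scan by scan) plus a JSON
#' sidecar carrying the protocol, origin, channel list and an intensity
#' scale. Values are divided by the stored scale so the TIFF payload stays
#' in `[0, 1]`; the round trip is lossless at single precision. Output
#' bytes are deterministic for identical input.
#'
#' @param stack a valid [bscan_stack()].
#' @param path output TIFF path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @seealso [read_stack()]
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "bscan_stack"))
  channels <- if (is.null(stack$motion_contrast)) "structural" else c("structural", "motion")
  scale <- max(1, max(stack$reflectivity),
               if (is.null(stack$motion_contrast)) 0 else max(stack$motion_contrast))
  pages <- vector("list", stack$protocol$n_scans * length(channels))
  k <- 1L
  for (i in seq_len(stack$protocol$n_scans)) {
    pages[[k]] <- stack$reflectivity[i, , ] / scale
    k <- k + 1L
    if (!is.null(stack$motion_contrast)) {
      pages[[k]] <- stack$motion_contrast[i, , ] / scale
      k <- k + 1L
    }
  }
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  p <- stack$protocol
  meta <- list(
    n_scans = p$n_scans,
    scan_spacing_um = p$scan_spacing,
    lateral_pitch_um = p$lateral_pitch,
    axial_pitch_um = p$axial_pitch,
    field_width_um = p$field_width,
    n_averaged_frames = p$n_averaged_frames,
    axial_resolution_um = p$axial_resolution,
    lateral_resolution_um = p$lateral_resolution,
    origin_um = stack$origin_offset,
    channels = channels,
    intensity_scale = scale
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a B-scan stack from disk
#'
#' Reads a multi-page TIFF volume written by [write_stack()] together with
#' its JSON metadata sidecar and returns a validated [bscan_stack()]. The
#' page count must match `n_scans` (times the channel count) declared in
#' the sidecar.
#'
#' @param path TIFF path (sidecar expected next to it).
#' @return a [bscan_stack()].
#' @export
read_stack <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("missing sidecar: expected metadata file at ", sc)
  if (!file.exists(path)) stop("missing volume file: ", path)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  req <- c("n_scans", "scan_spacing_um", "lateral_pitch_um", "axial_pitch_um",
           "field_width_um", "n_averaged_frames", "origin_um", "channels",
           "intensity_scale")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("sidecar missing field '", miss[1], "'")
  protocol <- scan_protocol(
    n_scans = meta$n_scans, scan_spacing = meta$scan_spacing_um,
    lateral_pitch = meta$lateral_pitch_um, axial_pitch = meta$axial_pitch_um,
    field_width = meta$field_width_um, n_averaged_frames = meta$n_averaged_frames,
    axial_resolution = if (!is.null(meta$axial_resolution_um)) meta$axial_resolution_um else 7,
    lateral_resolution = if (!is.null(meta$lateral_resolution_um)) meta$lateral_resolution_um else 14)
  pages <- suppressWarnings(tiff::readTIFF(path, all = TRUE))
  nch <- length(meta$channels)
  if (length(pages) != protocol$n_scans * nch) {
    stop(sprintf("shape/protocol mismatch in field 'n_scans': sidecar declares %d scans x %d channels but volume has %d pages",
                 protocol$n_scans, nch, length(pages)))
  }
  d2 <- dim(pages[[1]])
  scale <- meta$intensity_scale
  refl <- array(0, c(protocol$n_scans, d2[1], d2[2]))
  mot <- if (nch == 2) array(0, c(protocol$n_scans, d2[1], d2[2])) else NULL
  for (i in seq_len(protocol$n_scans)) {
    refl[i, , ] <- pages[[(i - 1) * nch + 1]] * scale
    if (nch == 2) mot[i, , ] <- pages[[(i - 1) * nch + 2]] * scale
  }
  bscan_stack(refl, protocol, motion_contrast = mot,
              origin_offset = unlist(meta$origin_um))
}
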