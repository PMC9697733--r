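#' Scan protocol for a B-scan stack
#'
#' Describes the acquisition geometry of an OCT B-scan stack: how many
#' parallel B-scans were taken, their spacing along the slow (scan) axis,
#' the pixel pitches within a B-scan, the lateral field size, how many
#' frames were averaged per B-scan, and the nominal optical resolution.
#' All physical quantities are in micrometres.
#'
#' The depth extent of the stack along the scan axis is derived, not
#' supplied: `field_depth_scans = scan_spacing * (n_scans - 1)`.
#'
#' @param n_scans number of B-scans in the stack (>= 1).
#' @param scan_spacing distance between adjacent B-scans, um.
#' @param lateral_pitch um per pixel within a B-scan (fast axis).
#' @param axial_pitch um per pixel in depth.
#' @param field_width lateral extent of the field, um.
#' @param n_averaged_frames frames averaged per B-scan (sets speckle level).
#' @param axial_resolution nominal axial optical resolution (FWHM), um.
#' @param lateral_resolution nominal lateral optical resolution (FWHM), um.
#' @return an object of class `scan_protocol`.
#' @examples
#' p <- structural_protocol()
#' p$field_depth_scans  # 1430 um for 131 scans spaced 11 um apart
#' @export
scan_protocol <- function(n_scans, scan_spacing, lateral_pitch, axial_pitch,
                          field_width, n_averaged_frames,
                          axial_resolution = 7, lateral_resolution = 14) {
  n_scans <- as.integer(n_scans)
  stopifnot(length(n_scans) == 1, !is.na(n_scans))
  if (n_scans < 1) stop("n_scans must be >= 1")
  vals <- c(scan_spacing = scan_spacing, lateral_pitch = lateral_pitch,
            axial_pitch = axial_pitch, field_width = field_width,
            axial_resolution = axial_resolution,
            lateral_resolution = lateral_resolution)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all pitches, spacings and resolutions must be positive")
  }
  if (n_averaged_frames < 1) stop("n_averaged_frames must be >= 1")
  structure(list(
    n_scans = n_scans,
    scan_spacing = scan_spacing,
    lateral_pitch = lateral_pitch,
    axial_pitch = axial_pitch,
    field_width = field_width,
    field_depth_scans = scan_spacing * (n_scans - 1),
    n_averaged_frames = n_averaged_frames,
    axial_resolution = axial_resolution,
    lateral_resolution = lateral_resolution
  ), class = "scan_protocol")
}

#' @export
print.scan_protocol <- function(x, ...) {
  cat(sprintf(
    "<scan_protocol> %d B-scans spaced %.1f um (%.0f x %.0f um field), %g-frame averaging\n",
    x$n_scans, x$scan_spacing, x$field_width, x$field_depth_scans,
    x$n_averaged_frames))
  invisible(x)
}

#' Structural acquisition protocol
#'
#' The dense structural protocol: 131 horizontal B-scans spaced 11 um apart
#' over a 4.5 x 1 mm fovea-centered field with 100-frame averaging.
#' Pixel pitches default to 6 um lateral and 3.9 um axial, i.e. modest
#' oversampling of the 14 um / 7 um optical resolution.
#'
#' @param lateral_pitch,axial_pitch pixel pitches, um.
#' @return a [scan_protocol()].
#' @export
structural_protocol <- function(lateral_pitch = 6, axial_pitch = 3.9) {
  scan_protocol(n_scans = 131, scan_spacing = 11,
                lateral_pitch = lateral_pitch, axial_pitch = axial_pitch,
                field_width = 4500, n_averaged_frames = 100)
}

#' Angiographic acquisition protocol
#'
#' The angiographic protocol: horizontal B-scans spaced 5.9 um apart over a
#' concentric 3 x 3 mm fovea-centered field with 7-frame averaging. The
#' block length defaults to 512 scans; 256-scan blocks of the same spacing
#' are also accepted.
#'
#' @param n_scans number of B-scans in the block (default 512).
#' @param lateral_pitch,axial_pitch pixel pitches, um.
#' @return a [scan_protocol()].
#' @export
angio_protocol <- function(n_scans = 512, lateral_pitch = 6, axial_pitch = 3.9) {
  scan_protocol(n_scans = n_scans, scan_spacing = 5.9,
                lateral_pitch = lateral_pitch, axial_pitch = axial_pitch,
                field_width = 3000, n_averaged_frames = 7)
}

#' Classification parameters
#'
#' Tunable thresholds of the grading procedure. Defaults follow the manual
#' grading rules: granules span no more than three adjacent B-scans, outer
#' nuclear layer dots count only above 15 um diameter, the parafoveal region
#' of interest runs 500 to 1500 um temporal from the fovea center, and the
#' structural-to-angiographic scan match is trusted within +/- 1 B-scan.
#'
#' @param granule_max_scans maximum number of adjacent B-scans for a granule.
#' @param onl_min_diameter minimum axial diameter (um) for an ONL dot to count.
#' @param roi_inner,roi_outer parafoveal ROI bounds, um temporal from fovea.
#' @param alignment_tolerance_scans +/- scans searched around the mapped
#'   angiographic B-scan.
#' @param perfusion_overlap_fraction minimum fraction of an element's scans
#'   that must show an interior motion-contrast signal for a perfused call.
#' @param adjacency_window um around the element footprint searched for an
#'   adjacent (but not interior) motion signal.
#' @param contrast_threshold peak/background ratio above which a local
#'   maximum counts as a hyperreflective dot.
#' @return an object of class `classification_params`.
#' @export
classification_params <- function(granule_max_scans = 3,
                                  onl_min_diameter = 15,
                                  roi_inner = 500,
                                  roi_outer = 1500,
                                  alignment_tolerance_scans = 1,
                                  perfusion_overlap_fraction = 0.5,
                                  adjacency_window = 15,
                                  contrast_threshold = 1.5) {
  if (roi_inner >= roi_outer) stop("roi_inner must be < roi_outer")
  if (granule_max_scans < 1) stop("granule_max_scans must be >= 1")
  if (perfusion_overlap_fraction < 0 || perfusion_overlap_fraction > 1) {
    stop("perfusion_overlap_fraction must be in [0, 1]")
  }
  structure(list(
    granule_max_scans = as.integer(granule_max_scans),
    onl_min_diameter = onl_min_diameter,
    roi_inner = roi_inner,
    roi_outer = roi_outer,
    alignment_tolerance_scans = as.integer(alignment_tolerance_scans),
    perfusion_overlap_fraction = perfusion_overlap_fraction,
    adjacency_window = adjacency_window,
    contrast_threshold = contrast_threshold
  ), class = "classification_params")
}
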