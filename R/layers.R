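#' Retinal layer boundary model
#'
#' A smooth parametric model of the retinal layer interfaces that the
#' grading rules refer to: the inner edge of the inner plexiform layer
#' (IPL), the IPL/INL interface, the INL/OPL interface, the OPL/ONL
#' interface and the outer limit of the outer nuclear layer (ONL), plus an
#' inner-retina surface used only for rendering. Boundary depth (um from
#' the image top, increasing posteriorly) is a function of en-face position
#' `(lateral, scan-axis)` um relative to the fovea center.
#'
#' The model consists of a nearly flat outer retina, layer thicknesses that
#' taper toward a central foveal pit (the INL in particular thins at the
#' fovea), and a low-amplitude smooth undulation shared by all boundaries
#' with a smaller independent per-boundary ripple. Boundaries are strictly
#' ordered in depth at every position.
#'
#' @param base_onl_outer depth of the ONL outer limit away from the fovea, um.
#' @param onl_thickness,opl_thickness,inl_thickness,ipl_thickness,rnfl_thickness
#'   peripheral layer thicknesses, um.
#' @param pit_sigma Gaussian radius of the foveal pit, um.
#' @param pit_fraction_inl,pit_fraction_opl,pit_fraction_ipl fractional
#'   thinning of each inner layer at the pit center.
#' @param undulation_amp amplitude of the shared smooth depth undulation, um.
#' @param ripple_amp amplitude of the independent per-boundary ripple, um.
#' @param undulation_wavelength en-face wavelength of the undulation, um.
#' @param phases optional 2x7 matrix of phase offsets (filled from the RNG
#'   by [make_layer_geometry()]).
#' @param fovea_center en-face `(lateral, scan-axis)` position of the fovea, um.
#' @return an object of class `layer_model`.
#' @seealso [boundary_depth()], [make_layer_geometry()]
#' @export
layer_model <- function(base_onl_outer = 315,
                        onl_thickness = 85,
                        opl_thickness = 30,
                        inl_thickness = 40,
                        ipl_thickness = 40,
                        rnfl_thickness = 60,
                        pit_sigma = 350,
                        pit_fraction_inl = 0.7,
                        pit_fraction_opl = 0.5,
                        pit_fraction_ipl = 0.8,
                        undulation_amp = 2,
                        ripple_amp = 0.8,
                        undulation_wavelength = 750,
                        phases = matrix(0, 2, 7),
                        fovea_center = c(0, 0)) {
  m <- structure(list(
    base_onl_outer = base_onl_outer,
    onl_thickness = onl_thickness, opl_thickness = opl_thickness,
    inl_thickness = inl_thickness, ipl_thickness = ipl_thickness,
    rnfl_thickness = rnfl_thickness,
    pit_sigma = pit_sigma,
    pit_fraction_inl = pit_fraction_inl,
    pit_fraction_opl = pit_fraction_opl,
    pit_fraction_ipl = pit_fraction_ipl,
    undulation_amp = undulation_amp, ripple_amp = ripple_amp,
    undulation_wavelength = undulation_wavelength,
    phases = phases,
    fovea_center = as.numeric(fovea_center)
  ), class = "layer_model")
  m
}

LAYER_BOUNDARIES <- c("ilm", "ipl_inner", "ipl_inl", "inl_opl", "opl_onl", "onl_outer")

pit_factor <- function(model, x, y) {
  dx <- x - model$fovea_center[1]
  dy <- y - model$fovea_center[2]
  exp(-(dx^2 + dy^2) / (2 * model$pit_sigma^2))
}

undulation <- function(model, x, y, k) {
  lam <- model$undulation_wavelength
  ph <- model$phases
  shared <- model$undulation_amp *
    sin(2 * pi * (x / lam + ph[1, 1])) * sin(2 * pi * (y / (1.3 * lam) + ph[2, 1]))
  ripple <- model$ripple_amp *
    sin(2 * pi * (x / (0.8 * lam) + ph[1, k + 1])) *
    sin(2 * pi * (y / (1.1 * lam) + ph[2, k + 1]))
  shared + ripple
}

#' Evaluate a layer boundary at physical positions
#'
#' @param model a [layer_model()].
#' @param boundary one of `"ilm"`, `"ipl_inner"`, `"ipl_inl"`, `"inl_opl"`,
#'   `"opl_onl"`, `"onl_outer"`.
#' @param x,y en-face positions (lateral, scan-axis), um relative to the
#'   fovea center; vectors are recycled to a common length.
#' @return boundary depth in um from the image top.
#' @export
boundary_depth <- function(model, boundary, x, y) {
  boundary <- match.arg(boundary, LAYER_BOUNDARIES)
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  pf <- pit_factor(model, x, y)
  onl_outer <- model$base_onl_outer + undulation(model, x, y, 5)
  if (boundary == "onl_outer") return(onl_outer)
  opl_onl <- onl_outer - model$onl_thickness + undulation(model, x, y, 4)
  if (boundary == "opl_onl") return(opl_onl)
  inl_opl <- opl_onl - model$opl_thickness * (1 - model$pit_fraction_opl * pf) +
    undulation(model, x, y, 3)
  if (boundary == "inl_opl") return(inl_opl)
  ipl_inl <- inl_opl - model$inl_thickness * (1 - model$pit_fraction_inl * pf) +
    undulation(model, x, y, 2)
  if (boundary == "ipl_inl") return(ipl_inl)
  ipl_inner <- ipl_inl - model$ipl_thickness * (1 - model$pit_fraction_ipl * pf) +
    undulation(model, x, y, 1)
  if (boundary == "ipl_inner") return(ipl_inner)
  ipl_inner - model$rnfl_thickness * (1 - 0.9 * pf)
}

# All six boundaries at once, as a length(x)-row matrix.
boundary_matrix <- function(model, x, y) {
  vapply(LAYER_BOUNDARIES, function(b) boundary_depth(model, b, x, y),
         numeric(max(length(x), length(y))))
}

#' Materialize per-scan boundary curves for a stack
#'
#' Evaluates the boundary model on the pixel grid of a stack, returning for
#' each B-scan the boundary depth curves as a function of lateral position.
#'
#' @param model a [layer_model()].
#' @param stack a [bscan_stack()].
#' @return a list with one `n_lateral x 6` matrix per scan.
#' @export
layer_curves <- function(model, stack) {
  xs <- lateral_positions(stack)
  lapply(scan_positions(stack), function(y) boundary_matrix(model, xs, y))
}

#' @export
print.layer_model <- function(x, ...) {
  cat(sprintf("<layer_model> ONL outer at %.0f um, INL %.0f um thick peripherally, pit sigma %.0f um\n",
              x$base_onl_outer, x$inl_thickness, x$pit_sigma))
  invisible(x)
}

#' Write / read a layer model as JSON
#'
#' @param model a [layer_model()].
#' @param path JSON file path.
#' @return `read_layers` returns a [layer_model()]; `write_layers` returns
#'   `path` invisibly.
#' @export
write_layers <- function(model, path) {
  o <- unclass(model)
  o$phases <- as.numeric(o$phases)
  jsonlite::write_json(o, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_layers
#' @export
read_layers <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  o$phases <- matrix(o$phases, nrow = 2)
  do.call(layer_model, o)
}
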