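#' Run the full grading pipeline on a stack pair
#'
#' Speckle suppression, INL dot detection in the parafoveal region of
#' interest, linking into 3D elements, structural-to-angiographic
#' alignment, perfusion-based classification, and the ONL branch
#' (full-field detection, size/clearance filtering, linking), ending in a
#' per-subject grading summary.
#'
#' @param structural structural [bscan_stack()].
#' @param angio angiographic [bscan_stack()] with motion channel.
#' @param layers a [layer_model()] covering both stacks.
#' @param params a [classification_params()].
#' @param subject_id,group identifiers carried into the summary row.
#' @return a list with `inl_detections`, `elements`, `transform`,
#'   `classified`, `onl_detections`, `onl_elements`, `summary`.
#' @export
run_pipeline <- function(structural, angio, layers,
                         params = classification_params(),
                         subject_id = NA, group = NA) {
  sf <- suppress_background(structural)
  inl <- detect_dots(sf, layers, params, roi = "inl")
  els <- link_detections(inl, structural$protocol)
  tr <- align_stacks(structural, angio)
  cls <- classify_elements(els, angio, tr, params)
  onl <- filter_onl(detect_dots(sf, layers, params, roi = "onl"), params)
  onl_els <- link_detections(onl, structural$protocol)
  summ <- summarize_subject(cls, onl_els, structural$protocol, params,
                            subject_id = subject_id, group = group)
  list(inl_detections = inl, elements = els, transform = tr,
       classified = cls, onl_detections = onl, onl_elements = onl_els,
       summary = summ)
}

#' Score pipeline output against phantom ground truth
#'
#' Matches each planted inner-nuclear-layer object (granules and capillary
#' segments; branch children and superficial vessels are excluded) to the
#' recovered root elements by en-face and depth proximity and checks that
#' exactly one element recovered it with the correct shape class, final
#' perfusion class and location label.
#'
#' @param classified list of [classify_element()] results.
#' @param truth ground-truth data.frame from [plant_objects()].
#' @param protocol structural [scan_protocol()].
#' @param capture_radius um added to the object radius when testing whether
#'   a detection lies on the object.
#' @param min_capture_fraction fraction of an element's detections that
#'   must lie on an object for the element to be assigned to it.
#' @return a data.frame with one row per planted INL object: `id`, `kind`,
#'   `n_matched`, `shape_ok`, `class_ok`, `location_ok`, `recovered`.
#' @export
evaluate_recovery <- function(classified, truth, protocol,
                              capture_radius = 12,
                              min_capture_fraction = 0.5) {
  roots <- Filter(function(ce) is.na(ce$element$parent_id), classified)
  tgt <- truth[truth$kind %in% c("granule", "capillary") &
                 truth$layer_attachment != "ONL" &
                 is.na(truth$branch_of), , drop = FALSE]
  # fraction of each element's detections lying inside each object's
  # (dilated) capsule; every root is assigned to its best object
  capture <- function(ce, o) {
    d <- ce$element$detections
    ef <- enface_segment_dist(d$lateral, d$scan_um, o)
    d3 <- sqrt(ef^2 + (d$depth - o$z)^2)
    mean(d3 <= o$diameter / 2 + capture_radius)
  }
  assigned <- vapply(roots, function(ce) {
    sc <- vapply(seq_len(nrow(tgt)), function(k) capture(ce, tgt[k, ]), numeric(1))
    if (!length(sc) || max(sc) < min_capture_fraction) NA_integer_
    else which.max(sc)
  }, integer(1))
  res <- lapply(seq_len(nrow(tgt)), function(k) {
    o <- tgt[k, ]
    hits <- which(!is.na(assigned) & assigned == k)
    expected_shape <- if (o$kind == "granule") "granule" else "elongated"
    expected_class <- if (o$kind == "granule") "granule"
      else if (isTRUE(o$perfused)) "perfused_filiform" else "nonperfused_filiform"
    shape_ok <- length(hits) == 1 &&
      roots[[hits]]$shape_class == expected_shape
    class_ok <- length(hits) == 1 &&
      roots[[hits]]$final_class == expected_class
    loc_ok <- length(hits) == 1 &&
      roots[[hits]]$element$location == o$layer_attachment
    data.frame(id = o$id, kind = o$kind, n_matched = length(hits),
               shape_ok = shape_ok, class_ok = class_ok,
               location_ok = loc_ok,
               recovered = length(hits) == 1 && shape_ok && class_ok && loc_ok)
  })
  do.call(rbind, res)
}
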