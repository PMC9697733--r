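#' Build an element from linked detections
#'
#' An element is a 3D hyperreflective object: an ordered run of per-scan
#' detections on strictly consecutive B-scans. Its conservative transverse
#' extent is the inter-scan spacing times the number of adjacent-scan
#' transitions (`n_scans - 1`) -- a deliberate underestimate of the true
#' length, which could be nearly two spacings longer.
#'
#' @param detections data.frame of detections on consecutive scan indices.
#' @param id element id.
#' @param parent_id id of the parent element when this element is a branch
#'   child, else `NA`.
#' @return an object of class `hrdot_element`.
#' @export
new_element <- function(detections, id = 1L, parent_id = NA_integer_) {
  si <- detections$scan_index
  if (nrow(detections) > 1 && any(diff(si) != 1L)) {
    stop("element detections must occupy strictly consecutive scan indices")
  }
  loc <- element_location(detections)
  structure(list(
    id = as.integer(id),
    detections = detections,
    n_scans = nrow(detections),
    first_scan = si[1],
    mean_diameter = mean(detections$axial_diameter),
    location = loc,
    parent_id = as.integer(parent_id),
    branch_ids = integer(0)
  ), class = "hrdot_element")
}

element_location <- function(detections) {
  locs <- detections$location
  locs <- locs[!is.na(locs) & locs != "not_applicable"]
  if (!length(locs)) return("not_applicable")
  tab <- table(locs)
  best <- names(tab)[tab == max(tab)]
  if (length(best) == 1) return(best)
  # tie: label of the highest-contrast detection among the tied labels
  cand <- detections[detections$location %in% best, ]
  cand$location[which.max(cand$peak_contrast)]
}

#' @export
print.hrdot_element <- function(x, ...) {
  cat(sprintf("<element %d> %d scan(s) from scan %d, mean diameter %.1f um, location %s%s\n",
              x$id, x$n_scans, x$first_scan, x$mean_diameter, x$location,
              if (is.na(x$parent_id)) "" else sprintf(" (branch of %d)", x$parent_id)))
  invisible(x)
}

#' Link per-scan detections into 3D elements
#'
#' Greedy nearest-neighbour linking between consecutive B-scans, mirroring
#' the manual follow-the-dot procedure: a detection continues the element
#' whose last detection lies within the gating window (defaults: lateral
#' <= 20 um, depth <= 15 um). When one element has two in-gate candidates
#' on the next scan, the nearer candidate continues the element and the
#' nearest remaining one starts a branch child. Every detection belongs to
#' exactly one element; the result is deterministic for a given input
#' order, with distance ties broken by the smaller lateral position.
#'
#' @param detections a [detect_dots()] data.frame from a single stack and
#'   layer mode.
#' @param protocol the stack's [scan_protocol()].
#' @param gating `c(lateral_um, depth_um)` linking window.
#' @return a list of [new_element()] objects.
#' @export
link_detections <- function(detections, protocol, gating = c(20, 15)) {
  if (!nrow(detections)) return(list())
  uid <- attr(detections, "stack_uid")
  if (!is.null(uid) && length(unique(uid)) > 1) {
    stop("detections come from mixed stacks")
  }
  if (length(unique(detections$layer)) > 1) {
    stop("detections come from mixed layer modes")
  }
  det <- detections[order(detections$scan_index, detections$lateral), ]
  det$.row <- seq_len(nrow(det))
  scans <- sort(unique(det$scan_index))
  # open element bookkeeping: list of (id, parent, rows, last lateral/depth/scan)
  next_id <- 1L
  open <- list()
  closed <- list()
  assign_rows <- integer(nrow(det))   # element id per detection
  parent_of <- integer(0)

  start_element <- function(row, parent = NA_integer_) {
    e <- list(id = next_id, parent = parent, rows = row,
              lat = det$lateral[row], dep = det$depth[row],
              last_scan = det$scan_index[row])
    next_id <<- next_id + 1L
    e
  }

  for (s in scans) {
    rows_s <- which(det$scan_index == s)
    # elements still open on the previous scan
    active <- which(vapply(open, function(e) e$last_scan == s - 1L, logical(1)))
    matched_det <- rep(FALSE, length(rows_s))
    matched_el <- rep(FALSE, length(active))
    if (length(active) && length(rows_s)) {
      pairs <- expand.grid(ai = seq_along(active), di = seq_along(rows_s))
      e_lat <- vapply(open[active], `[[`, numeric(1), "lat")
      e_dep <- vapply(open[active], `[[`, numeric(1), "dep")
      dl <- abs(det$lateral[rows_s[pairs$di]] - e_lat[pairs$ai])
      dd <- abs(det$depth[rows_s[pairs$di]] - e_dep[pairs$ai])
      ok <- dl <= gating[1] & dd <= gating[2]
      pairs <- pairs[ok, , drop = FALSE]
      if (nrow(pairs)) {
        pairs$dist <- sqrt(dl[ok]^2 + dd[ok]^2)
        pairs$lat <- det$lateral[rows_s[pairs$di]]
        pairs <- pairs[order(pairs$dist, pairs$lat), , drop = FALSE]
        # greedy mutual assignment
        for (k in seq_len(nrow(pairs))) {
          ai <- pairs$ai[k]; di <- pairs$di[k]
          if (matched_el[ai] || matched_det[di]) next
          matched_el[ai] <- TRUE; matched_det[di] <- TRUE
          e <- open[[active[ai]]]
          row <- rows_s[di]
          e$rows <- c(e$rows, row)
          e$lat <- det$lateral[row]; e$dep <- det$depth[row]
          e$last_scan <- s
          open[[active[ai]]] <- e
        }
        # branch children: nearest remaining in-gate candidate of a
        # matched element starts a child element
        for (ai in which(matched_el)) {
          sub <- pairs[pairs$ai == ai & !matched_det[pairs$di], , drop = FALSE]
          if (!nrow(sub)) next
          di <- sub$di[1]
          matched_det[di] <- TRUE
          open[[length(open) + 1]] <- start_element(rows_s[di],
                                                    parent = open[[active[ai]]]$id)
        }
      }
    }
    # close elements that found no continuation
    stale <- which(vapply(open, function(e) e$last_scan < s, logical(1)))
    if (length(stale)) {
      closed <- c(closed, open[stale])
      open <- open[-stale]
    }
    # unmatched detections start new root elements
    for (di in which(!matched_det)) {
      open[[length(open) + 1]] <- start_element(rows_s[di])
    }
  }
  closed <- c(closed, open)
  # materialize, ordered by id
  closed <- closed[order(vapply(closed, `[[`, integer(1), "id"))]
  els <- lapply(closed, function(e) {
    new_element(det[e$rows, setdiff(names(det), ".row"), drop = FALSE],
                id = e$id, parent_id = e$parent)
  })
  # record branch ids on parents
  ids <- vapply(els, `[[`, integer(1), "id")
  for (e in els) {
    if (!is.na(e$parent_id)) {
      pi <- which(ids == e$parent_id)
      if (length(pi)) els[[pi]]$branch_ids <- c(els[[pi]]$branch_ids, e$id)
    }
  }
  els
}

#' Conservative transverse extent of an element
#'
#' The element length estimated as the inter-scan spacing times the number
#' of adjacent-scan transitions: `scan_spacing * (n_scans - 1)`. An element
#' first seen on one scan and followed through four more adjacent scans at
#' 11 um spacing therefore measures 44 um; a single-scan dot measures 0.
#'
#' @param element a [new_element()].
#' @param protocol the stack's [scan_protocol()].
#' @return extent in um.
#' @export
conservative_extent <- function(element, protocol) {
  protocol$scan_spacing * (element$n_scans - 1)
}

#' Classify the shape of an element
#'
#' Elements spanning up to, but no more than, `granule_max_scans` adjacent
#' B-scans (default three) are granules; elements spanning more are
#' elongated.
#'
#' @param element a [new_element()].
#' @param params a [classification_params()].
#' @return `"granule"` or `"elongated"`.
#' @export
classify_shape <- function(element, params = classification_params()) {
  if (element$n_scans <= params$granule_max_scans) "granule" else "elongated"
}

#' Tabulate elements
#'
#' @param elements list of [new_element()] objects.
#' @param protocol the stack's [scan_protocol()].
#' @param params a [classification_params()].
#' @return a data.frame with one row per element: `id`, `first_scan`,
#'   `n_scans`, `extent_um`, `mean_diameter_um`, `shape_class`, `location`,
#'   `parent_id`.
#' @export
elements_table <- function(elements, protocol, params = classification_params()) {
  if (!length(elements)) {
    return(data.frame(id = integer(0), first_scan = integer(0),
                      n_scans = integer(0), extent_um = numeric(0),
                      mean_diameter_um = numeric(0), shape_class = character(0),
                      location = character(0), parent_id = integer(0)))
  }
  data.frame(
    id = vapply(elements, `[[`, integer(1), "id"),
    first_scan = vapply(elements, `[[`, integer(1), "first_scan"),
    n_scans = vapply(elements, `[[`, integer(1), "n_scans"),
    extent_um = vapply(elements, conservative_extent, numeric(1), protocol = protocol),
    mean_diameter_um = vapply(elements, `[[`, numeric(1), "mean_diameter"),
    shape_class = vapply(elements, classify_shape, character(1), params = params),
    location = vapply(elements, `[[`, character(1), "location"),
    parent_id = vapply(elements, `[[`, integer(1), "parent_id")
  )
}
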