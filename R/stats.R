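#' Group median
#'
#' Median with the grading convention for absent values: an even-count
#' median is the midpoint of the two central order statistics, and absent
#' markers (`NA`) are replaced by 0 when `absent_as_zero` is set -- the
#' convention used for the ONL transverse-dimension summaries, where
#' subjects without ONL dots contribute 0.
#'
#' @param values numeric vector, possibly with `NA` absent markers.
#' @param absent_as_zero replace `NA` by 0 before taking the median.
#' @return the median.
#' @export
group_median <- function(values, absent_as_zero = FALSE) {
  if (absent_as_zero) values[is.na(values)] <- 0
  if (!length(values) || any(is.na(values))) {
    stop("group_median needs at least one value and no unresolved absent markers")
  }
  stats::median(values)
}

#' Two-sided unpaired Wilcoxon rank-sum test
#'
#' Rank-sum (Mann-Whitney) test with mid-ranks for ties. The exact null
#' distribution is used when the combined sample size is at most 20 and
#' there are no ties; otherwise a normal approximation with tie-corrected
#' variance is used (no continuity correction). When the tie-corrected
#' variance is zero (all pooled values identical) the p-value is 1.
#'
#' @param group_a,group_b numeric vectors (each non-empty).
#' @return list with `statistic` (the Mann-Whitney U of `group_a`),
#'   `p.value`, and `exact` (logical, which path was taken).
#' @export
wilcoxon_rank_sum <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  na <- length(group_a); nb <- length(group_b)
  pooled <- c(group_a, group_b)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  if (na + nb <= 20 && !ties) {
    p <- if (U > na * nb / 2) {
      1 - stats::pwilcox(U - 1, na, nb)
    } else {
      stats::pwilcox(U, na, nb)
    }
    return(list(statistic = U, p.value = min(2 * p, 1), exact = TRUE))
  }
  N <- na + nb
  tie_tab <- table(pooled)
  sig2 <- (na * nb / 12) * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  if (sig2 <= 0) return(list(statistic = U, p.value = 1, exact = FALSE))
  z <- (U - na * nb / 2) / sqrt(sig2)
  list(statistic = U, p.value = min(2 * stats::pnorm(-abs(z)), 1), exact = FALSE)
}

#' Per-subject grading summary
#'
#' Tallies one subject's classified INL elements and filtered ONL elements
#' into a grading row: INL dot count, granule and elongated counts, mean
#' conservative extent of the elongated elements, location tallies with
#' integer percentages (rounded half away from zero over the INL dot
#' count), final-class tallies, ONL dot count and mean ONL extent (absent,
#' `NA`, when there are no ONL dots). Branch children are counted as part
#' of their parent: only root elements are tallied.
#'
#' @param classified list of [classify_element()] results for the INL.
#' @param onl_elements list of [new_element()] objects for the ONL (after
#'   [filter_onl()] and linking).
#' @param protocol structural [scan_protocol()].
#' @param params a [classification_params()].
#' @param subject_id,group identifiers carried into the row.
#' @return a one-row data.frame of class `subject_summary`.
#' @export
summarize_subject <- function(classified, onl_elements = list(),
                              protocol, params = classification_params(),
                              subject_id = NA, group = NA) {
  roots <- Filter(function(ce) is.na(ce$element$parent_id), classified)
  shapes <- vapply(roots, `[[`, character(1), "shape_class")
  finals <- vapply(roots, `[[`, character(1), "final_class")
  locs <- vapply(roots, function(ce) ce$element$location, character(1))
  exts <- vapply(roots, function(ce) conservative_extent(ce$element, protocol),
                 numeric(1))
  n <- length(roots)
  n_gran <- sum(shapes == "granule")
  n_elon <- sum(shapes == "elongated")
  loc_counts <- vapply(c("near_IPL", "inside_INL", "near_OPL"),
                       function(l) sum(locs == l), numeric(1))
  loc_pct <- if (n > 0) round_half_up(100 * loc_counts / n) else rep(0, 3)
  onl_roots <- Filter(function(e) is.na(e$parent_id), onl_elements)
  n_onl <- length(onl_roots)
  onl_ext <- if (n_onl > 0) {
    mean(vapply(onl_roots, conservative_extent, numeric(1), protocol = protocol))
  } else NA_real_
  out <- data.frame(
    subject_id = subject_id, group = group,
    inl_dots = n, granules = n_gran, elongated = n_elon,
    elongated_extent_mean = if (n_elon > 0) mean(exts[shapes == "elongated"]) else NA_real_,
    near_ipl = loc_counts[1], near_ipl_pct = loc_pct[1],
    inside_inl = loc_counts[2], inside_inl_pct = loc_pct[2],
    near_opl = loc_counts[3], near_opl_pct = loc_pct[3],
    class_granule = sum(finals == "granule"),
    class_perfused = sum(finals == "perfused_filiform"),
    class_nonperfused = sum(finals == "nonperfused_filiform"),
    class_unclassifiable = sum(finals == "unclassifiable"),
    onl_dots = n_onl, onl_extent_mean = onl_ext
  )
  rownames(out) <- NULL
  class(out) <- c("subject_summary", class(out))
  out
}

#' Recompute the grading-table medians from the packaged fixture
#'
#' Recomputes every group-median cell of the packaged per-subject grading
#' table -- INL dot counts, granule and elongated counts, mean elongated
#' extents, the three location tallies, ONL dot counts and mean ONL
#' extents (absent-as-zero) -- and compares each against the printed
#' median.
#'
#' @param fixture the per-subject table (defaults to [table2_fixture()]).
#' @return a data.frame with columns `row`, `group`, `computed`, `printed`,
#'   `match`.
#' @examples
#' rep <- reproduce_table2()
#' all(rep$match)
#' @export
reproduce_table2 <- function(fixture = table2_fixture()) {
  printed <- table2_printed_medians()
  printed$computed <- NA_real_
  for (k in seq_len(nrow(printed))) {
    vals <- fixture[fixture$group == printed$group[k], printed$row[k]]
    printed$computed[k] <- group_median(vals,
                                        absent_as_zero = printed$row[k] == "onl_extent_mean")
  }
  printed$match <- printed$computed == printed$printed
  printed[, c("row", "group", "computed", "printed", "match")]
}
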