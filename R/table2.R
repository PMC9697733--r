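#' Packaged per-subject grading table
#'
#' The per-subject hyperreflective-dot grading values for the 8 diabetic
#' patients (subjects 1-8) and 8 healthy controls (subjects 9-16) that ship
#' with the package: inner nuclear layer (INL) dot counts on the graded
#' transfoveal B-scan, granule and elongated-element counts, mean transverse
#' dimension of the elongated elements, location tallies with their printed
#' integer percentages, outer nuclear layer (ONL) dot counts over the full
#' 131-scan block, and mean ONL transverse dimensions. Subjects with no ONL
#' dots have no ONL transverse dimension; that absent value is stored as
#' `NA` (printed as "-" in the source table).
#'
#' @return a data.frame with one row per subject, columns
#'   `subject_id`, `group` (`"patient"`/`"control"`), `inl_dots`,
#'   `granules`, `elongated`, `elongated_extent_mean`, `near_ipl`,
#'   `near_ipl_pct`, `inside_inl`, `inside_inl_pct`, `near_opl`,
#'   `near_opl_pct`, `onl_dots`, `onl_extent_mean`.
#' @examples
#' fx <- table2_fixture()
#' sum(fx$inl_dots[fx$group == "patient"])  # 105
#' @export
table2_fixture <- function() {
  data.frame(
    subject_id = 1:16,
    group = rep(c("patient", "control"), each = 8),
    inl_dots = c(18, 14, 13, 13, 7, 13, 12, 15,
                 13, 8, 16, 11, 13, 6, 8, 7),
    granules = c(5, 2, 3, 4, 0, 6, 2, 3,
                 2, 0, 7, 0, 0, 2, 3, 6),
    elongated = c(13, 12, 10, 9, 7, 7, 10, 12,
                  11, 8, 9, 11, 13, 4, 5, 1),
    elongated_extent_mean = c(59, 79, 51, 67, 115, 63, 183, 82,
                              128, 87, 76, 180, 121, 58, 62, 66),
    near_ipl = c(7, 6, 6, 4, 2, 2, 1, 6,
                 4, 0, 3, 2, 4, 0, 3, 3),
    near_ipl_pct = c(39, 43, 46, 31, 29, 15, 8, 40,
                     31, 0, 19, 18, 31, 0, 38, 43),
    inside_inl = c(3, 0, 1, 4, 0, 7, 3, 7,
                   0, 1, 1, 0, 0, 1, 0, 0),
    inside_inl_pct = c(17, 0, 8, 31, 0, 54, 25, 47,
                       0, 13, 6, 0, 0, 17, 0, 0),
    near_opl = c(8, 8, 6, 5, 5, 4, 8, 2,
                 9, 7, 12, 9, 9, 5, 5, 4),
    near_opl_pct = c(44, 57, 46, 38, 71, 31, 67, 13,
                     69, 88, 75, 82, 69, 83, 63, 57),
    onl_dots = c(2, 0, 11, 2, 2, 4, 1, 3,
                 0, 0, 0, 3, 1, 0, 1, 1),
    onl_extent_mean = c(11, NA, 24, 39, 11, 30, 22, 29,
                        NA, NA, NA, 11, 22, NA, 22, 33)
  )
}

# Printed group medians of the grading table, used by reproduce_table2()
# as the comparison column. ONL extent medians use the absent-as-zero
# convention.
table2_printed_medians <- function() {
  data.frame(
    row = rep(c("inl_dots", "granules", "elongated", "elongated_extent_mean",
                "near_ipl", "inside_inl", "near_opl",
                "onl_dots", "onl_extent_mean"), each = 2),
    group = rep(c("patient", "control"), times = 9),
    printed = c(13, 9.5,
                3, 2,
                10, 8.5,
                73, 81.5,
                5, 3,
                3, 0,
                5.5, 8,
                2, 0.5,
                23, 5.5)
  )
}
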