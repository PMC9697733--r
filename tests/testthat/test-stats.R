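test_that("group medians follow the grading conventions", {
  # printed group medians of the dot counts
  expect_equal(group_median(c(18, 14, 13, 13, 7, 13, 12, 15)), 13)
  expect_equal(group_median(c(13, 8, 16, 11, 13, 6, 8, 7)), 9.5)
  # absent-as-zero: healthy ONL transverse dimensions
  expect_equal(group_median(c(NA, NA, NA, 11, 22, NA, 22, 33),
                            absent_as_zero = TRUE), 5.5)
  expect_error(group_median(numeric(0)), "at least one")
  expect_error(group_median(c(1, NA)), "absent")
})

test_that("group_median agrees with a sort-based oracle on random input", {
  set.seed(101)
  for (i in 1:1000) {
    v <- round(stats::rnorm(sample(1:12, 1), 10, 5), 2)
    expect_identical(group_median(v), sort_median(v))
  }
})

test_that("rank-sum test: exact path, ties, and invariances", {
  # frozen example computed by full enumeration: all 70 assignments of 8
  # ranks to two groups of 4; both extreme orderings give 2/70
  w <- wilcoxon_rank_sum(1:4, 10:13)
  expect_true(w$exact)
  expect_equal(w$p.value, 2 / 70)
  expect_equal(w$p.value, enum_wilcox_p(1:4, 10:13))
  # identical groups: full ties, zero variance, p = 1
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  expect_equal(wilcoxon_rank_sum(rep(5, 4), rep(5, 3))$p.value, 1)
  # the statistic is invariant under strictly monotone transforms
  a <- c(0.3, 2.5, 7, 11); b <- c(1, 4, 9)
  expect_equal(wilcoxon_rank_sum(a, b)$statistic,
               wilcoxon_rank_sum(exp(a), exp(b))$statistic)
  expect_equal(wilcoxon_rank_sum(a, b)$p.value,
               wilcoxon_rank_sum(log(a + 1), log(b + 1))$p.value)
})

test_that("exact rank-sum path matches brute-force enumeration for n <= 10", {
  set.seed(77)
  for (na in 1:5) {
    for (nb in na:(10 - na)) {
      for (rep in 1:3) {
        pooled <- sample(seq_len(50), na + nb)  # tie-free
        a <- pooled[seq_len(na)]; b <- pooled[-seq_len(na)]
        w <- wilcoxon_rank_sum(a, b)
        expect_true(w$exact)
        expect_equal(w$p.value, enum_wilcox_p(a, b),
                     label = sprintf("na=%d nb=%d", na, nb))
      }
    }
  }
})

test_that("tied data fall back to the tie-corrected normal approximation", {
  a <- c(1, 2, 2, 3, 5, 5, 6, 8, 9, 9, 11)
  b <- c(2, 3, 3, 5, 7, 7, 8, 10, 10, 12, 13)
  w <- wilcoxon_rank_sum(a, b)
  expect_false(w$exact)
  ref <- suppressWarnings(stats::wilcox.test(a, b, correct = FALSE, exact = FALSE))
  expect_equal(w$p.value, ref$p.value, tolerance = 1e-10)
  expect_equal(unname(w$statistic), unname(ref$statistic))
})

test_that("subject summaries tally classes, locations and extents", {
  p <- fake_protocol()
  params <- classification_params()
  mk_ce <- function(scans, loc, final, parent = NA_integer_, id = 1L) {
    e <- new_element(fake_detections(scans, location = loc), id = id,
                     parent_id = parent)
    structure(list(element = e, shape_class = classify_shape(e, params),
                   final_class = final, motion_overlap_fraction = 0,
                   adjacent_signal = FALSE, projection_risk = FALSE,
                   retrievable = TRUE), class = "classified_element")
  }
  cls <- list(
    mk_ce(1:6, "near_OPL", "perfused_filiform", id = 1L),
    mk_ce(10:11, "near_IPL", "granule", id = 2L),
    mk_ce(20:28, "near_OPL", "nonperfused_filiform", id = 3L),
    mk_ce(40:44, "inside_INL", "perfused_filiform", id = 4L),
    # branch child: folded into its parent, not counted
    mk_ce(21:22, "near_OPL", "granule", parent = 3L, id = 5L)
  )
  onl <- list(new_element(fake_detections(5:6, layer = "ONL",
                                          location = "not_applicable"), id = 1L))
  s <- summarize_subject(cls, onl, p, params, subject_id = 1, group = "patient")
  expect_equal(s$inl_dots, 4)
  expect_equal(s$granules, 1)
  expect_equal(s$elongated, 3)
  expect_equal(s$granules + s$elongated, s$inl_dots)
  expect_equal(s$elongated_extent_mean, mean(c(55, 88, 44)))
  expect_equal(s$near_opl, 2); expect_equal(s$near_opl_pct, 50)
  expect_equal(s$near_ipl_pct, 25); expect_equal(s$inside_inl_pct, 25)
  expect_equal(s$class_perfused, 2)
  expect_equal(s$class_nonperfused, 1)
  expect_equal(s$onl_dots, 1)
  expect_equal(s$onl_extent_mean, 11)
  # no elements at all: zero counts and absent extents
  s0 <- summarize_subject(list(), list(), p, params)
  expect_equal(s0$inl_dots, 0)
  expect_true(is.na(s0$onl_extent_mean))
  # percentage rounding is half away from zero
  expect_equal(round_half_up(c(37.5, 12.5, -2.5, 38.46)), c(38, 13, -3, 38))
})

test_that("fixture-derived per-subject rows reproduce printed cells", {
  fx <- table2_fixture()
  # patient 1: granules 5, elongated 13, total 18
  r1 <- fx[fx$subject_id == 1, ]
  expect_equal(r1$granules, 5)
  expect_equal(r1$elongated, 13)
  expect_equal(r1$inl_dots, 18)
  # patient 7: 1 of 12 near the IPL prints as 8%
  r7 <- fx[fx$subject_id == 7, ]
  expect_equal(round_half_up(100 * r7$near_ipl / r7$inl_dots), 8)
})
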