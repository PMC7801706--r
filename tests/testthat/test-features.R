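labels_from_string <- function(s, rate = 500) {
  new_labels(match(strsplit(s, "")[[1]], MS_CLASSES), rate_hz = rate)
}

test_that("run-length segmentation tiles the epoch and flags truncation", {
  seg <- extract_segments(labels_from_string("AABBBA"))
  expect_equal(seg$class, c("A", "B", "A"))
  expect_equal(seg$length, c(2L, 3L, 1L))
  expect_equal(seg$truncated, c(TRUE, FALSE, TRUE))
  expect_equal(sum(seg$length), attr(seg, "n_samples"))
  # constant sequence: one run covering the epoch
  seg1 <- extract_segments(labels_from_string("CCCC"))
  expect_equal(nrow(seg1), 1L)
  expect_true(all(seg1$truncated))
  # alternating: n runs of length 1
  segn <- extract_segments(labels_from_string("ABABAB"))
  expect_equal(segn$length, rep(1L, 6L))
  # runs tile exactly: starts are cumulative
  expect_equal(seg$start, c(1L, 3L, 6L))
})

test_that("the 18 microstate features match hand evaluation", {
  # 2-s epoch at 500 Hz; class A = two interior runs of 50 samples
  lab <- c(rep(2L, 100), rep(1L, 50), rep(3L, 300), rep(1L, 50),
           rep(4L, 400), rep(3L, 100))
  seg <- extract_segments(new_labels(lab, rate_hz = 500))
  fv <- microstate_features(seg, gfp = rep(2, 1000))
  expect_equal(unname(fv["duration_A"]), 100)     # 50 samples = 100 ms
  expect_equal(unname(fv["occurrence_A"]), 1)     # 2 runs / 2 s
  expect_equal(unname(fv["coverage_A"]), 10)      # 100 / 1000 samples
  # coverages always sum to 100
  expect_equal(sum(fv[paste0("coverage_", MS_CLASSES)]), 100, tolerance = 1e-9)
  # constant GFP propagates to every present class
  expect_equal(unname(fv[paste0("gfp_", MS_CLASSES)]), rep(2, 4))
  # mean_occurrence equals the sum of per-class occurrences exactly
  expect_identical(unname(fv["mean_occurrence"]),
                   sum(fv[paste0("occurrence_", MS_CLASSES)]))
  # degenerate: single-class epoch
  seg1 <- extract_segments(new_labels(rep(3L, 1000), rate_hz = 500))
  fv1 <- microstate_features(seg1)
  expect_equal(unname(fv1["coverage_C"]), 100)
  expect_equal(unname(fv1[c("occurrence_A", "coverage_A")]), c(0, 0))
  expect_true(is.na(fv1["duration_A"]))
  expect_true("A" %in% attr(fv1, "missing"))
  expect_error(microstate_features(structure(data.frame(), class = c("ms_segments", "data.frame"))),
               "empty")
})

test_that("transition percentages count run boundaries", {
  seg <- extract_segments(labels_from_string("ABAC"))
  tp <- transition_percentages(seg)
  expect_equal(unname(tp[c("t_A_B", "t_B_A", "t_A_C")]),
               rep(100 / 3, 3), tolerance = 1e-9)
  expect_equal(sum(tp), 100, tolerance = 1e-9)
  # periodic ABAB...
  tp2 <- transition_percentages(extract_segments(labels_from_string("ABABABAB")))
  expect_equal(unname(tp2[c("t_A_B", "t_B_A")]), c(4 / 7, 3 / 7) * 100)
  # single run: zeros with the no-transition flag
  tp3 <- transition_percentages(extract_segments(labels_from_string("AAAA")))
  expect_true(all(tp3 == 0))
  expect_true(attr(tp3, "no_transition"))
})

test_that("directional predominance is antisymmetric and ordered", {
  seg <- extract_segments(labels_from_string("ABACDBDC"))
  tp <- transition_percentages(seg)
  dp <- directional_predominance(tp)
  expect_named(dp, c("dp_A_B", "dp_A_C", "dp_A_D", "dp_B_C", "dp_B_D", "dp_C_D"))
  expect_equal(unname(dp["dp_A_C"]),
               unname(tp["t_A_C"] - tp["t_C_A"]))
  # symmetric transitions -> all zero (odd run count: equal boundary counts)
  dps <- directional_predominance(
    transition_percentages(extract_segments(labels_from_string("ABABABA"))))
  expect_equal(unname(dps), rep(0, 6))
  # time reversal negates every difference
  rev_lab <- labels_from_string(paste(rev(strsplit("ABACDBDC", "")[[1]]), collapse = ""))
  dpr <- directional_predominance(
    transition_percentages(extract_segments(rev_lab)))
  expect_equal(unname(dpr), -unname(dp))
})

test_that("feature vectors have the fixed 36-name schema and imputation policy", {
  b <- make_test_epoch(seed = 61)
  fv <- epoch_feature_vector(b$labels, compute_gfp(b$rec))
  expect_length(fv, 36L)
  expect_identical(names(fv), microstatr:::FEATURE_NAMES)
  # names survive a CSV round-trip
  f <- file.path(tempdir(), "fv.csv")
  utils::write.csv(t(fv), f, row.names = FALSE)
  expect_identical(names(utils::read.csv(f, check.names = FALSE)),
                   microstatr:::FEATURE_NAMES)
  # epoch lacking a class: duration imputed to 0 and recorded
  lab <- labels_from_string(paste(rep("ACDACD", 20), collapse = ""))
  fv2 <- epoch_feature_vector(lab)
  expect_equal(unname(fv2["duration_B"]), 0)
  expect_true("duration_B" %in% attr(fv2, "imputed"))
})

test_that("coverage, occurrence and duration satisfy the consistency identity", {
  tr <- microstate_truth(seed = 62)
  # symmetric boundary handling: the identity coverage = occ x dur / 10
  # (%, Hz, ms) is exact for every class present in interior runs
  for (i in 1:10) {
    lab <- generate_state_sequence(tr, 1000, 500, seed = 100 + i)
    seg <- extract_segments(lab)
    fv <- microstate_features(seg, boundary = "symmetric")
    for (k in MS_CLASSES) {
      dur <- fv[paste0("duration_", k)]
      occ <- fv[paste0("occurrence_", k)]
      cov <- fv[paste0("coverage_", k)]
      if (!is.na(dur)) {
        expect_equal(unname(cov), unname(occ * dur / 10), tolerance = 1e-9)
      }
    }
    expect_equal(sum(fv[paste0("coverage_", MS_CLASSES)]), 100, tolerance = 1e-9)
  }
  # default boundary policy: truncation bias vanishes on long stretches
  lab_long <- generate_state_sequence(tr, 30000, 500, seed = 200)
  fvl <- microstate_features(extract_segments(lab_long))
  for (k in MS_CLASSES) {
    expect_equal(unname(fvl[paste0("coverage_", k)]),
                 unname(fvl[paste0("occurrence_", k)] *
                          fvl[paste0("duration_", k)] / 10),
                 tolerance = 0.02)
  }
})

test_that("the asymmetry permutation test flags cyclic chains and accepts symmetry", {
  # strictly cyclic A->B->C->D->A...
  lab <- labels_from_string(paste(rep("ABCD", 100), collapse = ""))
  seg <- extract_segments(lab)
  for (pair in list(c("A", "B"), c("B", "C"), c("C", "D"))) {
    r <- permutation_test_asymmetry(seg, pair, n_permutations = 2000, seed = 5)
    expect_lte(r$p_value, 0.001)
  }
  # observed difference 0 -> p = 1 within resolution
  seg0 <- extract_segments(labels_from_string(
    paste(c(rep("AB", 50), "A"), collapse = "")))
  r0 <- permutation_test_asymmetry(seg0, c("A", "B"), n_permutations = 500, seed = 6)
  expect_gt(r0$p_value, 0.9)
  # degenerate single run
  r1 <- permutation_test_asymmetry(extract_segments(labels_from_string("AAA")),
                                   c("A", "B"))
  expect_true(is.na(r1$p_value))
})
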