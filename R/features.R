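#' Run-length segmentation of a label sequence
#'
#' Maximal constant runs in temporal order. The first and last runs are
#' flagged as boundary-truncated: their true dwell extends past the epoch
#' window, so duration averages exclude them.
#'
#' @param labels An `ms_labels` or integer/character vector.
#' @param rate_hz Sampling rate, required for a bare vector.
#' @param classes Class names (default A-D), required for a bare integer vector.
#' @return Object of class `ms_segments`: data.frame with `class`, `start`,
#'   `length`, `truncated`; attributes `rate_hz`, `n_samples`, `classes`.
#' @export
extract_segments <- function(labels, rate_hz = NULL, classes = MS_CLASSES) {
  if (inherits(labels, "ms_labels")) {
    rate_hz <- labels$rate_hz
    classes <- labels$classes
    labels <- labels$labels
  }
  if (is.character(labels)) labels <- match(labels, classes)
  stopifnot(length(labels) >= 1L, !is.null(rate_hz))
  r <- rle(as.integer(labels))
  n_runs <- length(r$lengths)
  seg <- data.frame(
    class = classes[r$values],
    start = cumsum(c(1L, r$lengths[-n_runs])),
    length = r$lengths,
    truncated = seq_len(n_runs) %in% c(1L, n_runs)
  )
  structure(seg, class = c("ms_segments", "data.frame"),
            rate_hz = rate_hz, n_samples = sum(r$lengths), classes = classes)
}

#' The 18 per-epoch microstate features
#'
#' Per class k in A-D: `duration_k` the mean dwell in ms over non-truncated
#' runs of k (NA when k has no interior run), `occurrence_k` the number of
#' runs of k starting in the epoch per second (Hz), `coverage_k` the
#' percentage of samples labelled k, `gfp_k` the mean GFP over those samples.
#' Across classes: `mean_duration` over all non-truncated runs and
#' `mean_occurrence` = total run starts per second (so it equals the sum of
#' the four occurrences exactly).
#'
#' @param segments An `ms_segments`.
#' @param gfp A `gfp_series` aligned sample-wise with the labels (optional;
#'   GFP features are NA without it).
#' @param boundary Handling of the truncated first/last runs.
#'   `"duration_only"` (default): they are excluded from duration means but
#'   still counted in coverage and occurrence (a run occurs if it starts in
#'   the epoch). `"symmetric"`: they are excluded from coverage and
#'   occurrence as well (denominators restricted to interior samples), which
#'   makes the identity `coverage_k = occurrence_k * duration_k / 10` exact.
#' @return Named numeric vector of length 18, with attribute `missing` naming
#'   classes absent from interior runs.
#' @export
microstate_features <- function(segments, gfp = NULL,
                                boundary = c("duration_only", "symmetric")) {
  stopifnot(inherits(segments, "ms_segments"))
  boundary <- match.arg(boundary)
  if (nrow(segments) == 0L) stop("empty segment list", call. = FALSE)
  classes <- attr(segments, "classes")
  rate <- attr(segments, "rate_hz")
  n_samples <- attr(segments, "n_samples")
  gv <- if (!is.null(gfp)) { if (inherits(gfp, "gfp_series")) gfp$values else as.numeric(gfp) }
  if (!is.null(gv)) stopifnot(length(gv) == n_samples)

  interior <- segments[!segments$truncated, , drop = FALSE]
  counted <- if (boundary == "symmetric" && nrow(interior)) interior else segments
  denom_samples <- sum(counted$length)
  epoch_s <- denom_samples / rate
  dur <- occ <- cov <- gfpk <- stats::setNames(numeric(length(classes)), classes)
  lab_per_sample <- rep.int(match(segments$class, classes), segments$length)
  for (i in seq_along(classes)) {
    k <- classes[i]
    runs_k <- interior$length[interior$class == k]
    dur[i] <- if (length(runs_k)) mean(runs_k) / rate * 1000 else NA_real_
    occ[i] <- sum(counted$class == k) / epoch_s
    cov[i] <- sum(counted$length[counted$class == k]) / denom_samples * 100
    gfpk[i] <- if (!is.null(gv) && any(lab_per_sample == i)) {
      mean(gv[lab_per_sample == i])
    } else NA_real_
  }
  mean_duration <- if (nrow(interior)) mean(interior$length) / rate * 1000 else NA_real_
  mean_occurrence <- nrow(counted) / epoch_s
  out <- c(stats::setNames(dur, paste0("duration_", classes)),
           mean_duration = mean_duration,
           stats::setNames(occ, paste0("occurrence_", classes)),
           mean_occurrence = mean_occurrence,
           stats::setNames(cov, paste0("coverage_", classes)),
           stats::setNames(gfpk, paste0("gfp_", classes)))
  attr(out, "missing") <- classes[is.na(dur)]
  out
}

#' Transition percentages for the 12 ordered class pairs
#'
#' For each ordered pair (X, Y), X != Y: the percentage of adjacent run
#' boundaries that go X to Y. Sums to 100 when at least one boundary exists;
#' a single-run epoch yields all zeros with attribute `no_transition = TRUE`.
#'
#' @param segments An `ms_segments`.
#' @return Named numeric vector of length 12 (`t_A_B`, `t_A_C`, ...).
#' @export
transition_percentages <- function(segments) {
  stopifnot(inherits(segments, "ms_segments"))
  classes <- attr(segments, "classes")
  pairs <- ordered_pairs(classes)
  nm <- vapply(pairs, function(p) paste0("t_", p[1], "_", p[2]), "")
  out <- stats::setNames(numeric(length(pairs)), nm)
  n_runs <- nrow(segments)
  if (n_runs < 2L) {
    attr(out, "no_transition") <- TRUE
    return(out)
  }
  from <- segments$class[-n_runs]
  to <- segments$class[-1L]
  for (i in seq_along(pairs)) {
    out[i] <- sum(from == pairs[[i]][1] & to == pairs[[i]][2])
  }
  out <- out / (n_runs - 1L) * 100
  attr(out, "no_transition") <- FALSE
  out
}

#' Directional predominance of the six microstate pairs
#'
#' For each unordered pair \{X, Y\} in the fixed order (A,B), (A,C), (A,D),
#' (B,C), (B,D), (C,D): `P(X->Y) - P(Y->X)` in percentage points, the
#' asymmetry of the transition between the two directions.
#'
#' @param transitions The 12 ordered percentages from
#'   [transition_percentages()].
#' @return Named numeric vector of length 6 (`dp_A_B`, ...).
#' @export
directional_predominance <- function(transitions) {
  pairs <- unordered_pairs(MS_CLASSES)
  out <- vapply(pairs, function(p) {
    unname(transitions[paste0("t_", p[1], "_", p[2])] -
           transitions[paste0("t_", p[2], "_", p[1])])
  }, 0)
  names(out) <- vapply(pairs, function(p) paste0("dp_", p[1], "_", p[2]), "")
  out
}

# Predominance of one pair from a run-class integer vector, counting only
# boundaries between differing adjacent runs (shuffles can merge runs).
pair_predominance <- function(cls, xi, yi) {
  n <- length(cls)
  from <- cls[-n]
  to <- cls[-1L]
  nb <- sum(from != to)
  if (nb == 0L) return(0)
  (sum(from == xi & to == yi) - sum(from == yi & to == xi)) / nb * 100
}

# Studentized asymmetry of one pair: (N_xy - N_yx) / sqrt(N_xy + N_yx), the
# binomial-style z for the two transition directions. Pivotal under both the
# sequence law (direction counts are binomial-like given the pair total) and
# the shuffle null, which makes the permutation test calibrate even though
# shuffling changes the total boundary count.
pair_asymmetry_z <- function(cls, xi, yi) {
  n <- length(cls)
  from <- cls[-n]
  to <- cls[-1L]
  a <- sum(from == xi & to == yi)
  b <- sum(from == yi & to == xi)
  if (a + b == 0L) return(0)
  (a - b) / sqrt(a + b)
}

#' Permutation test for transition asymmetry of one pair
#'
#' Tests the observed directional predominance of a pair against a null built
#' by uniformly shuffling the order of the runs (run lengths stay attached to
#' their classes; per-class run counts are preserved, sequence order is
#' destroyed) and recomputing the asymmetry each shuffle. The test statistic
#' is the studentized count difference
#' `(N_xy - N_yx) / sqrt(N_xy + N_yx)`: shuffling merges some adjacent runs
#' and so changes the boundary total, and the raw percentage difference is
#' not pivotal across that change, while the studentized form is (the
#' direction split behaves binomially given the pair total in both worlds).
#' Two-sided add-one p-value:
#' `p = (1 + #{|null| >= |observed|}) / (n_permutations + 1)`.
#' The analytic independence expectation of the asymmetry under the shuffle
#' null is zero by symmetry; the realized null mean is reported alongside for
#' comparison.
#'
#' @param segments An `ms_segments` with >= 2 runs.
#' @param pair Length-2 character vector, e.g. `c("A", "B")`.
#' @param n_permutations Number of shuffles (default 10000).
#' @param seed Integer seed.
#' @return List with `p_value`, `observed` (predominance in percentage
#'   points), `observed_z` (the studentized statistic actually permuted),
#'   `null_mean` (of the studentized statistic).
#' @export
permutation_test_asymmetry <- function(segments, pair, n_permutations = 10000,
                                       seed = NULL) {
  stopifnot(inherits(segments, "ms_segments"), length(pair) == 2L)
  if (nrow(segments) < 2L) {
    return(list(p_value = NA_real_, observed = NA_real_,
                observed_z = NA_real_, null_mean = NA_real_,
                flag = "fewer than 2 runs"))
  }
  classes <- attr(segments, "classes")
  cls <- match(segments$class, classes)
  xi <- match(pair[1], classes)
  yi <- match(pair[2], classes)
  obs_pct <- pair_predominance(cls, xi, yi)
  obs <- pair_asymmetry_z(cls, xi, yi)
  with_seed(seed, {
    null <- vapply(seq_len(n_permutations), function(i) {
      pair_asymmetry_z(cls[sample.int(length(cls))], xi, yi)
    }, 0)
    p <- (1 + sum(abs(null) >= abs(obs) - 1e-12)) / (n_permutations + 1)
    list(p_value = p, observed = obs_pct, observed_z = obs,
         null_mean = mean(null))
  })
}

FEATURE_NAMES <- c(
  paste0("duration_", MS_CLASSES), "mean_duration",
  paste0("occurrence_", MS_CLASSES), "mean_occurrence",
  paste0("coverage_", MS_CLASSES),
  paste0("gfp_", MS_CLASSES),
  vapply(ordered_pairs(), function(p) paste0("t_", p[1], "_", p[2]), ""),
  vapply(unordered_pairs(), function(p) paste0("dp_", p[1], "_", p[2]), "")
)

#' Assemble the fixed 36-feature vector of one epoch
#'
#' Fixed, documented order: the 18 microstate features (durations A-D, mean
#' duration, occurrences A-D, mean occurrence, coverages A-D, GFPs A-D), the
#' 12 transition percentages, then the 6 directional predominances. Missing
#' durations (class absent from interior runs) are imputed with 0 and the
#' affected names recorded in the `imputed` attribute.
#'
#' @param ms 18-vector from [microstate_features()].
#' @param tr 12-vector from [transition_percentages()].
#' @return Named numeric vector of length 36.
#' @export
assemble_feature_vector <- function(ms, tr) {
  dp <- directional_predominance(tr)
  out <- c(ms[FEATURE_NAMES[1:18]], tr, dp)
  names(out) <- FEATURE_NAMES
  imputed <- names(out)[is.na(out)]
  out[is.na(out)] <- 0
  attr(out, "imputed") <- imputed
  out
}

#' 36-feature vector straight from a label sequence
#'
#' Convenience wrapper: run-length segmentation, the 18 microstate features,
#' 12 transition percentages and 6 predominances in one call.
#'
#' @param labels An `ms_labels`.
#' @param gfp Optional aligned `gfp_series`.
#' @return Named numeric vector of length 36.
#' @export
epoch_feature_vector <- function(labels, gfp = NULL) {
  seg <- extract_segments(labels)
  assemble_feature_vector(microstate_features(seg, gfp),
                          transition_percentages(seg))
}

#' Per-epoch feature table for a set of epochs
#'
#' Backfits each epoch with the model, extracts the 36 features, and returns
#' one row per epoch with subject/group/condition metadata — the input shape
#' for [compare_states()] and the classification harness.
#'
#' @param epochs List of `eeg_epoch`.
#' @param model A `microstate_model` (archetype-labelled).
#' @return data.frame: `subject_id`, `group`, `condition`, `state_group`
#'   (PR/PT/GR/GT), `epoch_index`, then the 36 feature columns.
#' @export
feature_table <- function(epochs, model) {
  rows <- lapply(epochs, function(ep) {
    lab <- backfit_labels(model, ep)
    fv <- epoch_feature_vector(lab, compute_gfp(ep))
    cbind(data.frame(subject_id = ep$subject_id, group = ep$group,
                     condition = ep$condition,
                     state_group = state_group_code(ep$group, ep$condition),
                     epoch_index = ep$epoch_index, stringsAsFactors = FALSE),
          as.data.frame(as.list(fv)))
  })
  do.call(rbind, rows)
}
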