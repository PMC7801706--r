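#' Generate four archetype-oriented unit-norm topographies
#'
#' Builds the four generating topographies of the synthetic model by adding a
#' seeded smooth perturbation to the canonical orientation templates
#' (left-right, right-left, anterior-posterior, fronto-central focal), then
#' re-centering and re-normalizing. Maps are zero-mean across channels
#' (average-reference consistent), unit Euclidean norm, and pairwise
#' |correlation| < 0.95.
#'
#' @param n_channels Number of electrodes (>= 4). 19 selects the built-in
#'   10-20 montage; other counts use a generic circular layout unless a
#'   montage is supplied.
#' @param seed Integer seed; same seed gives identical maps.
#' @param montage Optional montage data.frame (`channel`, `x`, `y`).
#' @param jitter Standard deviation of the perturbation relative to the
#'   template scale (default 0.15).
#' @return Channels x 4 matrix with columns `A`..`D`.
#' @export
#' @examples
#' tp <- generate_topographies(19, seed = 1)
#' round(colSums(tp^2), 10)  # unit norms
generate_topographies <- function(n_channels = 19, seed = NULL,
                                  montage = NULL, jitter = 0.15) {
  if (n_channels < 4) stop("n_channels must be >= 4", call. = FALSE)
  if (is.null(montage)) {
    montage <- if (n_channels == 19L) montage_1020() else circular_montage(n_channels)
  }
  check_montage(montage)
  if (nrow(montage) != n_channels) {
    stop("montage must have n_channels rows", call. = FALSE)
  }
  tpl <- canonical_templates(montage)
  with_seed(seed, {
    for (try in 1:50) {
      maps <- tpl + matrix(stats::rnorm(length(tpl), sd = jitter), nrow(tpl))
      maps <- sweep(maps, 2L, colMeans(maps), "-")
      maps <- unit_norm_cols(maps)
      cc <- abs(crossprod(maps))
      diag(cc) <- 0
      if (max(cc) < 0.95) break
    }
    if (max(cc) >= 0.95) stop("could not generate well-separated maps", call. = FALSE)
    rownames(maps) <- montage$channel
    colnames(maps) <- MS_CLASSES
    maps
  })
}

#' Define the ground truth of the synthetic microstate model
#'
#' Collects everything the generator needs and every downstream stage should
#' recover: the four topographies, the row-stochastic zero-diagonal transition
#' matrix, per-class mean dwell times, the per-segment amplitude law, and the
#' signal-to-noise ratio.
#'
#' @param topographies Channels x 4 zero-mean unit-norm matrix (columns A-D).
#' @param transition_matrix 4x4 row-stochastic matrix with zero diagonal;
#'   default uniform over the three other classes.
#' @param dwell_mean_ms Mean segment duration in ms, scalar or length-4
#'   (per class). Default 80 ms, inside the 60-120 ms quasi-stability range.
#' @param dwell_distribution Currently `"truncated_geometric"`: segment length
#'   in samples is geometric with minimum 1 sample and the requested mean.
#' @param gfp_mean_uv Target mean GFP of the noiseless signal in uV
#'   (default 5).
#' @param snr Signal-RMS / noise-RMS ratio (> 0, default 5).
#' @param montage Montage used for the spatially correlated noise covariance.
#' @param seed Integer seed stored with the truth.
#' @return Object of class `ms_truth`.
#' @export
microstate_truth <- function(topographies = generate_topographies(19, seed = seed),
                             transition_matrix = NULL,
                             dwell_mean_ms = 80,
                             dwell_distribution = "truncated_geometric",
                             gfp_mean_uv = 5,
                             snr = 5,
                             montage = montage_1020(),
                             seed = 1L) {
  k <- ncol(topographies)
  if (is.null(transition_matrix)) {
    transition_matrix <- matrix(1 / (k - 1), k, k)
    diag(transition_matrix) <- 0
  }
  stopifnot(nrow(transition_matrix) == k, ncol(transition_matrix) == k)
  if (any(abs(rowSums(transition_matrix) - 1) > 1e-12)) {
    stop("transition_matrix rows must sum to 1", call. = FALSE)
  }
  if (any(diag(transition_matrix) != 0)) {
    stop("transition_matrix diagonal must be exactly 0", call. = FALSE)
  }
  if (any(dwell_mean_ms <= 0)) stop("dwell_mean_ms must be > 0", call. = FALSE)
  if (snr <= 0) stop("snr must be > 0", call. = FALSE)
  if (max(abs(colMeans(topographies))) > 1e-8) {
    stop("topographies must be zero-mean across channels", call. = FALSE)
  }
  if (max(abs(colSums(topographies^2) - 1)) > 1e-8) {
    stop("topographies must have unit norm", call. = FALSE)
  }
  dwell_mean_ms <- rep_len(dwell_mean_ms, k)
  structure(
    list(topographies = topographies, transition_matrix = transition_matrix,
         dwell_mean_ms = dwell_mean_ms, dwell_distribution = dwell_distribution,
         gfp_mean_uv = gfp_mean_uv, snr = snr, montage = montage, seed = seed),
    class = "ms_truth"
  )
}

#' Generate a piecewise-constant microstate label sequence
#'
#' Draws a sequence of microstate segments: the class chain follows the
#' truth's transition matrix (zero diagonal, so adjacent segments always
#' differ), segment lengths are geometric in samples with minimum one sample
#' and per-class mean `dwell_mean_ms`.
#'
#' @param truth An `ms_truth`.
#' @param n_samples Number of samples to generate (>= 1).
#' @param rate_hz Sampling rate (Hz).
#' @param seed Integer seed.
#' @return An `ms_labels` object.
#' @export
generate_state_sequence <- function(truth, n_samples, rate_hz = 500, seed = NULL) {
  stopifnot(inherits(truth, "ms_truth"), n_samples >= 1)
  k <- ncol(truth$topographies)
  mean_samples <- truth$dwell_mean_ms / 1000 * rate_hz
  if (any(mean_samples < 1)) stop("dwell_mean_ms below one sample period", call. = FALSE)
  p_stop <- 1 / mean_samples  # geometric on {1,2,...} has mean 1/p
  with_seed(seed, {
    # preallocate for the expected segment count plus slack
    cap <- max(16L, ceiling(n_samples / min(mean_samples) * 1.5) + 32L)
    cls <- integer(cap)
    len <- integer(cap)
    state <- sample.int(k, 1L)
    total <- 0
    i <- 0L
    while (total < n_samples) {
      i <- i + 1L
      if (i > cap) {
        cap <- cap * 2L
        cls <- c(cls, integer(cap / 2L))
        len <- c(len, integer(cap / 2L))
      }
      cls[i] <- state
      len[i] <- 1L + stats::rgeom(1L, p_stop[state])
      total <- total + len[i]
      state <- sample.int(k, 1L, prob = truth$transition_matrix[state, ])
    }
    labels <- rep.int(cls[seq_len(i)], len[seq_len(i)])[seq_len(n_samples)]
    new_labels(labels, rate_hz = rate_hz, classes = MS_CLASSES[seq_len(k)])
  })
}

#' Synthesize multichannel EEG from a label sequence
#'
#' Each sample is the topography of its label scaled by a smooth within-segment
#' amplitude envelope (half-sine arc, so GFP peaks fall inside segments) and a
#' per-segment random scale; the sign of each segment flips with probability
#' 1/2 (spontaneous-EEG polarity convention). Spatially correlated Gaussian
#' noise (squared-exponential covariance over electrode distances) is scaled so
#' signal-RMS / noise-RMS equals `truth$snr`, and the result is
#' average-referenced.
#'
#' @param truth An `ms_truth`.
#' @param labels An `ms_labels` from [generate_state_sequence()].
#' @param seed Integer seed.
#' @param noise_corr_length Length scale of the noise spatial covariance in
#'   montage units (default 0.6).
#' @return An `eeg_recording` (channels x samples, uV).
#' @export
synthesize_eeg <- function(truth, labels, seed = NULL, noise_corr_length = 0.6) {
  stopifnot(inherits(truth, "ms_truth"), inherits(labels, "ms_labels"))
  if (truth$snr <= 0) stop("snr must be > 0", call. = FALSE)
  lab <- labels$labels
  n <- length(lab)
  nch <- nrow(truth$topographies)
  r <- rle(lab)
  n_seg <- length(r$lengths)
  with_seed(seed, {
    sign_seg <- sample(c(-1, 1), n_seg, replace = TRUE)
    scale_seg <- stats::runif(n_seg, 0.7, 1.3)
    # within-segment half-sine envelope (floor 0.25 so boundaries stay
    # nonzero), normalized to unit asymptotic mean so the noiseless mean GFP
    # matches gfp_mean_uv
    env_mean <- 0.25 + 0.75 * 2 / pi
    env <- unlist(lapply(seq_len(n_seg), function(s) {
      L <- r$lengths[s]
      e <- (0.25 + 0.75 * sin(pi * (seq_len(L) - 0.5) / L)) / env_mean
      sign_seg[s] * scale_seg[s] * e
    }), use.names = FALSE)
    # unit-norm zero-mean map at amplitude a has GFP = a / sqrt(nch)
    amp <- truth$gfp_mean_uv * sqrt(nch) * env
    sig <- truth$topographies[, lab, drop = FALSE] *
      matrix(amp, nch, n, byrow = TRUE)
    d <- as.matrix(stats::dist(truth$montage[, c("x", "y")]))
    K <- exp(-d^2 / (2 * noise_corr_length^2)) + diag(1e-6, nch)
    noise <- t(chol(K)) %*% matrix(stats::rnorm(nch * n), nch, n)
    noise <- demean_channels(noise)
    noise <- noise * (sqrt(mean(sig^2)) / sqrt(mean(noise^2)) / truth$snr)
    new_recording(sig + noise, truth$montage$channel, labels$rate_hz)
  })
}

#' Define a two-group synthetic cohort
#'
#' Mirrors the study design by default: 26 good and 10 poor performers, one
#' rest and one task recording each (3 min rest, 1 min task analysed), 500 Hz,
#' 2-s epochs. Group-by-condition effects are injected as per-class dwell-time
#' multipliers on the base truth.
#'
#' @param n_good,n_poor Subjects per group (defaults 26 and 10).
#' @param rate_hz Sampling rate (default 500).
#' @param epoch_length_s Epoch length in seconds (default 2).
#' @param rest_duration_s,task_duration_s Recording durations (defaults 180
#'   and 60 s).
#' @param base_truth Base `ms_truth` shared by all cells.
#' @param dwell_mult Named list of per-class dwell multipliers keyed by state
#'   group (`"PR"`, `"PT"`, `"GR"`, `"GT"`), each a length-4 numeric vector.
#'   E.g. `list(GT = c(1, 1, 1, 1.2))` raises class-D dwell by 20% in the
#'   good-performer task state only.
#' @return Object of class `ms_cohort_spec`.
#' @export
cohort_spec <- function(n_good = 26, n_poor = 10, rate_hz = 500,
                        epoch_length_s = 2,
                        rest_duration_s = 180, task_duration_s = 60,
                        base_truth = microstate_truth(seed = 1L),
                        dwell_mult = list()) {
  stopifnot(n_good >= 1, n_poor >= 1, rate_hz > 0, epoch_length_s > 0)
  structure(
    list(n_good = n_good, n_poor = n_poor, rate_hz = rate_hz,
         epoch_length_s = epoch_length_s,
         rest_duration_s = rest_duration_s, task_duration_s = task_duration_s,
         base_truth = base_truth, dwell_mult = dwell_mult),
    class = "ms_cohort_spec"
  )
}

state_group_code <- function(group, condition) {
  paste0(toupper(substr(group, 1, 1)), toupper(substr(condition, 1, 1)))
}

# Truth for one cohort cell, with its dwell multiplier applied.
cell_truth <- function(spec, group, condition) {
  tr <- spec$base_truth
  code <- state_group_code(group, condition)
  m <- spec$dwell_mult[[code]]
  if (!is.null(m)) tr$dwell_mean_ms <- tr$dwell_mean_ms * rep_len(m, length(tr$dwell_mean_ms))
  tr
}

#' Generate a synthetic two-group cohort
#'
#' One rest and one task recording per subject, each with its generating label
#' sequence kept as ground truth. Deterministic under `seed`.
#'
#' @param spec An `ms_cohort_spec`.
#' @param seed Integer seed.
#' @return List with `recordings` (list of `eeg_recording`) and `truth_labels`
#'   (matching list of `ms_labels`), plus `spec`.
#' @export
generate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "ms_cohort_spec"))
  subjects <- data.frame(
    subject_id = sprintf("S%02d", seq_len(spec$n_good + spec$n_poor)),
    group = c(rep("good", spec$n_good), rep("poor", spec$n_poor)),
    stringsAsFactors = FALSE
  )
  recordings <- list()
  truth_labels <- list()
  i <- 0L
  for (s in seq_len(nrow(subjects))) {
    for (condition in c("rest", "task")) {
      i <- i + 1L
      dur <- if (condition == "rest") spec$rest_duration_s else spec$task_duration_s
      n_samples <- round(dur * spec$rate_hz)
      tr <- cell_truth(spec, subjects$group[s], condition)
      lab <- generate_state_sequence(tr, n_samples, spec$rate_hz,
                                     seed = derive_seed(seed, 2L * i))
      rec <- synthesize_eeg(tr, lab, seed = derive_seed(seed, 2L * i + 1L))
      rec$subject_id <- subjects$subject_id[s]
      rec$condition <- condition
      rec$group <- subjects$group[s]
      recordings[[i]] <- rec
      truth_labels[[i]] <- lab
    }
  }
  list(recordings = recordings, truth_labels = truth_labels, spec = spec)
}
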