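#' Global field power of an epoch
#'
#' GFP(t) is the root-mean-square deviation of the instantaneous channel
#' potentials around their mean:
#' `GFP(t) = sqrt( sum_i (V_i(t) - V_mean(t))^2 / N )`,
#' a reference-free per-sample measure of field strength.
#'
#' @param x An `eeg_epoch`, `eeg_recording`, or channels x samples matrix.
#' @param rate_hz Sampling rate, required only for a bare matrix.
#' @return Object of class `gfp_series`: list with `values` (uV, >= 0) and
#'   `rate_hz`.
#' @export
#' @examples
#' compute_gfp(matrix(c(1, -1), 2, 1), rate_hz = 500)$values  # 1
compute_gfp <- function(x, rate_hz = NULL) {
  if (inherits(x, c("eeg_epoch", "eeg_recording"))) {
    rate_hz <- x$rate_hz
    x <- x$data
  }
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("GFP needs >= 2 channels", call. = FALSE)
  v <- sqrt(colMeans(demean_channels(x)^2))
  structure(list(values = as.numeric(v), rate_hz = rate_hz), class = "gfp_series")
}

#' Local maxima of a GFP series
#'
#' A sample t is a peak iff `g[t-1] < g[t] >= g[t+1]` (the first sample of a
#' plateau counts; endpoints never do).
#'
#' @param gfp A `gfp_series` or numeric vector of length >= 3.
#' @return Integer vector of peak indices (possibly empty).
#' @export
find_gfp_peaks <- function(gfp) {
  g <- if (inherits(gfp, "gfp_series")) gfp$values else as.numeric(gfp)
  n <- length(g)
  if (n < 3L) stop("series too short for peak finding", call. = FALSE)
  t <- 2:(n - 1L)
  t[g[t - 1L] < g[t] & g[t] >= g[t + 1L]]
}

# Demean columns, return list(V = demeaned maps, Vn = unit-norm, ss = ||v||^2).
prep_maps <- function(maps) {
  V <- demean_channels(as.matrix(maps))
  ss <- colSums(V^2)
  list(V = V, Vn = unit_norm_cols(V), ss = ss)
}

# GEV of an assignment: templates unit-norm zero-mean (channels x k),
# V demeaned maps, ss their squared norms.
gev_of_assignment <- function(templates, V, ss, assign) {
  proj <- crossprod(templates, V)  # k x M
  num <- sum(proj[cbind(assign, seq_along(assign))]^2)
  num / sum(ss)
}

# Dominant spatial pattern (first principal direction) of a set of maps.
principal_map <- function(V) {
  S <- tcrossprod(V)
  e <- eigen(S, symmetric = TRUE)
  v <- e$vectors[, 1L]
  v / sqrt(sum(v^2))
}

#' Polarity-invariant modified k-means clustering of topographic maps
#'
#' The microstate variant of k-means: maps are assigned to the template with
#' maximal squared spatial correlation (sign ignored), and each template is
#' updated as the dominant spatial pattern (first principal direction) of its
#' assigned maps, so a global polarity flip of any input changes nothing.
#' Iterations stop when the relative GEV change falls below `threshold` or
#' after `max_iterations`. The whole procedure is restarted `n_reruns` times
#' from random map seeds and the re-run with maximal GEV is returned.
#'
#' @param peak_maps Channels x M matrix of maps (typically at GFP peaks),
#'   average-referenced.
#' @param k Number of clusters (default 4).
#' @param n_reruns Random restarts (default 20).
#' @param threshold Relative GEV convergence threshold (default 1e-6).
#' @param max_iterations Iteration cap per re-run (default 1000).
#' @param seed Integer seed for the restarts.
#' @return Object of class `microstate_model`: `maps` (channels x k,
#'   unit-norm, zero-mean), `gev`, `assignments` (per input map),
#'   `gev_trace` (per-iteration GEV of the winning re-run; non-decreasing up
#'   to the threshold tolerance), `k`,
#'   `rerun_gev` (GEV of every re-run), `archetype_labels` (NULL until
#'   [assign_archetypes()]), plus the run parameters.
#' @export
modified_kmeans <- function(peak_maps, k = 4, n_reruns = 20, threshold = 1e-6,
                            max_iterations = 1000, seed = NULL) {
  pm <- prep_maps(peak_maps)
  M <- ncol(pm$V)
  if (M < k) stop("fewer peak maps than clusters", call. = FALSE)
  if (all(pm$ss < 1e-24)) stop("degenerate input: all maps are zero", call. = FALSE)
  with_seed(seed, {
    best <- NULL
    rerun_gev <- numeric(n_reruns)
    for (run in seq_len(n_reruns)) {
      templates <- pm$Vn[, sample.int(M, k), drop = FALSE]
      gev_prev <- -Inf
      assign <- rep(1L, M)
      trace <- numeric(0)
      for (it in seq_len(max_iterations)) {
        proj2 <- crossprod(templates, pm$V)^2     # k x M
        assign <- max.col(t(proj2), ties.method = "first")
        # refill empty clusters with the worst-fitted maps
        fit <- proj2[cbind(assign, seq_len(M))] / pmax(pm$ss, 1e-300)
        empty <- setdiff(seq_len(k), unique(assign))
        if (length(empty)) {
          ord <- order(fit)
          for (jj in seq_along(empty)) assign[ord[jj]] <- empty[jj]
        }
        for (j in seq_len(k)) {
          templates[, j] <- principal_map(pm$V[, assign == j, drop = FALSE])
        }
        gev <- gev_of_assignment(templates, pm$V, pm$ss, assign)
        trace <- c(trace, gev)
        if (is.finite(gev_prev) && abs(gev - gev_prev) <= threshold * max(gev_prev, 1e-300)) break
        gev_prev <- gev
      }
      rerun_gev[run] <- gev
      if (is.null(best) || gev > best$gev) {
        best <- list(maps = templates, gev = gev, assignments = assign,
                     trace = trace)
      }
    }
    structure(
      list(maps = best$maps, gev = best$gev, assignments = best$assignments,
           gev_trace = best$trace,
           k = k, rerun_gev = rerun_gev, archetype_labels = NULL,
           n_reruns = n_reruns, convergence_threshold = threshold,
           max_iterations = max_iterations, seed = seed),
      class = "microstate_model"
    )
  })
}

#' @export
print.microstate_model <- function(x, ...) {
  cat(sprintf("<microstate_model> k=%d, GEV=%.4f (best of %d re-runs)\n",
              x$k, x$gev, length(x$rerun_gev)))
  if (!is.null(x$archetype_labels)) {
    cat("  archetypes:", paste(x$archetype_labels, collapse = " "), "\n")
  }
  invisible(x)
}

#' Global explained variance of a labelled sample set
#'
#' `GEV = sum_t GFP(t)^2 corr(V(t), map_label(t))^2 / sum_t GFP(t)^2`:
#' the GFP-weighted squared spatial correlation between each sample and its
#' assigned template, normalized by total squared GFP. Always in [0, 1].
#'
#' @param maps Channels x k matrix of templates.
#' @param samples Channels x T matrix of EEG samples.
#' @param labels Integer vector of length T assigning each sample to a map.
#' @param gfp Optional precomputed `gfp_series` (recomputed otherwise).
#' @return GEV fraction in [0, 1].
#' @export
compute_gev <- function(maps, samples, labels, gfp = NULL) {
  pm <- prep_maps(samples)
  tpl <- unit_norm_cols(demean_channels(as.matrix(maps)))
  labels <- if (inherits(labels, "ms_labels")) labels$labels else as.integer(labels)
  stopifnot(length(labels) == ncol(pm$V))
  if (sum(pm$ss) < 1e-24) stop("degenerate input: all-zero GFP", call. = FALSE)
  gev_of_assignment(tpl, pm$V, pm$ss, labels)
}

#' Backfit microstate labels onto every sample of an epoch
#'
#' Each sample is labelled with the template of maximal squared spatial
#' correlation, polarity ignored; ties (including zero-field samples) go to
#' the lowest archetype index. No temporal smoothing is applied by default.
#'
#' @param model A `microstate_model`.
#' @param epoch An `eeg_epoch`, `eeg_recording`, or channels x samples matrix.
#' @param rate_hz Sampling rate, required only for a bare matrix.
#' @return An `ms_labels` with per-sample |spatial correlation| attached.
#' @export
backfit_labels <- function(model, epoch, rate_hz = NULL) {
  if (inherits(epoch, c("eeg_epoch", "eeg_recording"))) {
    rate_hz <- epoch$rate_hz
    epoch <- epoch$data
  }
  pm <- prep_maps(epoch)
  proj <- crossprod(model$maps, pm$V)          # k x T
  lab <- max.col(t(proj^2), ties.method = "first")
  nrm <- sqrt(pm$ss)
  corr <- abs(proj[cbind(lab, seq_along(lab))]) / ifelse(nrm > 0, nrm, 1)
  classes <- if (!is.null(model$archetype_labels)) model$archetype_labels else
    MS_CLASSES[seq_len(model$k)]
  new_labels(lab, rate_hz = rate_hz, classes = classes, corr = corr)
}

#' Label a four-class model with the archetype taxonomy A-D
#'
#' Finds the bijection between the model's maps and the canonical orientation
#' templates (A left-right, B right-left, C anterior-posterior, D
#' fronto-central focal) that maximizes the summed absolute spatial
#' correlation over all 24 permutations, then reorders the maps into A, B, C,
#' D order.
#'
#' @param model A `microstate_model` with `k = 4`.
#' @param montage Montage with 2-D coordinates for every channel.
#' @return The model with maps reordered to A-D, `archetype_labels` set, and
#'   `match_scores` (per-map |correlation| with its canonical template).
#' @export
assign_archetypes <- function(model, montage = montage_1020()) {
  if (model$k != 4L) stop("archetype labeling requires k = 4", call. = FALSE)
  tpl <- canonical_templates(montage)
  cc <- abs(crossprod(tpl, model$maps))  # 4 canonical x 4 model maps
  best <- NULL
  for (p in all_perms(4L)) {
    # p[j] = model map assigned to canonical archetype j
    sc <- sum(cc[cbind(1:4, p)])
    if (is.null(best) || sc > best$score) best <- list(score = sc, perm = p)
  }
  perm <- best$perm
  model$maps <- model$maps[, perm, drop = FALSE]
  colnames(model$maps) <- MS_CLASSES
  model$archetype_labels <- MS_CLASSES
  model$match_scores <- stats::setNames(cc[cbind(1:4, perm)], MS_CLASSES)
  inv <- order(perm)
  model$assignments <- inv[model$assignments]
  model
}

#' Pool GFP-peak maps across epochs and fit one microstate model
#'
#' The standard aggregation: GFP local-maxima maps are extracted from every
#' epoch, pooled, clustered with [modified_kmeans()], and the k = 4 model is
#' archetype-labelled.
#'
#' @param epochs List of `eeg_epoch` (preprocessed).
#' @param k,n_reruns,threshold,max_iterations,seed Passed to
#'   [modified_kmeans()].
#' @param montage Montage for archetype labeling (k = 4 only).
#' @return A `microstate_model`.
#' @export
fit_microstates <- function(epochs, k = 4, n_reruns = 20, threshold = 1e-6,
                            max_iterations = 1000, seed = NULL,
                            montage = montage_1020()) {
  peaks <- lapply(epochs, function(ep) {
    g <- compute_gfp(ep)
    idx <- find_gfp_peaks(g)
    ep$data[, idx, drop = FALSE]
  })
  pooled <- do.call(cbind, peaks)
  model <- modified_kmeans(pooled, k = k, n_reruns = n_reruns,
                           threshold = threshold,
                           max_iterations = max_iterations, seed = seed)
  if (k == 4L) model <- assign_archetypes(model, montage)
  model
}
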