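test_that("GFP matches its closed forms", {
  # all channels equal -> 0
  expect_equal(compute_gfp(matrix(3, 4, 1), 500)$values, 0)
  # two channels +1/-1 -> 1
  expect_equal(compute_gfp(matrix(c(1, -1), 2, 1), 500)$values, 1)
  # four channels (3, -1, 2, 0) -> sqrt(10/4)
  expect_equal(compute_gfp(matrix(c(3, -1, 2, 0), 4, 1), 500)$values,
               sqrt(10 / 4), tolerance = 1e-12)
  expect_error(compute_gfp(matrix(1, 1, 5), 500), "2 channels")
  expect_true(all(compute_gfp(matrix(rnorm(40), 4, 10), 500)$values >= 0))
})

test_that("GFP peak finding follows the local-maximum definition", {
  expect_length(find_gfp_peaks(1:10), 0L)
  expect_equal(find_gfp_peaks(c(0, 1, 0, 2, 0)), c(2L, 4L))
  # plateau: first sample of the plateau counts
  expect_equal(find_gfp_peaks(c(0, 2, 2, 1, 0)), 2L)
  # 10 Hz rectified-style GFP over 1 s at 500 Hz -> 10 maxima
  t <- seq_len(500) / 500
  g <- abs(sin(2 * pi * 5 * t)) + 0.01  # |sin| at 5 Hz has 10 maxima per second
  expect_length(find_gfp_peaks(g), 10L)
  expect_error(find_gfp_peaks(c(1, 2)), "too short")
})

test_that("modified k-means recovers noiseless two-template mixtures exactly", {
  set.seed(31)
  t1 <- rnorm(12); t1 <- t1 - mean(t1); t1 <- t1 / sqrt(sum(t1^2))
  t2 <- rnorm(12); t2 <- t2 - mean(t2); t2 <- t2 - t1 * sum(t1 * t2)
  t2 <- t2 / sqrt(sum(t2^2))
  signs <- sample(c(-1, 1), 40, replace = TRUE)
  amps <- runif(40, 0.5, 2)
  maps <- sapply(seq_len(40), function(i) {
    signs[i] * amps[i] * (if (i %% 2) t1 else t2)
  })
  mod <- modified_kmeans(maps, k = 2, seed = 17)
  expect_equal(mod$gev, 1, tolerance = 1e-9)
  cc <- abs(crossprod(mod$maps, cbind(t1, t2)))
  expect_equal(max(cc[1, ]), 1, tolerance = 1e-6)
  expect_equal(max(cc[2, ]), 1, tolerance = 1e-6)
  expect_error(modified_kmeans(maps[, 1:1, drop = FALSE], k = 2), "fewer")
  expect_error(modified_kmeans(matrix(0, 12, 8), k = 2), "degenerate")
})

test_that("clustering is polarity-invariant and GEV-monotone", {
  set.seed(32)
  for (i in 1:5) {
    maps <- matrix(rnorm(8 * 30), 8, 30)
    flip <- sample(c(-1, 1), 30, replace = TRUE)
    m1 <- modified_kmeans(maps, k = 3, seed = i)
    m2 <- modified_kmeans(sweep(maps, 2L, flip, "*"), k = 3, seed = i)
    expect_equal(m1$gev, m2$gev, tolerance = 1e-12)
    expect_identical(m1$assignments, m2$assignments)
    # GEV non-decreasing over iterations (up to the convergence tolerance)
    expect_true(all(diff(m1$gev_trace) >= -1e-6 * max(m1$gev_trace)))
    # selected re-run attains the maximum over re-runs
    expect_equal(m1$gev, max(m1$rerun_gev))
  }
})

test_that("k-means attains the exhaustive-partition optimum on small instances", {
  set.seed(33)
  for (i in 1:10) {
    maps <- matrix(rnorm(6 * sample(5:8, 1)), 6)
    mod <- modified_kmeans(maps, k = 2, seed = i)
    expect_equal(mod$gev, oracle_best_gev_k2(maps), tolerance = 1e-6)
  }
})

test_that("compute_gev matches the term-by-term formula and its limits", {
  set.seed(34)
  maps <- matrix(rnorm(10 * 3), 10, 3)
  samples <- matrix(rnorm(10 * 10), 10, 10)
  labels <- sample(1:3, 10, replace = TRUE)
  expect_equal(compute_gev(maps, samples, labels),
               oracle_gev(maps, samples, labels), tolerance = 1e-12)
  # perfect fit: each sample proportional (+-) to its map
  m2 <- sweep(matrix(rnorm(10 * 2), 10, 2), 2L, c(1, 1), "*")
  m2 <- sweep(m2, 2L, colMeans(m2), "-")
  lab2 <- c(1, 2, 1, 2)
  s2 <- m2[, lab2] %*% diag(c(2, -3, 0.5, 1))
  expect_equal(compute_gev(m2, s2, lab2), 1, tolerance = 1e-12)
  # orthogonal maps explain nothing
  A <- qr.Q(qr(matrix(rnorm(10 * 4), 10, 4)))
  onev <- rep(1 / sqrt(10), 10)
  A <- A - onev %*% t(onev) %*% A  # keep everything average-referenced
  A <- qr.Q(qr(A))
  s3 <- A[, 1:2][, c(1, 2, 1)] %*% diag(c(1, 2, 3))
  expect_equal(compute_gev(A[, 3:4], s3, c(1, 2, 2)), 0, tolerance = 1e-9)
  expect_error(compute_gev(maps, matrix(0, 10, 4), c(1, 1, 2, 2)), "degenerate")
})

test_that("backfitting labels noiseless data perfectly and breaks ties low", {
  b <- make_test_epoch(seed = 41, n_samples = 1500)
  tr_inf <- b$truth; tr_inf$snr <- 1e9
  rec <- synthesize_eeg(tr_inf, b$labels, seed = 2)
  model <- structure(list(maps = b$truth$topographies, k = 4L,
                          archetype_labels = MS_CLASSES),
                     class = "microstate_model")
  bl <- backfit_labels(model, rec)
  expect_identical(bl$labels, b$labels$labels)
  expect_true(all(bl$corr > 0.999))
  # tie: a zero sample is equidistant to all maps -> class A (index 1)
  z <- backfit_labels(model, matrix(0, 19, 3), rate_hz = 500)
  expect_identical(z$labels, rep(1L, 3L))
  # snr = 5: >= 90% agreement
  rec5 <- synthesize_eeg(b$truth, b$labels, seed = 3)
  bl5 <- backfit_labels(model, rec5)
  expect_gt(mean(bl5$labels == b$labels$labels), 0.9)
})

test_that("archetype assignment maximizes total |correlation| over permutations", {
  tpl <- canonical_templates()
  model <- structure(list(maps = tpl, k = 4L, assignments = 1:4),
                     class = "microstate_model")
  m <- assign_archetypes(model)
  expect_identical(m$archetype_labels, MS_CLASSES)
  expect_equal(unname(m$match_scores), rep(1, 4), tolerance = 1e-12)
  # sign flips are ignored
  model$maps <- -tpl
  m2 <- assign_archetypes(model)
  expect_equal(unname(m2$match_scores), rep(1, 4), tolerance = 1e-12)
  # random maps: agree with brute-force permutation search
  set.seed(51)
  for (i in 1:5) {
    maps <- matrix(rnorm(19 * 4), 19, 4)
    maps <- sweep(maps, 2L, colMeans(maps), "-")
    maps <- sweep(maps, 2L, sqrt(colSums(maps^2)), "/")
    model$maps <- maps
    m3 <- assign_archetypes(model)
    cc <- abs(crossprod(canonical_templates(), maps))
    best <- max(vapply(microstatr:::all_perms(4L),
                       function(p) sum(cc[cbind(1:4, p)]), 0))
    expect_equal(sum(m3$match_scores), best, tolerance = 1e-12)
  }
  model$k <- 3L
  expect_error(assign_archetypes(model), "k = 4")
})
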