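# Independent oracles used across tests. These deliberately avoid the code
# paths they check.

# Exhaustive 2-partition oracle for polarity-invariant clustering: for every
# bipartition of the maps, the best template per part is the first principal
# direction; return the maximum GEV over all partitions.
oracle_best_gev_k2 <- function(maps) {
  V <- sweep(maps, 2L, colMeans(maps), "-")
  ss <- colSums(V^2)
  M <- ncol(V)
  pd <- function(Vs) {
    e <- eigen(tcrossprod(Vs), symmetric = TRUE)
    v <- e$vectors[, 1L]
    v / sqrt(sum(v^2))
  }
  best <- -Inf
  for (code in seq_len(2^M - 2L)) {
    part <- as.logical(bitwAnd(code, 2^(seq_len(M) - 1L)))
    if (!any(part) || all(part)) next
    t1 <- pd(V[, part, drop = FALSE])
    t2 <- pd(V[, !part, drop = FALSE])
    num <- sum(crossprod(t1, V[, part, drop = FALSE])^2) +
      sum(crossprod(t2, V[, !part, drop = FALSE])^2)
    best <- max(best, num / sum(ss))
  }
  best
}

# Exact two-sided Mann-Whitney p by enumerating all rank arrangements
# (tie-free samples only).
oracle_exact_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  obs_u <- sum(rank(c(x, y))[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2L, function(idx) sum(idx) - n1 * (n1 + 1) / 2)
  mean(abs(us - mu) >= abs(obs_u - mu) - 1e-12)
}

# Brute-force pairwise AUC, ties half-counted.
oracle_pairwise_auc <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Term-by-term GEV hand computation (independent of compute_gev internals).
oracle_gev <- function(maps, samples, labels) {
  N <- nrow(samples)
  num <- den <- 0
  for (t in seq_len(ncol(samples))) {
    v <- samples[, t] - mean(samples[, t])
    gfp2 <- sum(v^2) / N
    m <- maps[, labels[t]] - mean(maps[, labels[t]])
    cr <- if (sum(v^2) == 0) 0 else sum(v * m) / sqrt(sum(v^2) * sum(m^2))
    num <- num + gfp2 * cr^2
    den <- den + gfp2
  }
  num / den
}

# Small fixed-seed synthetic epoch bundle reused across feature tests.
make_test_epoch <- function(seed = 42, n_samples = 1000, snr = 5) {
  tp <- generate_topographies(19, seed = seed)
  tr <- microstate_truth(topographies = tp, snr = snr, seed = seed)
  lab <- generate_state_sequence(tr, n_samples, 500, seed = seed + 1L)
  rec <- synthesize_eeg(tr, lab, seed = seed + 2L)
  list(truth = tr, labels = lab, rec = rec)
}
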