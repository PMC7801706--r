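#' Mann-Whitney rank-sum test with a signed z statistic
#'
#' Two-sided rank-sum test. Following the standard convention, the p-value is
#' exact (from the null U distribution) for small tie-free samples
#' (both n < 50) and otherwise uses the tie-corrected, continuity-corrected
#' normal approximation. z is always reported from the normal approximation,
#' signed so that positive means `x` is stochastically larger than `y`.
#'
#' @param x,y Nonempty numeric samples.
#' @return List with `z`, `p` (two-sided), `U` (U statistic of `x`), and
#'   `exact` (whether the exact null distribution was used for `p`).
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty", call. = FALSE)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(list(z = 0, p = 1, U = U, exact = FALSE))
  sigma <- sqrt(sigma2)
  d <- U - mu
  z <- if (d == 0) 0 else (d - 0.5 * sign(d)) / sigma
  exact <- !has_ties && n1 < 50 && n2 < 50
  p <- if (exact) {
    # U is symmetric about mu under the null
    min(1, 2 * stats::pwilcox(min(U, n1 * n2 - U), n1, n2))
  } else {
    min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(z = z, p = p, U = U, exact = exact)
}

#' Bonferroni-Holm step-down correction
#'
#' Sorts p-values ascending, multiplies the i-th by (m - i + 1), enforces
#' monotonicity, caps at 1, and returns the adjusted values in input order
#' (delegates to `stats::p.adjust(method = "holm")`, which implements exactly
#' this rule).
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in input order.
#' @export
#' @examples
#' holm_correction(c(0.01, 0.04, 0.03))  # 0.03 0.06 0.06
holm_correction <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must be in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "holm")
}

# feature-name block used as the Holm family: 18 microstate features,
# 12 transitions, 6 predominances
feature_block <- function(feature) {
  ifelse(startsWith(feature, "t_"), "transition",
         ifelse(startsWith(feature, "dp_"), "predominance", "microstate"))
}

#' Between-state comparisons of the epoch-level feature table
#'
#' For each feature and contrast, a Mann-Whitney test on epoch-level values,
#' with Bonferroni-Holm correction applied within each contrast and feature
#' block (the 18 microstate features; the 12 transition percentages; the 6
#' predominances), the narrowest defensible family. The unit of analysis is
#' the epoch, matching the source design; a subject-level mode is available
#' by pre-aggregating the table.
#'
#' @param ft Feature table from [feature_table()] (needs `state_group`).
#' @param contrasts Character vector like `"GR_vs_GT"`; the two state-group
#'   codes separated by `"_vs_"`. Defaults to the three study contrasts.
#' @param features Feature columns to test (default all 36).
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @return data.frame: `feature`, `block`, `contrast`, `mean_x`, `sd_x`,
#'   `mean_y`, `sd_y`, `z`, `p_raw`, `p_adjusted`, `significant`.
#' @export
compare_states <- function(ft, contrasts = c("PR_vs_PT", "GR_vs_GT", "PT_vs_GT"),
                           features = FEATURE_NAMES, alpha = 0.05) {
  stopifnot("state_group" %in% names(ft))
  rows <- list()
  for (ctr in contrasts) {
    gg <- strsplit(ctr, "_vs_", fixed = TRUE)[[1]]
    x_all <- ft[ft$state_group == gg[1], , drop = FALSE]
    y_all <- ft[ft$state_group == gg[2], , drop = FALSE]
    if (!nrow(x_all) || !nrow(y_all)) {
      warning("contrast ", ctr, " has an empty cell; skipped")
      next
    }
    for (f in features) {
      mw <- mann_whitney(x_all[[f]], y_all[[f]])
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, block = feature_block(f), contrast = ctr,
        mean_x = mean(x_all[[f]]), sd_x = stats::sd(x_all[[f]]),
        mean_y = mean(y_all[[f]]), sd_y = stats::sd(y_all[[f]]),
        z = mw$z, p_raw = mw$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- NA_real_
  for (ctr in unique(out$contrast)) {
    for (blk in unique(out$block)) {
      idx <- out$contrast == ctr & out$block == blk
      out$p_adjusted[idx] <- holm_correction(out$p_raw[idx])
    }
  }
  out$significant <- out$p_adjusted < alpha
  out
}

#' One-sample test of directional predominance against zero
#'
#' Default: sign-flip permutation test of the mean (each epoch's value is
#' multiplied by a random +-1, two-sided add-one p). Alternative: Wilcoxon
#' signed-rank.
#'
#' @param values Numeric vector (>= 2 values), e.g. one pair's predominance
#'   across epochs.
#' @param method `"signflip"` (default) or `"signedrank"`.
#' @param n_permutations Sign flips for the permutation variant (default
#'   10000).
#' @param seed Integer seed.
#' @return List with `p_value`, `estimate` (mean of values), `method`.
#' @export
test_vs_zero <- function(values, method = c("signflip", "signedrank"),
                         n_permutations = 10000, seed = NULL) {
  method <- match.arg(method)
  if (length(values) < 2L) stop("need >= 2 values", call. = FALSE)
  est <- mean(values)
  if (method == "signedrank") {
    p <- if (all(values == 0)) 1 else
      suppressWarnings(stats::wilcox.test(values, mu = 0)$p.value)
    return(list(p_value = p, estimate = est, method = method))
  }
  obs <- abs(est)
  n <- length(values)
  with_seed(seed, {
    exceed <- 0L
    chunk <- max(1L, min(n_permutations, floor(2e6 / n)))
    done <- 0L
    while (done < n_permutations) {
      m <- min(chunk, n_permutations - done)
      signs <- matrix(sample(c(-1, 1), n * m, replace = TRUE), n, m)
      null_means <- abs(colMeans(signs * values))
      exceed <- exceed + sum(null_means >= obs - 1e-12)
      done <- done + m
    }
    list(p_value = (1 + exceed) / (n_permutations + 1), estimate = est,
         method = method)
  })
}
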