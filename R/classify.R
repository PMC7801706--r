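#' Balanced downsampling of the feature table
#'
#' Uniform random subset without replacement of `n_per_group` epochs per
#' group, the standard remedy for the unbalanced cohort. Deterministic
#' under `seed`.
#'
#' @param ft Feature table (needs `group_col`).
#' @param n_per_group Epochs kept per group (default 250).
#' @param group_col Grouping column (default `"group"`).
#' @param seed Integer seed.
#' @return Row-subset of `ft` with `n_per_group` rows per group.
#' @export
downsample_balance <- function(ft, n_per_group = 250, group_col = "group",
                               seed = NULL) {
  groups <- unique(ft[[group_col]])
  for (g in groups) {
    n_g <- sum(ft[[group_col]] == g)
    if (n_g < n_per_group) {
      stop("group '", g, "' has only ", n_g, " epochs (< ", n_per_group, ")",
           call. = FALSE)
    }
  }
  with_seed(seed, {
    idx <- unlist(lapply(groups, function(g) {
      sample(which(ft[[group_col]] == g), n_per_group)
    }))
    ft[sort(idx), , drop = FALSE]
  })
}

# Train-fold standardization: z-score parameters from the training rows only.
std_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mu = mu, sd = sd)
}
std_apply <- function(X, s) sweep(sweep(X, 2L, s$mu, "-"), 2L, s$sd, "/")

# Median-heuristic RBF width: 1 / (2 * median pairwise squared distance).
rbf_gamma <- function(X) {
  n <- nrow(X)
  if (n > 200L) X <- X[seq(1L, n, length.out = 200L), , drop = FALSE]
  d2 <- stats::dist(X)^2
  m <- stats::median(d2[d2 > 0])
  if (!is.finite(m) || m == 0) 1 / ncol(X) else 1 / (2 * m)
}

svm_spec <- function(name, kernel) {
  list(
    name = name, score_type = "margin", rank = "permutation",
    fit = function(X, y) {
      args <- list(x = X, y = y, kernel = kernel, cost = 1, scale = FALSE)
      if (kernel == "radial") args$gamma <- rbf_gamma(X)
      do.call(e1071::svm, args)
    },
    score = function(model, X) {
      pr <- stats::predict(model, X, decision.values = TRUE)
      dv <- attr(pr, "decision.values")[, 1L]
      pos_first <- strsplit(colnames(attr(pr, "decision.values"))[1L], "/")[[1]][1]
      if (pos_first == levels(model$fitted)[2L]) dv else -dv
    }
  )
}

knn_spec <- function(k) {
  list(
    name = paste0("kNN-", k), score_type = "prob", rank = "permutation",
    fit = function(X, y) list(X = X, y = y, k = k),
    score = function(model, X) {
      pr <- class::knn(model$X, X, model$y, k = model$k, prob = TRUE)
      p_win <- attr(pr, "prob")
      ifelse(pr == levels(model$y)[2L], p_win, 1 - p_win)
    }
  )
}

#' The eight-classifier suite
#'
#' Logistic regression; SVM with linear, polynomial, and radial-basis kernels
#' (cost 1; RBF width by the median heuristic); k-nearest neighbours with
#' k = 2, 5, 10; random forest (500 trees). Every spec exposes `fit(X, y)`
#' and a continuous `score(model, X)` usable for ROC (probability of the
#' positive class, or a decision margin oriented toward it), plus the feature
#' ranking rule used by RFE (`"coef"` for linear models, `"permutation"`
#' otherwise). `y` must be a two-level factor; the second level is the
#' positive class.
#'
#' @return Named list of 8 classifier specs (`LR`, `SVM-Lin`, `SVM-Poly`,
#'   `SVM-RBF`, `kNN-2`, `kNN-5`, `kNN-10`, `RF`).
#' @export
classifier_suite <- function() {
  lr <- list(
    name = "LR", score_type = "prob", rank = "coef",
    fit = function(X, y) {
      suppressWarnings(stats::glm.fit(cbind(1, X), as.integer(y) - 1L,
                                      family = stats::binomial()))
    },
    score = function(model, X) {
      co <- model$coefficients
      co[!is.finite(co)] <- 0
      as.numeric(stats::plogis(cbind(1, X) %*% co))
    },
    importance = function(model, X, y) {
      co <- model$coefficients[-1L]
      co[!is.finite(co)] <- 0
      abs(co)
    }
  )
  svml <- svm_spec("SVM-Lin", "linear")
  svml$rank <- "coef"
  svml$importance <- function(model, X, y) {
    w <- crossprod(model$coefs, model$SV)
    abs(as.numeric(w))
  }
  rf <- list(
    name = "RF", score_type = "prob", rank = "permutation",
    fit = function(X, y) randomForest::randomForest(X, y, ntree = 500),
    score = function(model, X) {
      stats::predict(model, X, type = "prob")[, levels(model$y)[2L]]
    }
  )
  list(`LR` = lr, `SVM-Lin` = svml, `SVM-Poly` = svm_spec("SVM-Poly", "polynomial"),
       `SVM-RBF` = svm_spec("SVM-RBF", "radial"),
       `kNN-2` = knn_spec(2), `kNN-5` = knn_spec(5), `kNN-10` = knn_spec(10),
       `RF` = rf)
}

score_to_class <- function(spec, score, levels) {
  cut <- if (spec$score_type == "prob") 0.5 else 0
  factor(ifelse(score >= cut, levels[2L], levels[1L]), levels = levels)
}

# Feature importance for RFE: native coefficients where available, otherwise
# permutation importance (training-accuracy drop when one column is shuffled).
rank_importance <- function(spec, model, X, y) {
  if (!is.null(spec$importance)) return(spec$importance(model, X, y))
  base_pred <- score_to_class(spec, spec$score(model, X), levels(y))
  base_acc <- mean(base_pred == y)
  vapply(seq_len(ncol(X)), function(j) {
    Xp <- X
    Xp[, j] <- Xp[sample.int(nrow(X)), j]
    pred <- score_to_class(spec, spec$score(model, Xp), levels(y))
    base_acc - mean(pred == y)
  }, 0)
}

#' Area under the ROC curve by the rank formula
#'
#' Probability that a random positive scores above a random negative, ties
#' half-counted: `AUC = (R1 - n1 (n1 + 1) / 2) / (n1 n0)` with `R1` the rank
#' sum of positive scores.
#'
#' @param scores Continuous classifier scores, larger = more positive.
#' @param labels Logical or two-level factor (second level positive).
#' @return AUC in [0, 1].
#' @export
auc_score <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == levels(labels)[2L]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("need both classes for AUC", call. = FALSE)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

make_xy <- function(ft, features, group_col, positive) {
  X <- as.matrix(ft[, features, drop = FALSE])
  g <- ft[[group_col]]
  y <- factor(ifelse(g == positive, positive, "other"),
              levels = c("other", positive))
  list(X = X, y = y)
}

#' Recursive feature elimination with repeated cross-validation
#'
#' Per repetition and training fold: features are standardized and ranked on
#' the training data only; the lowest-ranked feature is dropped and test
#' accuracy recorded at every feature count down to one. The accuracy curve is
#' averaged over folds and repetitions; the optimal count maximizes mean
#' accuracy (smallest count wins ties) and the selected set is the features
#' most often retained at that count.
#'
#' @param ft Feature table (balanced; see [downsample_balance()]).
#' @param spec One classifier spec from [classifier_suite()].
#' @param n_repetitions Repetitions of the fold split (default 100).
#' @param folds Cross-validation folds (default 5).
#' @param seed Integer seed.
#' @param features Candidate features (default the 36-feature schema).
#' @param group_col,positive Group column and positive class label.
#' @param redraw_from Optional unbalanced table: when given, each repetition
#'   re-draws its own balanced subsample of `n_per_group` from it.
#' @param n_per_group Subsample size per group for `redraw_from`.
#' @return Object of class `rfe_result`: `classifier`, `counts`, `acc_mean`,
#'   `acc_sd`, `optimal_count`, `selected_features`, `presence` (count x
#'   feature retention totals), and `presence_rep` (per-repetition retention
#'   counts over folds, `[rep, count, feature]`).
#' @export
rfe_select <- function(ft, spec, n_repetitions = 100, folds = 5, seed = NULL,
                       features = FEATURE_NAMES, group_col = "group",
                       positive = "good", redraw_from = NULL,
                       n_per_group = 250) {
  p <- length(features)
  acc_rep <- matrix(NA_real_, n_repetitions, p)  # per-rep fold-mean accuracy
  presence <- matrix(0, p, p, dimnames = list(NULL, features))  # count x feature
  # per-repetition fold-retention counts: [rep, count, feature]
  presence_rep <- array(0L, c(n_repetitions, p, p),
                        dimnames = list(NULL, NULL, features))
  for (rep in seq_len(n_repetitions)) {
    rep_seed <- derive_seed(seed, rep)
    tbl <- if (!is.null(redraw_from)) {
      downsample_balance(redraw_from, n_per_group, group_col, seed = rep_seed)
    } else ft
    xy <- make_xy(tbl, features, group_col, positive)
    fold <- stratified_folds(xy$y, folds, seed = derive_seed(rep_seed, 1L))
    acc_fold <- matrix(NA_real_, folds, p)
    for (f in seq_len(folds)) {
      tr <- fold != f
      s <- std_fit(xy$X[tr, , drop = FALSE])
      Xtr <- std_apply(xy$X[tr, , drop = FALSE], s)
      Xte <- std_apply(xy$X[!tr, , drop = FALSE], s)
      ytr <- xy$y[tr]; yte <- xy$y[!tr]
      current <- seq_len(p)
      with_seed(derive_seed(rep_seed, 100L + f), {
        while (length(current) >= 1L) {
          m <- spec$fit(Xtr[, current, drop = FALSE], ytr)
          pred <- score_to_class(spec, spec$score(m, Xte[, current, drop = FALSE]),
                                 levels(yte))
          cnt <- length(current)
          acc_fold[f, cnt] <- mean(pred == yte)
          presence[cnt, current] <- presence[cnt, current] + 1
          presence_rep[rep, cnt, current] <- presence_rep[rep, cnt, current] + 1L
          if (cnt == 1L) break
          imp <- rank_importance(spec, m, Xtr[, current, drop = FALSE], ytr)
          current <- current[-which.min(imp)]
        }
      })
    }
    acc_rep[rep, ] <- colMeans(acc_fold)
  }
  acc_mean <- colMeans(acc_rep)
  acc_sd <- apply(acc_rep, 2L, stats::sd)
  optimal <- which.max(acc_mean)  # ties: smallest count
  sel <- names(sort(presence[optimal, ], decreasing = TRUE))[seq_len(optimal)]
  structure(
    list(classifier = spec$name, counts = seq_len(p), acc_mean = acc_mean,
         acc_sd = acc_sd, optimal_count = optimal, selected_features = sel,
         presence = presence, presence_rep = presence_rep, folds = folds),
    class = "rfe_result"
  )
}

#' @export
print.rfe_result <- function(x, ...) {
  cat(sprintf("<rfe_result> %s: optimal %d features, mean accuracy %.3f\n",
              x$classifier, x$optimal_count, x$acc_mean[x$optimal_count]))
  cat("  selected:", paste(x$selected_features, collapse = ", "), "\n")
  invisible(x)
}

#' Stratified cross-validated evaluation of one classifier
#'
#' Stratified fold split; per fold the model is fitted on standardized
#' training data and scored on the held-out fold. Reports mean accuracy,
#' AUC (mean of per-fold AUCs from the continuous scores), sensitivity
#' (recall of the positive class) and specificity, plus per-fold ROC points.
#'
#' @param ft Feature table.
#' @param features Feature columns to use.
#' @param spec One classifier spec from [classifier_suite()].
#' @param folds Number of folds (default 5).
#' @param seed Integer seed.
#' @param group_col,positive Group column and positive class label.
#' @return Object of class `cv_report`: `classifier`, `accuracy`, `auc`,
#'   `sensitivity`, `specificity`, `fold_auc`, `roc` (data.frame `fold`,
#'   `fpr`, `tpr`), `fold_assignment`, `seed`.
#' @export
crossval_evaluate <- function(ft, features, spec, folds = 5, seed = NULL,
                              group_col = "group", positive = "good") {
  xy <- make_xy(ft, features, group_col, positive)
  fold <- stratified_folds(xy$y, folds, seed = seed)
  if (any(tapply(xy$y, fold, function(v) length(unique(v))) < 2L)) {
    stop("invalid-fold: a fold contains one class only", call. = FALSE)
  }
  acc <- sens <- spc <- aucs <- numeric(folds)
  roc <- list()
  for (f in seq_len(folds)) {
    tr <- fold != f
    s <- std_fit(xy$X[tr, , drop = FALSE])
    Xtr <- std_apply(xy$X[tr, , drop = FALSE], s)
    Xte <- std_apply(xy$X[!tr, , drop = FALSE], s)
    ytr <- xy$y[tr]; yte <- xy$y[!tr]
    m <- with_seed(derive_seed(seed, f), spec$fit(Xtr, ytr))
    sc <- with_seed(derive_seed(seed, 1000L + f), spec$score(m, Xte))
    pred <- score_to_class(spec, sc, levels(yte))
    pos <- yte == levels(yte)[2L]
    acc[f] <- mean(pred == yte)
    sens[f] <- mean(pred[pos] == levels(yte)[2L])
    spc[f] <- mean(pred[!pos] == levels(yte)[1L])
    aucs[f] <- auc_score(sc, yte)
    thr <- c(Inf, sort(unique(sc), decreasing = TRUE))
    roc[[f]] <- data.frame(
      fold = f,
      fpr = vapply(thr, function(t) mean(sc[!pos] >= t), 0),
      tpr = vapply(thr, function(t) mean(sc[pos] >= t), 0))
  }
  structure(
    list(classifier = spec$name, accuracy = mean(acc), auc = mean(aucs),
         sensitivity = mean(sens), specificity = mean(spc), fold_auc = aucs,
         fold_accuracy = acc, roc = do.call(rbind, roc),
         fold_assignment = fold, seed = seed),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s: acc %.3f, AUC %.3f, sens %.3f, spec %.3f\n",
              x$classifier, x$accuracy, x$auc, x$sensitivity, x$specificity))
  invisible(x)
}
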