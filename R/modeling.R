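#' Random-forest variable-importance feature ranking
#'
#' Fits a random forest with out-of-bag permutation importance and
#' ranks features by mean decrease in accuracy.  Selection keeps
#' features whose importance exceeds that of every appended random
#' "probe" feature (shuffled copies of real columns, which carry the
#' marginal distributions but no signal).  With a probe set as large
#' as the feature set, a pure-noise feature clears this shadow-maximum
#' threshold with probability about `1/(n_probes + 1)`, keeping null
#' selections rare.
#'
#' @param table a `feature_table` or data frame.
#' @param label_col name of the label column (default `"label"`).
#' @param n_trees forest size (default 500).
#' @param seed RNG seed; the ranking is deterministic given the seed.
#' @param n_probes number of probe features (default `max(30, p)`).
#' @return `feature_ranking`: list with `importance` (named, sorted
#'   decreasing), `selected` (character), `seed`.
#' @export
rank_features <- function(table, label_col = "label", n_trees = 500,
                          seed = 1, n_probes = NULL) {
  fcols <- feature_columns(table)
  y <- factor(table[[label_col]])
  if (nlevels(droplevels(y)) < 2) stop("need >= 2 label classes")
  X <- as.matrix(table[, fcols, drop = FALSE])
  if (anyNA(X)) stop("missing values in feature table")
  set.seed(seed)
  p <- ncol(X)
  if (is.null(n_probes)) n_probes <- max(30L, p)
  probe_src <- sample(p, n_probes, replace = TRUE)
  probes <- vapply(probe_src, function(j) sample(X[, j]), numeric(nrow(X)))
  colnames(probes) <- paste0(".probe", seq_len(n_probes))
  Xa <- cbind(X, probes)
  colnames(Xa) <- make.names(colnames(Xa), unique = TRUE)
  fit <- randomForest::randomForest(Xa, y, ntree = n_trees,
                                    importance = TRUE)
  imp <- randomForest::importance(fit, type = 1)[, 1]
  probe_imp <- imp[grepl("^\\.probe", names(imp))]
  feat_imp <- imp[!grepl("^\\.probe", names(imp))]
  names(feat_imp) <- fcols  # undo make.names
  thr <- max(probe_imp)
  ranking <- sort(feat_imp, decreasing = TRUE)
  structure(list(importance = ranking,
                 selected = names(ranking)[ranking > thr],
                 threshold = unname(thr), seed = seed),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("<feature_ranking> %d features ranked, %d selected (probe 95%% = %.3g)\n",
              length(x$importance), length(x$selected), x$threshold))
  invisible(x)
}

#' Sammon mapping to a low-dimensional space
#'
#' Minimizes the Sammon stress
#' `E = (1 / sum d*) * sum (d* - d)^2 / d*` over the embedded
#' coordinates, where `d*` are input-space Euclidean distances and `d`
#' embedded distances (sums over pairs).  Uses Sammon's pseudo-Newton
#' update with magic factor 0.3, principal-coordinate initialization,
#' and step halving so the stress trace is non-increasing.  Zero input
#' distances (duplicate points) are regularized with a small epsilon,
#' which places duplicates at essentially identical output
#' coordinates.  Axes of the projection are unitless: only the
#' cluster structure, not the axes, is interpretable.
#'
#' @param X numeric matrix (samples x features) or a `dist`.
#' @param out_dim embedding dimension (default 3).
#' @param max_iter iteration cap (default 300).
#' @param tol stop when the relative stress decrease falls below this.
#' @param seed RNG seed for degenerate tie-breaking jitter.
#' @param magic Sammon step factor (default 0.3).
#' @param eps regularizer for zero distances.
#' @return `sammon_projection`: list with `coords` (n x out_dim),
#'   `stress`, `stress_trace`, `converged`, `seed`.
#' @export
sammon_map <- function(X, out_dim = 3, max_iter = 300, tol = 1e-9,
                       seed = 1, magic = 0.3, eps = 1e-12) {
  D <- if (inherits(X, "dist")) as.matrix(X) else as.matrix(dist(X))
  n <- nrow(D)
  if (n < out_dim + 1) stop("need at least out_dim + 1 samples")
  if (all(D[upper.tri(D)] == 0)) stop("all pairwise distances are zero")
  D[D < eps] <- eps
  diag(D) <- 0
  csum <- sum(D[upper.tri(D)])
  set.seed(seed)
  Y <- tryCatch(suppressWarnings(cmdscale(D, k = out_dim)),
                error = function(e) NULL)
  if (is.null(Y) || ncol(Y) < out_dim) {
    Y <- matrix(rnorm(n * out_dim, sd = mean(D) / 10), n, out_dim)
  }
  Y <- Y + matrix(rnorm(n * out_dim, sd = max(mean(D), 1) * 1e-8),
                  n, out_dim)

  stress_of <- function(Y) {
    d <- as.matrix(dist(Y))
    diag(d) <- 1
    Dd <- D; diag(Dd) <- 1
    sum(((D - d)^2 / Dd)[upper.tri(D)]) / csum
  }

  trace <- stress_of(Y)
  for (it in seq_len(max_iter)) {
    d <- as.matrix(dist(Y))
    d[d < eps] <- eps
    diag(d) <- 1  # i = j terms are masked below
    D1 <- D
    diag(D1) <- 1
    W1 <- (D - d) / (D1 * d)
    diag(W1) <- 0
    grad <- matrix(0, n, out_dim)
    hess <- matrix(0, n, out_dim)
    for (k in seq_len(out_dim)) {
      dy <- outer(Y[, k], Y[, k], "-")
      grad[, k] <- rowSums(W1 * dy)
      H <- 1 / (D1 * d) * ((D - d) - dy^2 / d * (1 + (D - d) / d))
      diag(H) <- 0
      hess[, k] <- rowSums(H)
    }
    grad <- -2 / csum * grad
    hess <- -2 / csum * hess
    step <- magic * grad / pmax(abs(hess), 1e-30)
    s_prev <- trace[length(trace)]
    lambda <- 1
    repeat {
      Ynew <- Y - lambda * step
      s_new <- stress_of(Ynew)
      if (s_new <= s_prev || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    if (s_new > s_prev) { trace <- c(trace, s_prev); break }
    Y <- Ynew
    trace <- c(trace, s_new)
    if (s_prev - s_new < tol * max(s_prev, 1e-30)) break
  }
  converged <- length(trace) <= max_iter
  structure(list(coords = Y, stress = trace[length(trace)],
                 stress_trace = trace, converged = converged, seed = seed),
            class = "sammon_projection")
}

#' @export
print.sammon_projection <- function(x, ...) {
  cat(sprintf("<sammon_projection> %d points -> %dD | stress %.3g after %d iterations%s\n",
              nrow(x$coords), ncol(x$coords), x$stress,
              length(x$stress_trace) - 1,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Inverse-class-frequency misclassification cost matrix
#'
#' Builds the cost matrix used to counter class imbalance: the cost of
#' misclassifying a sample of class i (any wrong destination) is
#' proportional to `N_total / (K * N_i)`, so minority-class errors are
#' penalized more heavily.  Off-diagonal costs are normalized to mean
#' 1; the diagonal is 0.
#'
#' @param class_counts named vector of per-class sample counts (> 0).
#' @return K x K numeric matrix with dimnames the class names.
#' @export
make_cost_matrix <- function(class_counts) {
  if (length(class_counts) < 2) stop("need >= 2 classes")
  if (any(class_counts <= 0)) stop("zero-count class in cost matrix")
  K <- length(class_counts)
  w <- sum(class_counts) / (K * class_counts)
  C <- matrix(0, K, K, dimnames = list(true = names(class_counts),
                                       pred = names(class_counts)))
  for (i in seq_len(K)) C[i, -i] <- w[i]
  C / mean(C[row(C) != col(C)])
}

#' Grouped cross-validation scheme
#'
#' @param kind `"leave_one_subject_out"` (group = participant) or
#'   `"leave_one_side_out"` (group = participant x side).
#' @param participant_ids participant id per sample.
#' @param sides side per sample (required for leave-one-side-out).
#' @return `cv_scheme`: list with `kind` and the per-sample `group`
#'   factor; every sample belongs to exactly one test fold.
#' @export
make_cv_scheme <- function(kind = c("leave_one_subject_out",
                                    "leave_one_side_out"),
                           participant_ids, sides = NULL) {
  kind <- match.arg(kind)
  group <- if (kind == "leave_one_subject_out") {
    factor(participant_ids)
  } else {
    if (is.null(sides)) stop("leave-one-side-out needs sides")
    factor(paste(participant_ids, sides, sep = ":"))
  }
  structure(list(kind = kind, group = group), class = "cv_scheme")
}

macro_metrics <- function(truth, pred, classes) {
  cm <- table(factor(truth, classes), factor(pred, classes))
  acc <- sum(diag(cm)) / sum(cm)
  sens <- spec <- f1 <- c()
  for (cl in classes) {
    tp <- cm[cl, cl]
    fn <- sum(cm[cl, ]) - tp
    fp <- sum(cm[, cl]) - tp
    tn <- sum(cm) - tp - fn - fp
    if (tp + fn > 0) sens <- c(sens, tp / (tp + fn))
    if (tn + fp > 0) spec <- c(spec, tn / (tn + fp))
    if (tp + fn > 0) {
      prec <- if (tp + fp > 0) tp / (tp + fp) else 0
      rec <- tp / (tp + fn)
      f1 <- c(f1, if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0)
    }
  }
  list(confusion = cm, accuracy = acc,
       sensitivity = mean(sens), specificity = mean(spec), f1 = mean(f1))
}

#' Cost-sensitive random-forest estimation under grouped CV
#'
#' For every fold of the grouped scheme: trains a majority-vote random
#' forest on all other groups with the misclassification costs folded
#' into per-class weights (row means of the cost matrix, i.e. the
#' inverse-frequency penalty of the true class), tunes the number of
#' trees and minimum leaf size by cost-weighted out-of-bag error on
#' the training portion only, then predicts the held-out group.
#' Optionally re-runs probe-based feature selection inside each
#' training fold.  Group leakage (a group in both partitions) is a
#' hard assertion failure.
#'
#' @param table feature table (metadata + features + label).
#' @param label_col label column name.
#' @param scheme a [make_cv_scheme()] result aligned with `table`.
#' @param cost cost matrix from [make_cost_matrix()]; `NULL` for
#'   inverse-frequency costs computed on the training fold;
#'   `FALSE` disables cost weighting.
#' @param hyper_grid data frame of candidate `n_trees` / `min_leaf`
#'   (default `expand.grid(n_trees = c(100, 300, 500), min_leaf =
#'   c(1, 3, 5, 10))`); a single row skips tuning.
#' @param seed RNG seed.
#' @param select_features if `TRUE`, [rank_features()] is refit inside
#'   each training fold and only selected features are used.
#' @return `classification_report`: per-fold metrics, summary
#'   mean/SD/range per metric, pooled confusion matrix, chosen
#'   hyperparameters per fold, class set and seeds.
#' @export
crossvalidated_rf <- function(table, label_col = "label", scheme,
                              cost = NULL, hyper_grid = NULL, seed = 1,
                              select_features = FALSE) {
  stopifnot(inherits(scheme, "cv_scheme"),
            length(scheme$group) == nrow(table))
  y <- factor(table[[label_col]])
  classes <- levels(y)
  cls_groups <- tapply(scheme$group, y, function(g) length(unique(g)))
  vacuous <- names(cls_groups)[cls_groups < 2]
  if (length(vacuous)) {
    warning("class(es) present in < 2 groups (vacuous folds): ",
            paste(vacuous, collapse = ", "))
  }
  if (is.null(hyper_grid)) {
    hyper_grid <- expand.grid(n_trees = c(100, 300, 500),
                              min_leaf = c(1, 3, 5, 10))
  }
  fcols <- feature_columns(table)
  folds <- levels(droplevels(scheme$group))
  per_fold <- list()
  pooled <- matrix(0, length(classes), length(classes),
                   dimnames = list(true = classes, pred = classes))
  set.seed(seed)
  fold_seeds <- sample.int(1e6, length(folds))
  for (fi in seq_along(folds)) {
    g <- folds[fi]
    test_idx <- which(scheme$group == g)
    train_idx <- which(scheme$group != g)
    # structural leakage assertion
    stopifnot(length(intersect(unique(scheme$group[train_idx]),
                               unique(scheme$group[test_idx]))) == 0)
    ytr <- droplevels(y[train_idx])
    if (nlevels(ytr) < 2) stop("class absent from a training fold")
    use_cols <- fcols
    set.seed(fold_seeds[fi])
    if (select_features) {
      rk <- rank_features(table[train_idx, , drop = FALSE], label_col,
                          seed = fold_seeds[fi])
      if (length(rk$selected) >= 2) use_cols <- rk$selected
    }
    Xtr <- as.matrix(table[train_idx, use_cols, drop = FALSE])
    Xte <- as.matrix(table[test_idx, use_cols, drop = FALSE])
    counts <- table(ytr)
    cm_cost <- if (isFALSE(cost)) NULL
      else if (is.null(cost)) make_cost_matrix(counts)
      else cost[levels(ytr), levels(ytr), drop = FALSE]
    # cost-weighted voting: the forest's vote fractions are combined
    # with the cost matrix and the output class minimizes the expected
    # misclassification cost (plain majority vote when cost is FALSE)
    decide <- function(votes) {
      if (is.null(cm_cost)) {
        colnames(votes)[max.col(votes, ties.method = "first")]
      } else {
        expcost <- votes %*% cm_cost[colnames(votes), colnames(votes)]
        colnames(votes)[max.col(-expcost, ties.method = "first")]
      }
    }
    oob_cost <- function(fit) {
      pr <- decide(fit$votes)
      if (is.null(cm_cost)) return(mean(pr != as.character(ytr)))
      mean(cm_cost[cbind(as.character(ytr), pr)])
    }
    best <- NULL; best_err <- Inf; best_hp <- hyper_grid[1, ]
    for (hi in seq_len(nrow(hyper_grid))) {
      fit <- randomForest::randomForest(
        Xtr, ytr, ntree = hyper_grid$n_trees[hi],
        nodesize = hyper_grid$min_leaf[hi])
      err <- oob_cost(fit)
      if (err < best_err) { best <- fit; best_err <- err
                            best_hp <- hyper_grid[hi, ] }
    }
    pred <- decide(predict(best, Xte, type = "vote"))
    mm <- macro_metrics(as.character(y[test_idx]), as.character(pred),
                        classes)
    pooled <- pooled + mm$confusion
    per_fold[[g]] <- data.frame(fold = g, n_test = length(test_idx),
                                accuracy = mm$accuracy,
                                sensitivity = mm$sensitivity,
                                specificity = mm$specificity,
                                f1 = mm$f1,
                                n_trees = best_hp$n_trees,
                                min_leaf = best_hp$min_leaf)
  }
  fold_df <- do.call(rbind, per_fold)
  rownames(fold_df) <- NULL
  summ <- lapply(c("accuracy", "sensitivity", "specificity", "f1"),
                 function(m) {
    v <- fold_df[[m]][is.finite(fold_df[[m]])]
    c(mean = mean(v), sd = sd(v), min = min(v), max = max(v))
  })
  names(summ) <- c("accuracy", "sensitivity", "specificity", "f1")
  structure(list(folds = fold_df, summary = summ, confusion = pooled,
                 classes = classes, scheme = scheme$kind, seed = seed),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %s | %d folds | classes: %s\n",
              x$scheme, nrow(x$folds), paste(x$classes, collapse = ", ")))
  for (m in names(x$summary)) {
    s <- x$summary[[m]]
    cat(sprintf("  %-12s %.2f (%.2f) [%.2f-%.2f]\n", m,
                s["mean"], s["sd"], s["min"], s["max"]))
  }
  invisible(x)
}

#' Classification report as mean (SD) [range] JSON-ready list
#'
#' @param report a `classification_report`.
#' @return nested list `{metric: {mean, sd, min, max}}`.
#' @export
report_summary_list <- function(report) {
  lapply(report$summary, as.list)
}

#' Merge ordinal label classes
#'
#' Relabels according to a (possibly partial) mapping; values not in
#' the mapping pass through unchanged, e.g. mapping
#' `c("3" = ">=3", "4" = ">=3")` merges the top severity scores into
#' one class while leaving lower scores intact.  With `strict = TRUE`
#' every observed value must be mapped.
#'
#' @param table feature table (or any data frame with the label
#'   column).
#' @param mapping named character vector, old value -> new value.
#' @param label_col label column name.
#' @param strict require the mapping to cover all observed values.
#' @return the table with relabeled classes.
#' @export
merge_label_classes <- function(table, mapping, label_col = "label",
                                strict = FALSE) {
  lab <- as.character(table[[label_col]])
  if (strict) {
    un <- setdiff(unique(lab), names(mapping))
    if (length(un)) stop("unmapped label value(s): ",
                         paste(un, collapse = ", "))
  }
  hit <- lab %in% names(mapping)
  lab[hit] <- unname(mapping[lab[hit]])
  table[[label_col]] <- lab
  table
}

#' Inverse-power-law learning curve
#'
#' Fits `acc(n) = a - b * n^(-c)` to accuracy measurements at several
#' training-set sizes by weighted nonlinear least squares (weights
#' default proportional to n), and extrapolates classifier performance
#' to larger samples: predicted accuracy at a query n and the smallest
#' n achieving a target accuracy, with a bootstrap confidence band
#' from resampling per-n replicates.
#'
#' @param ns training-set sizes (>= 4 distinct values).
#' @param accuracies accuracies in `[0, 1]`, same length.
#' @param weights per-observation weights (default `ns`).
#' @param target_acc optional target accuracy to invert for n.
#' @param n_boot bootstrap replicates for the 95% band (0 disables).
#' @return `learning_curve_fit`: list with `par` (a, b, c),
#'   `predict(n)`, `n_for_target`, `plateau` flag, optional
#'   `boot_band` of the parameters.
#' @export
fit_learning_curve <- function(ns, accuracies, weights = NULL,
                               target_acc = NULL, n_boot = 200) {
  stopifnot(length(ns) == length(accuracies),
            all(accuracies >= 0 & accuracies <= 1))
  if (length(unique(ns)) < 4) stop("need >= 4 distinct sample sizes")
  if (is.null(weights)) weights <- ns
  plateau <- sd(accuracies) < 1e-10
  fit1 <- function(ns, acc, w) {
    if (sd(acc) < 1e-10) {
      return(c(a = mean(acc), b = 0, c = 0))
    }
    # log-linear warm start: log(a0 - acc) = log b - c log n
    a0 <- min(1, max(acc) + 0.05)
    pos <- a0 - acc > 1e-8
    lf <- lm(log(a0 - acc[pos]) ~ log(ns[pos]))
    start <- list(a = a0, b = unname(exp(coef(lf)[1])),
                  c = unname(max(0.05, -coef(lf)[2])))
    m <- minpack.lm::nlsLM(acc ~ a - b * I(ns^(-c)),
                           start = start, weights = w,
                           lower = c(a = 0, b = 0, c = 0),
                           upper = c(a = 2, b = 10, c = 5),
                           control = minpack.lm::nls.lm.control(maxiter = 500))
    setNames(coef(m), c("a", "b", "c"))
  }
  par <- tryCatch(fit1(ns, accuracies, weights), error = function(e) {
    stop("learning-curve fit did not converge: ", conditionMessage(e))
  })
  pred <- function(n) {
    p <- unname(par["a"] - par["b"] * n^(-par["c"]))
    if (any(p > 1)) {
      warning("predicted accuracy clipped at 1")
      p <- pmin(p, 1)
    }
    p
  }
  n_for_target <- NULL
  if (!is.null(target_acc)) {
    n_for_target <- if (par["a"] <= target_acc || par["c"] <= 0) {
      Inf
    } else {
      unname((par["b"] / (par["a"] - target_acc))^(1 / par["c"]))
    }
  }
  boot_band <- NULL
  if (n_boot > 0 && !plateau) {
    bp <- matrix(NA_real_, n_boot, 3, dimnames = list(NULL, c("a", "b", "c")))
    by_n <- split(seq_along(ns), ns)
    for (b in seq_len(n_boot)) {
      idx <- unlist(lapply(by_n, function(ii) sample(ii, length(ii),
                                                     replace = TRUE)))
      bp[b, ] <- tryCatch(fit1(ns[idx], accuracies[idx], weights[idx]),
                          error = function(e) rep(NA_real_, 3))
    }
    boot_band <- apply(bp, 2, quantile, c(0.025, 0.975), na.rm = TRUE)
  }
  structure(list(par = par, predict = pred, n_for_target = n_for_target,
                 plateau = plateau, boot_band = boot_band),
            class = "learning_curve_fit")
}

#' @export
print.learning_curve_fit <- function(x, ...) {
  cat(sprintf("<learning_curve_fit> acc(n) = %.4f - %.4f * n^(-%.4f)%s\n",
              x$par["a"], x$par["b"], x$par["c"],
              if (x$plateau) " [plateau]" else ""))
  invisible(x)
}
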