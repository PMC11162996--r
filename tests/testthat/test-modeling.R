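test_that("informative features are ranked on top and probes gate the noise", {
  found <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 120
    tab <- data.frame(label = rep(c("a", "b"), each = n / 2))
    tab$f1 <- ifelse(tab$label == "a", 0, 1) + rnorm(n, 0, 0.1)
    tab$f2 <- ifelse(tab$label == "a", 1, 0) + rnorm(n, 0, 0.1)
    for (j in 3:20) tab[[paste0("f", j)]] <- rnorm(n)
    rk <- rank_features(tab, seed = s)
    all(c("f1", "f2") %in% names(rk$importance)[1:2]) &&
      all(c("f1", "f2") %in% rk$selected)
  }, logical(1))
  expect_gte(sum(found), 9)
})

test_that("pure-noise tables select almost nothing", {
  sizes <- vapply(1:20, function(s) {
    set.seed(s)
    tab <- as.data.frame(matrix(rnorm(100 * 60), 100, 60))
    tab$label <- rep(c("a", "b"), 50)
    length(rank_features(tab, n_trees = 300, seed = s)$selected)
  }, numeric(1))
  expect_gte(mean(sizes <= 0.05 * 60), 0.9)
})

test_that("duplicated feature columns do not break the ranking", {
  set.seed(4)
  tab <- data.frame(label = rep(c("a", "b"), each = 30),
                    f1 = rnorm(60), f2 = rnorm(60))
  tab$f1_copy <- tab$f1
  rk <- rank_features(tab, seed = 1)
  expect_true(all(is.finite(rk$importance)))
  expect_length(rk$importance, 3)
  tab$label <- "a"
  expect_error(rank_features(tab, seed = 1), "2 label classes")
})

test_that("Sammon projection reaches isometric configurations", {
  set.seed(2)
  B <- matrix(rnorm(50 * 3), 3, 50)
  X <- matrix(rnorm(40 * 3), 40, 3) %*% B   # exactly 3-D in a 50-D space
  s <- sammon_map(X, seed = 1)
  expect_lt(s$stress, 1e-4)
  expect_true(all(diff(s$stress_trace) <= 1e-12))

  # 4-point regular simplex embeds exactly; distances within 1%
  X4 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
              c(0.5, sqrt(3) / 6, sqrt(6) / 3))
  s4 <- sammon_map(X4, seed = 1)
  d <- dist(s4$coords)
  expect_lt(max(abs(d - dist(X4)) / dist(X4)), 0.01)
})

test_that("Sammon stress is invariant under rigid motion and handles duplicates", {
  set.seed(5)
  X <- matrix(rnorm(30 * 8), 30, 8)
  s <- sammon_map(X, max_iter = 80, seed = 2)
  # rotate + translate the output: stress unchanged
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  Y2 <- s$coords %*% Q + matrix(5, nrow(s$coords), 3, byrow = TRUE)
  stress_of <- function(Y, X) {
    D <- as.matrix(dist(X)); d <- as.matrix(dist(Y))
    ut <- upper.tri(D)
    sum((D[ut] - d[ut])^2 / D[ut]) / sum(D[ut])
  }
  expect_equal(stress_of(Y2, X), s$stress, tolerance = 1e-9)

  Xd <- rbind(X[1:10, ], X[1, ])
  sd2 <- sammon_map(Xd, max_iter = 60, seed = 1)
  expect_lt(max(abs(sd2$coords[11, ] - sd2$coords[1, ])), 1e-6)

  expect_error(sammon_map(matrix(1, 5, 3)), "all pairwise")
})

test_that("Sammon final stress is competitive with the reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(6)
  X <- matrix(rnorm(40 * 10), 40, 10)
  ours <- sammon_map(X, max_iter = 200, seed = 3)
  ref <- MASS::sammon(dist(X), k = 3, trace = FALSE)
  # MASS reports stress with the same normalization
  expect_lt(ours$stress, ref$stress * 1.10 + 1e-6)
})

test_that("cost matrices encode inverse class frequency", {
  C <- make_cost_matrix(c(a = 50, b = 50))
  expect_true(all(C[row(C) != col(C)] == 1))
  C2 <- make_cost_matrix(c(maj = 90, min = 10))
  expect_equal(C2["min", "maj"] / C2["maj", "min"], 9)
  expect_equal(mean(C2[row(C2) != col(C2)]), 1)
  expect_equal(unname(diag(C2)), c(0, 0))
  expect_error(make_cost_matrix(c(a = 10)), "2 classes")
  expect_error(make_cost_matrix(c(a = 10, b = 0)), "zero-count")
})

test_that("label merging is partial by default and strict on request", {
  tab <- data.frame(label = c("0", "1", "3", "4"))
  merged <- merge_label_classes(tab, c("3" = ">=3", "4" = ">=3"))
  expect_setequal(unique(merged$label), c("0", "1", ">=3"))
  expect_false("4" %in% merged$label)
  expect_equal(merge_label_classes(tab, c("0" = "0", "1" = "1",
                                          "3" = "3", "4" = "4"))$label,
               tab$label)
  expect_error(
    merge_label_classes(tab, c("3" = ">=3"), strict = TRUE), "unmapped")
})

test_that("grouped CV partitions samples exactly once and never leaks", {
  co <- upper_cohort_small()
  ft <- co$features
  sch <- make_cv_scheme("leave_one_side_out", ft$participant_id, ft$side)
  rep <- crossvalidated_rf(ft, "label", sch,
                           hyper_grid = data.frame(n_trees = 150,
                                                   min_leaf = 3),
                           seed = 2)
  expect_equal(nrow(rep$folds), 20)  # 10 subjects x 2 sides
  expect_equal(sum(rep$folds$n_test), nrow(ft))
  expect_equal(sum(rep$confusion), nrow(ft))
  # separable by construction
  expect_gte(rep$summary$accuracy["mean"], 0.9)
  # report identities
  expect_equal(rep$summary$accuracy[["mean"]],
               mean(rep$folds$accuracy))
  for (m in rep$summary) {
    expect_true(all(m >= 0 & m <= 1 | is.na(m)))
  }
})

test_that("subject-level folds match the subject count", {
  co <- gait_cohort_small()
  gf <- co$features
  sch <- make_cv_scheme("leave_one_subject_out", gf$participant_id)
  rep <- crossvalidated_rf(gf, "label", sch,
                           hyper_grid = data.frame(n_trees = 200,
                                                   min_leaf = 3),
                           seed = 3)
  expect_equal(nrow(rep$folds), length(unique(gf$participant_id)))
  expect_equal(sum(diag(rep$confusion)) / sum(rep$confusion),
               sum(rep$folds$accuracy * rep$folds$n_test) / nrow(gf))
})

test_that("learning curves invert noiseless data and flag plateaus", {
  ns <- c(25, 50, 100, 200, 400)
  acc <- 0.9 - 0.5 * ns^(-0.5)
  fit <- fit_learning_curve(ns, acc, n_boot = 0)
  expect_equal(unname(fit$par), c(0.9, 0.5, 0.5), tolerance = 1e-4)
  expect_equal(fit$predict(100), 0.85, tolerance = 1e-4)

  fit2 <- fit_learning_curve(ns, acc, target_acc = 0.85, n_boot = 50)
  expect_equal(fit2$n_for_target, 100, tolerance = 0.01)
  expect_true(all(is.finite(fit2$boot_band)))

  flat <- fit_learning_curve(ns, rep(0.8, 5), n_boot = 0)
  expect_true(flat$plateau)
  expect_equal(unname(flat$par["c"]), 0)

  expect_error(fit_learning_curve(c(10, 20, 30), c(.5, .6, .7)),
               "4 distinct")
})
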