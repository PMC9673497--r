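test_that("percentile normalisation clamps and scales", {
  x <- matrix(0:100, ncol = 1, dimnames = list(NULL, "f"))
  b <- fit_normalizer(x)
  expect_equal(unname(b$lb), 5)
  expect_equal(unname(b$ub), 95)
  expect_equal(as.numeric(apply_normalizer(matrix(c(96, 4, 50), 3), b)),
               c(1, 0, 0.5))
  # constant feature maps to zero and is flagged
  bc <- fit_normalizer(matrix(rep(2, 10), 10))
  expect_true(bc$constant)
  expect_equal(as.numeric(apply_normalizer(matrix(c(1, 2, 3), 3), bc)),
               c(0, 0, 0))
  expect_error(fit_normalizer(matrix(numeric(0), 0, 1)), "empty")
})

test_that("undersampling balances deterministically", {
  set.seed(1)
  labels <- c(rep(TRUE, 620), rep(FALSE, 874))
  idx <- undersample(labels, seed = 3)
  expect_identical(sum(labels[idx]), 620L)
  expect_identical(sum(!labels[idx]), 620L)
  expect_identical(idx, undersample(labels, seed = 3))
  expect_false(identical(idx, undersample(labels, seed = 4)))
  lab10 <- rep(c(TRUE, FALSE), each = 10)
  expect_identical(undersample(lab10, 1), seq_len(20L))
  expect_error(undersample(rep(TRUE, 5), 1), "empty")
})

test_that("AUC is a rank statistic", {
  s <- c(0.9, 0.8, 0.1, 0.3)
  l <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(auc_score(s, l), 1)
  expect_equal(auc_score(1 - s, l), 0)
  set.seed(2)
  s2 <- runif(60)
  l2 <- runif(60) > 0.5
  expect_equal(auc_score(s2, l2), auc_score(qlogis(s2), l2)) # monotone map
  # against the Wilcoxon oracle
  w <- stats::wilcox.test(s2[l2], s2[!l2], exact = FALSE, correct = FALSE)
  expect_equal(auc_score(s2, l2),
               unname(w$statistic) / (sum(l2) * sum(!l2)))
})

test_that("evaluation metrics match their closed forms", {
  s <- c(0.9, 0.8, 0.7, 0.1)
  l <- c(TRUE, FALSE, TRUE, FALSE)
  ev <- evaluate_predictions(s, l, 0.65)
  expect_equal(ev$sensitivity, 1)   # 0.9, 0.7 called positive
  expect_equal(ev$specificity, 0.5) # 0.8 is a false positive
  expect_equal(ev$auc, 0.75)        # one discordant pair of four
  expect_equal(mcc_value(2, 1, 2, 0), 4 / sqrt(36))
  expect_equal(mcc_value(0, 0, 0, 0), 0)
  expect_equal(sn_n(c(0.9, 0.8, 0.1), c(TRUE, TRUE, FALSE), 2), 1)
  expect_error(sn_n(c(0.9), TRUE, 5), "exceeds")
  # perfect scores
  ev2 <- evaluate_predictions(c(1, 0, 1, 0), l, 0.5)
  expect_equal(ev2$mcc, 1)
  expect_equal(ev2$auc, 1)
})

test_that("MCC threshold search equals exhaustive enumeration", {
  set.seed(4)
  for (i in 1:25) {
    n <- sample(5:30, 1)
    s <- round(runif(n), 2)
    l <- runif(n) > 0.4
    if (length(unique(l)) < 2) next
    th <- max_mcc_threshold(s, l)
    mcc_at <- function(t) {
      p <- s >= t
      mcc_value(sum(p & l), sum(p & !l), sum(!p & !l), sum(!p & l))
    }
    # exhaustive: every value strictly between consecutive distinct scores
    su <- sort(unique(s))
    cands <- if (length(su) < 2) su else (su[-1] + su[-length(su)]) / 2
    best <- max(vapply(cands, mcc_at, numeric(1)))
    expect_equal(mcc_at(th), best)
    # ties resolved toward the smaller threshold
    expect_equal(th, cands[which(vapply(cands, mcc_at, numeric(1)) >=
                                   best - 1e-12)][1])
  }
})

test_that("cross-validation scores separable data and respects folds", {
  set.seed(6)
  n <- 160
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- X[, 1] * 2 + rnorm(n, 0, 0.2) > 0
  plan <- make_cv_plan(y, 5, 9)
  expect_identical(sort(unique(plan$fold)), 1:5)
  # stratification: each fold has both classes
  for (f in 1:5) expect_gt(min(table(y[plan$fold == f])), 0)
  cv <- cross_val_scores(X, y, plan, classifier_spec("svm_rbf"))
  expect_gte(cv$auc, 0.95)
  expect_true(all(cv$scores >= 0 & cv$scores <= 1))
  # shuffled labels give chance performance across seeds
  set.seed(7)
  aucs <- replicate(10, {
    ys <- sample(y)
    cross_val_scores(X, ys, make_cv_plan(ys, 5, 1),
                     classifier_spec("knn", k = 10))$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.08)
})

test_that("fold-internal normalisation differs from leaked normalisation", {
  set.seed(8)
  n <- 60
  X <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "f"))
  y <- X[, 1] > 0
  # an extreme outlier confined to one fold shifts the leaked percentiles
  X[1, 1] <- 1e4
  plan <- make_cv_plan(y, 3, 2)
  cv <- cross_val_scores(X, y, plan, classifier_spec("knn", k = 5))
  leaked_bounds <- fit_normalizer(X)
  leaked <- numeric(n)
  for (f in 1:3) {
    te <- plan$fold == f
    Xl <- apply_normalizer(X, leaked_bounds)
    model <- train_classifier(classifier_spec("knn", k = 5),
                              Xl[!te, , drop = FALSE], y[!te])
    leaked[te] <- predict_scores(model, Xl[te, , drop = FALSE])
  }
  expect_false(isTRUE(all.equal(cv$scores, leaked)))
})

test_that("KNN and random forest honour their contracts", {
  set.seed(9)
  n <- 120
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- rowSums(X[, 1:2]) > 0
  plan <- make_cv_plan(y, 5, 3)
  expect_gt(cross_val_scores(X, y, plan, classifier_spec("knn"))$auc, 0.9)
  expect_error(train_classifier(classifier_spec("knn", k = 500), X, y),
               "larger")
  # k = 1 on a duplicated training point returns that point's label
  m1 <- train_classifier(classifier_spec("knn", k = 1), X, y)
  expect_equal(predict_scores(m1, X[3, , drop = FALSE]), as.numeric(y[3]))
  # RF: seeded repeats reported with mean and sd
  rf_aucs <- vapply(1:3, function(r) {
    set.seed(100 + r)
    cross_val_scores(X, y, plan,
                     classifier_spec("random_forest", n_trees = 25),
                     train_seed = r)$auc
  }, numeric(1))
  expect_gt(mean(rf_aucs), 0.85)
  expect_true(is.finite(sd(rf_aucs)))
})

test_that("ASI removes noise, keeps signal, and its trajectory is monotone", {
  set.seed(11)
  n <- 220
  inf <- matrix(rnorm(n * 4), n, 4)
  y <- rowSums(inf) + rnorm(n, 0, 0.8) > 0
  X <- cbind(inf, matrix(rnorm(n * 10), n, 10))
  colnames(X) <- c(paste0("sig", 1:4), paste0("noise", 1:10))
  plan <- make_cv_plan(y, 5, 13)
  res <- asi_select(X, y, plan, classifier_spec("svm_rbf"), max_iter = 15)
  expect_gte(sum(grepl("^sig", res$selected)), 3)
  expect_lte(sum(grepl("^noise", res$selected)), 4)
  expect_true(all(diff(res$trajectory$auc) >= -1e-12))
  expect_lte(nrow(res$trajectory), 16)
})

test_that("ASI terminates on identical feature copies", {
  set.seed(12)
  n <- 80
  f <- rnorm(n)
  y <- f > 0
  X <- cbind(a = f, b = f, c = f)
  plan <- make_cv_plan(y, 4, 5)
  res <- asi_select(X, y, plan, classifier_spec("knn", k = 5),
                    max_iter = 10)
  expect_gte(length(res$selected), 1)
  expect_true(all(diff(res$trajectory$auc) >= -1e-12))
})

test_that("FFS keeps the top-ranked feature and rejects duplicates", {
  set.seed(14)
  n <- 150
  f <- rnorm(n)
  y <- f + rnorm(n, 0, 0.4) > 0
  X <- cbind(informative = f, copy = f, junk = rnorm(n))
  plan <- make_cv_plan(y, 5, 8)
  res <- ffs_select(X, y, plan, classifier_spec("knn", k = 10))
  expect_identical(res$ranking$feature[1],
                   res$selected[1]) # best single feature first
  expect_true(res$selected[1] %in% c("informative", "copy"))
  expect_false(all(c("informative", "copy") %in% res$selected))
})

test_that("model bundles train, predict, and round-trip through disk", {
  set.seed(15)
  n <- 150
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- X[, 1] + X[, 2] + rnorm(n, 0, 0.4) > 0
  bundle <- train_isg_model(X, y, seed = 3)
  expect_gt(bundle$cv_auc, 0.9)
  expect_true(bundle$threshold > 0 && bundle$threshold < 1)
  s <- predict(bundle, X)
  expect_true(all(s >= 0 & s <= 1))
  dir <- withr::local_tempdir()
  save_model(bundle, dir)
  back <- load_model(dir)
  expect_equal(predict(back, X), s, tolerance = 1e-12)
  expect_equal(back$threshold, bundle$threshold)
})
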