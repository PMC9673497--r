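# Normalisation, class balancing, cross-validation, evaluation metrics and
# the two feature-selection strategies (forward selection and the AUC-driven
# subtractive iteration algorithm).

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Fit percentile normalisation bounds
#'
#' Lower/upper bounds are the 5th and 95th percentiles of each feature,
#' learned on training data only.
#'
#' @param X Numeric matrix (training rows only).
#' @param probs Percentile pair.
#' @return List `lb`, `ub`, `constant` (per-feature logical).
#' @export
fit_normalizer <- function(X, probs = c(0.05, 0.95)) {
  X <- as.matrix(X)
  if (!nrow(X)) stop("empty training values")
  lb <- apply(X, 2L, stats::quantile, probs = probs[1L], names = FALSE)
  ub <- apply(X, 2L, stats::quantile, probs = probs[2L], names = FALSE)
  list(lb = lb, ub = ub, constant = ub <= lb)
}

#' Clamp-and-scale features to \[0, 1\]
#'
#' Values above the upper bound map to 1, below the lower bound to 0,
#' linear in between. Constant features (lb == ub) map to 0.
#'
#' @param X Numeric matrix.
#' @param bounds From [fit_normalizer()].
#' @return Matrix of the same shape with values in \[0, 1\].
#' @export
apply_normalizer <- function(X, bounds) {
  X <- as.matrix(X)
  out <- sweep(X, 2L, bounds$lb, "-")
  out <- sweep(out, 2L, pmax(bounds$ub - bounds$lb, .Machine$double.eps),
               "/")
  out[out < 0] <- 0
  out[out > 1] <- 1
  out[, bounds$constant] <- 0
  out
}

#' Undersample the majority class to a balanced set
#'
#' @param labels Logical vector (`TRUE` = positive).
#' @param seed Integer seed (sampling is deterministic given the seed).
#' @return Sorted integer indices of the balanced subset.
#' @export
undersample <- function(labels, seed = 1L) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) stop("one class is empty")
  minority <- min(n_pos, n_neg)
  maj_idx <- which(labels == (n_pos > n_neg))
  min_idx <- which(labels != (n_pos > n_neg))
  kept <- .with_seed(seed, sample(maj_idx, minority))
  sort(c(min_idx, kept))
}

#' Stratified k-fold cross-validation plan
#'
#' Fold assignments are stratified by class and frozen (the same plan is
#' reused across all feature-selection iterations).
#'
#' @param labels Logical vector.
#' @param k_folds Number of folds.
#' @param seed Integer seed.
#' @return List of class `cv_plan`: `fold` (integer per sample),
#'   `k_folds`, `seed`.
#' @export
make_cv_plan <- function(labels, k_folds = 5L, seed = 1L) {
  labels <- as.logical(labels)
  fold <- integer(length(labels))
  .with_seed(seed, {
    for (cl in c(TRUE, FALSE)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(k_folds), length(idx)))
    }
  })
  structure(list(fold = fold, k_folds = k_folds, seed = seed),
            class = "cv_plan")
}

#' Area under the ROC curve
#'
#' Rank statistic (Mann-Whitney) with midrank tie handling.
#'
#' @param scores Numeric scores.
#' @param labels Logical vector.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) stop("AUC needs both classes")
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Out-of-fold cross-validated scores
#'
#' Each sample is scored by the model trained on the other folds; the
#' normaliser is fitted inside each training fold (no leakage). Features are
#' therefore passed raw.
#'
#' @param X Raw feature matrix.
#' @param labels Logical vector.
#' @param plan A [make_cv_plan()] plan covering all samples.
#' @param spec A [classifier_spec()].
#' @param train_seed Seed fixed before each fold's training (so stochastic
#'   trainers are reproducible and fold results do not depend on evaluation
#'   order).
#' @return List `scores` (out-of-fold, input order) and `auc`.
#' @export
cross_val_scores <- function(X, labels, plan, spec,
                             train_seed = plan$seed) {
  stopifnot(inherits(plan, "cv_plan"), length(plan$fold) == nrow(X))
  labels <- as.logical(labels)
  X <- as.matrix(X)
  scores <- numeric(nrow(X))
  for (f in seq_len(plan$k_folds)) {
    te <- plan$fold == f
    if (length(unique(labels[!te])) < 2L)
      stop("training fold with a single class")
    norm <- fit_normalizer(X[!te, , drop = FALSE])
    Xtr <- apply_normalizer(X[!te, , drop = FALSE], norm)
    Xte <- apply_normalizer(X[te, , drop = FALSE], norm)
    model <- .with_seed(train_seed + f,
                        train_classifier(spec, Xtr, labels[!te]))
    scores[te] <- predict_scores(model, Xte)
  }
  list(scores = scores, auc = auc_score(scores, labels))
}

#' Threshold-dependent and threshold-free evaluation
#'
#' @param scores Scores in \[0, 1\].
#' @param labels Logical vector.
#' @param threshold Decision threshold (score >= threshold is positive).
#' @param sn_n_n Optional `n` for the top-n sensitivity criterion (defaults
#'   to the number of positives).
#' @return List `sensitivity`, `specificity`, `mcc`, `auc`, `sn_n`, `n`,
#'   `threshold`.
#' @export
evaluate_predictions <- function(scores, labels, threshold,
                                 sn_n_n = sum(labels)) {
  labels <- as.logical(labels)
  pred <- scores >= threshold
  tp <- sum(pred & labels)
  fn <- sum(!pred & labels)
  tn <- sum(!pred & !labels)
  fp <- sum(pred & !labels)
  sn <- if (tp + fn > 0) tp / (tp + fn) else 0
  sp <- if (tn + fp > 0) tn / (tn + fp) else 0
  list(sensitivity = sn, specificity = sp,
       mcc = mcc_value(tp, fp, tn, fn),
       auc = auc_score(scores, labels),
       sn_n = sn_n(scores, labels, sn_n_n), n = sn_n_n,
       threshold = threshold)
}

#' Matthews correlation coefficient (0 when a margin is empty)
#' @param tp,fp,tn,fn Confusion-matrix counts.
#' @return MCC in \[-1, 1\].
#' @export
mcc_value <- function(tp, fp, tn, fn) {
  den <- as.numeric(tp + fp) * as.numeric(tp + fn) *
    as.numeric(tn + fp) * as.numeric(tn + fn) # doubles: counts^4 overflows int
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Sensitivity among the n top-scoring samples
#'
#' Ties are broken by descending score then stable input order.
#'
#' @param scores Numeric scores.
#' @param labels Logical vector.
#' @param n Number of top samples.
#' @return Fraction of the top n that are positive.
#' @export
sn_n <- function(scores, labels, n) {
  if (n > length(scores)) stop("n exceeds the number of samples")
  if (n == 0L) return(NaN)
  top <- order(-scores)[seq_len(n)]
  mean(as.logical(labels)[top])
}

#' MCC-maximising decision threshold
#'
#' Candidate thresholds are the midpoints of consecutive distinct scores;
#' ties in MCC are broken toward the smaller threshold.
#'
#' @param scores Scores in \[0, 1\].
#' @param labels Logical vector.
#' @return Threshold value.
#' @export
max_mcc_threshold <- function(scores, labels) {
  labels <- as.logical(labels)
  s <- sort(unique(scores))
  if (length(s) < 2L) return(s[1L])
  cand <- (s[-1L] + s[-length(s)]) / 2
  mccs <- vapply(cand, function(th) {
    pred <- scores >= th
    mcc_value(sum(pred & labels), sum(pred & !labels),
              sum(!pred & !labels), sum(!pred & labels))
  }, numeric(1))
  cand[which.max(mccs)] # which.max returns the first (smallest) maximiser
}

#' AUC-driven subtractive iteration (ASI) feature elimination
#'
#' Per iteration, every feature is provisionally removed from the current
#' set on the frozen cross-validation folds; the disruptive set D collects
#' the features whose individual removal does not decrease the baseline AUC.
#' D is removed simultaneously and the loop stops when D is empty, one
#' feature remains, or `max_iter` is reached. If the simultaneous removal of
#' D would lower the baseline AUC (possible because the per-feature checks
#' are marginal), only the single best removal is applied, which keeps the
#' baseline trajectory non-decreasing.
#'
#' @param X Raw feature matrix with column names.
#' @param labels Logical vector.
#' @param plan Frozen [make_cv_plan()].
#' @param spec A [classifier_spec()] (retrained per candidate evaluation).
#' @param max_iter Safety bound on iterations.
#' @param verbose Print per-iteration progress.
#' @return List `selected` (feature names), `trajectory` (data frame:
#'   `iteration`, `n_features`, `auc`, `mcc`, `n_removed`).
#' @export
asi_select <- function(X, labels, plan, spec, max_iter = 50L,
                       verbose = FALSE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (ncol(X) < 2L) stop("need at least 2 features")
  current <- colnames(X)
  eps <- 1e-12
  cv_auc <- function(feats) {
    cv <- cross_val_scores(X[, feats, drop = FALSE], labels, plan, spec)
    list(auc = cv$auc,
         mcc = {
           th <- max_mcc_threshold(cv$scores, labels)
           ev <- evaluate_predictions(cv$scores, labels, th)
           ev$mcc
         })
  }
  base <- cv_auc(current)
  traj <- data.frame(iteration = 0L, n_features = length(current),
                     auc = base$auc, mcc = base$mcc, n_removed = 0L)
  for (it in seq_len(max_iter)) {
    auc_wo <- vapply(current, function(f)
      cross_val_scores(X[, setdiff(current, f), drop = FALSE],
                       labels, plan, spec)$auc, numeric(1))
    D <- current[auc_wo >= base$auc - eps]
    if (!length(D)) break
    if (length(D) == length(current)) {
      # nothing is individually needed; keep the single most needed feature
      keep <- current[which.min(auc_wo)]
      removed <- length(current) - 1L
      current <- keep
      base <- cv_auc(current)
      traj <- rbind(traj, data.frame(iteration = it, n_features = 1L,
                                     auc = base$auc, mcc = base$mcc,
                                     n_removed = removed))
      break
    }
    candidate <- setdiff(current, D)
    new_eval <- cv_auc(candidate)
    if (new_eval$auc < base$auc - eps) {
      # simultaneous removal hurt; fall back to the best single removal
      drop1 <- current[which.max(auc_wo)]
      candidate <- setdiff(current, drop1)
      new_eval <- cv_auc(candidate)
    }
    removed <- length(current) - length(candidate)
    current <- candidate
    base <- new_eval
    traj <- rbind(traj, data.frame(iteration = it,
                                   n_features = length(current),
                                   auc = base$auc, mcc = base$mcc,
                                   n_removed = removed))
    if (verbose)
      message("ASI iteration ", it, ": ", length(current),
              " features, AUC ", signif(base$auc, 4))
    if (length(current) <= 1L) break
  }
  list(selected = current, trajectory = traj)
}

#' Forward feature selection baseline
#'
#' Features are ranked by single-feature cross-validated AUC (descending,
#' stable) and scanned in order; a feature is kept iff adding it strictly
#' increases the running AUC. The top-ranked feature is always kept.
#'
#' @inheritParams asi_select
#' @return List `selected`, `ranking` (data frame `feature`, `auc`).
#' @export
ffs_select <- function(X, labels, plan, spec) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  single <- vapply(colnames(X), function(f)
    cross_val_scores(X[, f, drop = FALSE], labels, plan, spec)$auc,
    numeric(1))
  ord <- order(-single)
  selected <- colnames(X)[ord[1L]]
  running <- single[ord[1L]]
  for (f in colnames(X)[ord[-1L]]) {
    auc_with <- cross_val_scores(X[, c(selected, f), drop = FALSE],
                                 labels, plan, spec)$auc
    if (auc_with > running) {
      selected <- c(selected, f)
      running <- auc_with
    }
  }
  list(selected = selected,
       ranking = data.frame(feature = colnames(X)[ord],
                            auc = single[ord], row.names = NULL))
}

#' Univariate feature screen
#'
#' Ranks features by their direction-free single-feature AUC (the rank
#' statistic of the raw feature values, `max(AUC, 1 - AUC)`) and keeps the
#' top `n_keep`. A cheap pre-filter applied before the classifier-based
#' selection strategies, in the same spirit as the top-100 pattern cap.
#'
#' @param X Raw feature matrix with column names.
#' @param labels Logical vector.
#' @param n_keep Number of features to keep.
#' @return Character vector of feature names (ranked).
#' @export
screen_features <- function(X, labels, n_keep = 40L) {
  X <- as.matrix(X)
  labels <- as.logical(labels)
  single <- vapply(colnames(X), function(f) {
    a <- auc_score(X[, f], labels)
    max(a, 1 - a)
  }, numeric(1))
  names(sort(single, decreasing = TRUE))[seq_len(min(n_keep, ncol(X)))]
}

#' Train a full model bundle
#'
#' Fits the normaliser on all training rows, trains the classifier on the
#' normalised features, and sets the decision threshold by maximising MCC
#' over the out-of-fold cross-validated scores.
#'
#' @param X Raw feature matrix (training set, typically balanced).
#' @param labels Logical vector.
#' @param spec A [classifier_spec()].
#' @param k_folds,seed Cross-validation plan parameters.
#' @param features Feature subset to use (default: all columns).
#' @return List of class `isg_model_bundle`: `classifier`, `spec`,
#'   `features`, `bounds`, `threshold`, `seed`, `cv_auc`.
#' @export
train_isg_model <- function(X, labels, spec = classifier_spec("svm_rbf"),
                            k_folds = 5L, seed = 1L, features = NULL) {
  X <- as.matrix(X)
  if (is.null(features)) features <- colnames(X)
  X <- X[, features, drop = FALSE]
  labels <- as.logical(labels)
  plan <- make_cv_plan(labels, k_folds, seed)
  cv <- cross_val_scores(X, labels, plan, spec)
  threshold <- max_mcc_threshold(cv$scores, labels)
  bounds <- fit_normalizer(X)
  model <- .with_seed(seed, train_classifier(spec,
                                             apply_normalizer(X, bounds),
                                             labels))
  structure(list(classifier = model, spec = spec, features = features,
                 bounds = bounds, threshold = threshold, seed = seed,
                 cv_auc = cv$auc, cv_scores = cv$scores),
            class = "isg_model_bundle")
}

#' @export
predict.isg_model_bundle <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$features, drop = FALSE]
  predict_scores(object$classifier, apply_normalizer(X, object$bounds))
}

#' Serialise an SVM model bundle to a directory of text files
#' @param bundle An `isg_model_bundle` (SVM only).
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
save_model <- function(bundle, dir) {
  stopifnot(inherits(bundle, "isg_model_bundle"),
            bundle$spec$kind == "svm_rbf")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- bundle$classifier$model
  utils::write.table(
    data.frame(feature = bundle$features, lb = bundle$bounds$lb,
               ub = bundle$bounds$ub),
    file.path(dir, "bounds.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  sv <- as.data.frame(m$sv)
  sv$.coef <- m$coef
  utils::write.table(sv, file.path(dir, "support_vectors.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(kind = bundle$spec$kind, b = m$b, gamma = m$gamma, cost = m$cost,
         platt_A = m$platt[["A"]], platt_B = m$platt[["B"]],
         threshold = bundle$threshold, seed = bundle$seed,
         cv_auc = bundle$cv_auc),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a model bundle written by [save_model()]
#' @param dir Directory path.
#' @return An `isg_model_bundle`.
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  bounds_df <- read_tsv_checked(file.path(dir, "bounds.tsv"),
                                c("feature", "lb", "ub"))
  sv <- read_tsv_checked(file.path(dir, "support_vectors.tsv"))
  coef <- sv$.coef
  svm <- as.matrix(sv[, setdiff(names(sv), ".coef"), drop = FALSE])
  bounds <- list(lb = stats::setNames(bounds_df$lb, bounds_df$feature),
                 ub = stats::setNames(bounds_df$ub, bounds_df$feature),
                 constant = bounds_df$ub <= bounds_df$lb)
  model <- structure(list(kind = "svm_rbf",
                          model = list(sv = svm, coef = coef, b = meta$b,
                                       gamma = meta$gamma, cost = meta$cost,
                                       platt = c(A = meta$platt_A,
                                                 B = meta$platt_B))),
                     class = "isg_classifier")
  structure(list(classifier = model,
                 spec = classifier_spec("svm_rbf", cost = meta$cost,
                                        gamma = meta$gamma),
                 features = bounds_df$feature, bounds = bounds,
                 threshold = meta$threshold, seed = meta$seed,
                 cv_auc = meta$cv_auc),
            class = "isg_model_bundle")
}
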