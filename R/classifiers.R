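# Classifiers used by the machine-learning framework. No SVM/KNN/tree
# library is assumed: the RBF-SVM is trained with a compact SMO solver
# (src/svm_smo.cpp) and scored through a Platt sigmoid; KNN scores are the
# positive fraction among the k nearest training samples; the random forest
# bags depth-limited CART trees with per-node feature subsampling.

#' Describe a classifier
#'
#' @param method `"svm_rbf"`, `"knn"` or `"random_forest"`. (Named `method`
#'   rather than `kind` so that hyperparameters like `k` cannot partially
#'   match it.)
#' @param ... Hyperparameters. SVM: `cost` (default 1), `gamma` (default
#'   `1 / (p * mean feature variance)`). KNN: `k` (default 20). Random
#'   forest: `n_trees` (50), `mtry` (`floor(sqrt(p))`), `max_depth` (10),
#'   `min_node` (5).
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(method = c("svm_rbf", "knn", "random_forest"),
                            ...) {
  method <- match.arg(method)
  structure(list(kind = method, params = list(...)),
            class = "classifier_spec")
}

# Platt's sigmoid fit: P(y=1|f) = 1/(1+exp(A f + B)), Newton iterations with
# the usual smoothed targets.
.platt_fit <- function(f, y) {
  n1 <- sum(y)
  n0 <- sum(!y)
  t <- ifelse(y, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  A <- 0
  B <- log((n0 + 1) / (n1 + 1))
  for (it in 1:100) {
    z <- A * f + B
    p <- 1 / (1 + exp(z))
    # gradient and Hessian of the cross-entropy in (A, B)
    d1 <- t - p
    g <- c(sum(f * d1), sum(d1))
    w <- p * (1 - p)
    H <- matrix(c(sum(f * f * w) + 1e-10, sum(f * w),
                  sum(f * w), sum(w) + 1e-10), 2, 2)
    step <- tryCatch(solve(H, g), error = function(e) c(0, 0))
    A <- A - step[1]
    B <- B - step[2]
    if (sum(abs(step)) < 1e-9) break
  }
  c(A = A, B = B)
}

.platt_prob <- function(f, ab) 1 / (1 + exp(ab[["A"]] * f + ab[["B"]]))

#' Train a classifier
#'
#' @param spec A [classifier_spec()].
#' @param X Numeric matrix of (normalised) features.
#' @param y Logical vector, `TRUE` = positive class.
#' @return Model object of class `isg_classifier`.
#' @export
train_classifier <- function(spec, X, y) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- as.matrix(X)
  y <- as.logical(y)
  if (length(unique(y)) < 2L) stop("training data contains one class")
  p <- spec$params
  model <- switch(spec$kind,
    svm_rbf = {
      cost <- p$cost %||% 1
      vbar <- mean(apply(X, 2L, stats::var))
      gamma <- p$gamma %||% (if (vbar > 0) 1 / (ncol(X) * vbar)
                             else 1 / ncol(X))
      yy <- ifelse(y, 1, -1)
      fit <- svm_smo_train_cpp(X, yy, cost, gamma)
      sv <- which(fit$alpha > 1e-8)
      coef <- fit$alpha[sv] * yy[sv]
      f_tr <- svm_decision_cpp(X[sv, , drop = FALSE], coef, fit$b, gamma, X)
      list(sv = X[sv, , drop = FALSE], coef = coef, b = fit$b,
           gamma = gamma, cost = cost, platt = .platt_fit(f_tr, y))
    },
    knn = {
      k <- p$k %||% 20L
      if (k > nrow(X)) stop("k larger than the training set")
      list(X = X, y = y, k = k)
    },
    random_forest = {
      n_trees <- p$n_trees %||% 50L
      mtry <- p$mtry %||% max(1L, floor(sqrt(ncol(X))))
      max_depth <- p$max_depth %||% 10L
      min_node <- p$min_node %||% 5L
      trees <- lapply(seq_len(n_trees), function(i) {
        boot <- sample.int(nrow(X), replace = TRUE)
        .grow_tree(X[boot, , drop = FALSE], y[boot], mtry,
                   max_depth, min_node)
      })
      list(trees = trees)
    })
  structure(list(kind = spec$kind, model = model), class = "isg_classifier")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Prediction scores in \[0, 1\]
#' @param object An `isg_classifier`.
#' @param X Numeric matrix of (normalised) features.
#' @return Numeric vector of positive-class scores.
#' @export
predict_scores <- function(object, X) {
  stopifnot(inherits(object, "isg_classifier"))
  X <- as.matrix(X)
  m <- object$model
  switch(object$kind,
    svm_rbf = {
      f <- svm_decision_cpp(m$sv, m$coef, m$b, m$gamma, X)
      .platt_prob(f, m$platt)
    },
    knn = {
      d2 <- outer(rowSums(X^2), rowSums(m$X^2), "+") - 2 * X %*% t(m$X)
      apply(d2, 1L, function(row)
        mean(m$y[order(row)[seq_len(m$k)]]))
    },
    random_forest = {
      preds <- vapply(m$trees, function(tr) .predict_tree(tr, X),
                      numeric(nrow(X)))
      if (nrow(X) == 1L) mean(preds) else rowMeans(preds)
    })
}

#' SVM decision values (signed distance scale) for an SVM model
#' @param object An `isg_classifier` of kind `svm_rbf`.
#' @param X Feature matrix.
#' @return Numeric decision values.
#' @export
decision_values <- function(object, X) {
  stopifnot(object$kind == "svm_rbf")
  m <- object$model
  svm_decision_cpp(m$sv, m$coef, m$b, m$gamma, as.matrix(X))
}

# ---- compact CART ---------------------------------------------------------

.gini_split <- function(x, y) {
  o <- order(x)
  xs <- x[o]
  ys <- y[o]
  n <- length(ys)
  cum_pos <- cumsum(ys)
  pos_tot <- cum_pos[n]
  i <- which(diff(xs) > 0)           # split between i and i+1
  if (!length(i)) return(NULL)
  nl <- i
  nr <- n - i
  pl <- cum_pos[i] / nl
  pr <- (pos_tot - cum_pos[i]) / nr
  imp <- nl * pl * (1 - pl) + nr * pr * (1 - pr)
  best <- which.min(imp)
  list(threshold = (xs[i[best]] + xs[i[best] + 1L]) / 2,
       impurity = imp[best] / n)
}

.grow_tree <- function(X, y, mtry, max_depth, min_node) {
  node <- function(idx, depth) {
    py <- mean(y[idx])
    if (depth >= max_depth || length(idx) < min_node ||
        py == 0 || py == 1)
      return(list(leaf = TRUE, prob = py))
    feats <- sample.int(ncol(X), min(mtry, ncol(X)))
    best <- NULL
    for (f in feats) {
      sp <- .gini_split(X[idx, f], y[idx])
      if (!is.null(sp) && (is.null(best) || sp$impurity < best$impurity)) {
        best <- sp
        best$feature <- f
      }
    }
    if (is.null(best)) return(list(leaf = TRUE, prob = py))
    left <- idx[X[idx, best$feature] <= best$threshold]
    right <- setdiff(idx, left)
    if (!length(left) || !length(right))
      return(list(leaf = TRUE, prob = py))
    list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
         left = node(left, depth + 1L), right = node(right, depth + 1L))
  }
  node(seq_len(nrow(X)), 0L)
}

.predict_tree <- function(tree, X) {
  out <- numeric(nrow(X))
  walk <- function(nd, idx) {
    if (!length(idx)) return(invisible())
    if (nd$leaf) {
      out[idx] <<- nd$prob
      return(invisible())
    }
    go_left <- X[idx, nd$feature] <= nd$threshold
    walk(nd$left, idx[go_left])
    walk(nd$right, idx[!go_left])
  }
  walk(tree, seq_len(nrow(X)))
  out
}
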