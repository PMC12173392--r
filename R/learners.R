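# In-package learners. The environment ships no SVM/tree/forest/boosting
# R packages, so the four classifier families are implemented here from
# their standard formulations:
#  - soft-margin SVM, RBF kernel, solved by sequential minimal optimization
#  - CART decision tree (Gini impurity)
#  - random forest = bagged CART with per-split feature subsampling
#  - gradient boosting with logistic loss and second-order leaf weights
# All operate on a plain numeric matrix X (n x p) and labels y in {0, 1}.

## ---- RBF-kernel SVM via SMO -----------------------------------------------

.rbf_kernel <- function(A, B, gamma) {
  # exp(-gamma * ||a - b||^2) for all row pairs
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, `+`) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

# Sequential minimal optimization for the dual of the C-SVM:
#   max_a sum(a) - 1/2 sum_ij a_i a_j y_i y_j K_ij,  0 <= a_i <= C,  sum a_i y_i = 0
# Deterministic: the second index is chosen by the max |E1 - E2| heuristic.
.svm_fit <- function(X, y01, C = 1, gamma = 0.1, tol = 1e-3,
                     max_passes = 200L) {
  n <- nrow(X)
  y <- ifelse(y01 == 1, 1, -1)
  K <- .rbf_kernel(X, X, gamma)
  alpha <- numeric(n)
  b <- 0
  f <- numeric(n)             # f_i = sum_j alpha_j y_j K_ij + b
  E <- f - y
  passes <- 0L
  repeat {
    changed <- 0L
    for (i in seq_len(n)) {
      Ei <- E[i]
      if ((y[i] * Ei < -tol && alpha[i] < C) ||
          (y[i] * Ei > tol && alpha[i] > 0)) {
        j <- which.max(abs(E - Ei))
        if (j == i) next
        Ej <- E[j]
        ai_old <- alpha[i]; aj_old <- alpha[j]
        if (y[i] != y[j]) {
          L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
        } else {
          L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
        }
        if (L >= H) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        aj <- aj_old - y[j] * (Ei - Ej) / eta
        aj <- min(H, max(L, aj))
        if (abs(aj - aj_old) < 1e-7) next
        ai <- ai_old + y[i] * y[j] * (aj_old - aj)
        b1 <- b - Ei - y[i] * (ai - ai_old) * K[i, i] -
          y[j] * (aj - aj_old) * K[i, j]
        b2 <- b - Ej - y[i] * (ai - ai_old) * K[i, j] -
          y[j] * (aj - aj_old) * K[j, j]
        b_new <- if (ai > 0 && ai < C) b1
        else if (aj > 0 && aj < C) b2
        else (b1 + b2) / 2
        f <- f + (ai - ai_old) * y[i] * K[, i] +
          (aj - aj_old) * y[j] * K[, j] + (b_new - b)
        alpha[i] <- ai; alpha[j] <- aj; b <- b_new
        E <- f - y
        changed <- changed + 1L
      }
    }
    passes <- passes + 1L
    if (changed == 0L || passes >= max_passes) break
  }
  sv <- alpha > 1e-8
  list(sv_x = X[sv, , drop = FALSE],
       sv_coef = (alpha * y)[sv],
       b = b, gamma = gamma, C = C,
       n_sv = sum(sv), converged = passes < max_passes)
}

# decision values: positive -> class 1
.svm_decision <- function(model, X) {
  if (model$n_sv == 0L) return(rep(model$b, nrow(X)))
  K <- .rbf_kernel(X, model$sv_x, model$gamma)
  as.vector(K %*% model$sv_coef) + model$b
}

## ---- CART decision tree ---------------------------------------------------

# Best Gini split of (x columns, y in {0,1}) over the feature subset `cols`.
# Returns NULL when no split improves impurity.
.best_gini_split <- function(X, y, cols, min_samples_split) {
  n <- length(y)
  if (n < min_samples_split) return(NULL)
  n1 <- sum(y); n0 <- n - n1
  if (n1 == 0L || n0 == 0L) return(NULL)
  parent_gini <- 1 - (n1 / n)^2 - (n0 / n)^2
  best <- NULL; best_gain <- 1e-12
  for (jc in cols) {
    x <- X[, jc]
    ord <- order(x)
    xs <- x[ord]; ys <- y[ord]
    distinct <- which(diff(xs) > 0)
    if (!length(distinct)) next
    c1 <- cumsum(ys)                      # class-1 count in left part
    nl <- distinct                        # left sizes at each cut
    l1 <- c1[distinct]; l0 <- nl - l1
    nr <- n - nl; r1 <- n1 - l1; r0 <- nr - r1
    gl <- 1 - (l1 / nl)^2 - (l0 / nl)^2
    gr <- 1 - (r1 / nr)^2 - (r0 / nr)^2
    gain <- parent_gini - (nl * gl + nr * gr) / n
    k <- which.max(gain)
    if (gain[k] > best_gain) {
      best_gain <- gain[k]
      best <- list(feature = jc,
                   threshold = (xs[distinct[k]] + xs[distinct[k] + 1L]) / 2)
    }
  }
  best
}

# Recursive CART builder. mtry = number of candidate features per split
# (p for a plain tree, ~sqrt(p) inside a forest; subset drawn from the
# current RNG stream). Nodes are rows of a flat data frame.
.tree_fit <- function(X, y, max_depth = 5L, min_samples_split = 2L,
                      mtry = ncol(X)) {
  nodes <- list()
  grow <- function(idx, depth) {
    node_id <- length(nodes) + 1L
    prob1 <- mean(y[idx])
    node <- list(feature = NA_integer_, threshold = NA_real_,
                 left = NA_integer_, right = NA_integer_, prob1 = prob1)
    nodes[[node_id]] <<- node
    if (depth >= max_depth || length(idx) < min_samples_split ||
        prob1 == 0 || prob1 == 1)
      return(node_id)
    cols <- if (mtry >= ncol(X)) seq_len(ncol(X))
    else sort(sample.int(ncol(X), mtry))
    sp <- .best_gini_split(X[idx, , drop = FALSE], y[idx], cols,
                           min_samples_split)
    if (is.null(sp)) return(node_id)
    go_left <- X[idx, sp$feature] <= sp$threshold
    if (!any(go_left) || all(go_left)) return(node_id)
    nodes[[node_id]]$feature <<- sp$feature
    nodes[[node_id]]$threshold <<- sp$threshold
    nodes[[node_id]]$left <<- grow(idx[go_left], depth + 1L)
    nodes[[node_id]]$right <<- grow(idx[!go_left], depth + 1L)
    node_id
  }
  grow(seq_along(y), 0L)
  list(feature = vapply(nodes, `[[`, 0L, "feature"),
       threshold = vapply(nodes, `[[`, 0, "threshold"),
       left = vapply(nodes, `[[`, 0L, "left"),
       right = vapply(nodes, `[[`, 0L, "right"),
       prob1 = vapply(nodes, `[[`, 0, "prob1"))
}

# probability of class 1 for each row of X
.tree_predict <- function(tree, X) {
  n <- nrow(X)
  out <- numeric(n)
  for (i in seq_len(n)) {
    node <- 1L
    while (!is.na(tree$feature[node])) {
      node <- if (X[i, tree$feature[node]] <= tree$threshold[node])
        tree$left[node] else tree$right[node]
    }
    out[i] <- tree$prob1[node]
  }
  out
}

## ---- random forest --------------------------------------------------------

.forest_fit <- function(X, y, n_estimators = 100L, max_depth = 10L,
                        min_samples_split = 2L,
                        mtry = max(1L, floor(sqrt(ncol(X))))) {
  trees <- vector("list", n_estimators)
  n <- nrow(X)
  for (t in seq_len(n_estimators)) {
    boot <- sample.int(n, n, replace = TRUE)
    trees[[t]] <- .tree_fit(X[boot, , drop = FALSE], y[boot],
                            max_depth = max_depth,
                            min_samples_split = min_samples_split,
                            mtry = mtry)
  }
  list(trees = trees)
}

.forest_predict <- function(forest, X) {
  probs <- vapply(forest$trees, function(tr) .tree_predict(tr, X),
                  numeric(nrow(X)))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = nrow(X))
  rowMeans(probs)
}

## ---- gradient boosting (logistic loss, second-order leaves) ---------------

# Regression tree on gradient/hessian pairs with the usual boosted-tree
# split gain  sum_part G^2/(H + lambda); leaf weight -G/(H + lambda).
.gtree_fit <- function(X, g, h, max_depth = 4L, lambda = 1) {
  nodes <- list()
  gain_of <- function(G, H) G^2 / (H + lambda)
  grow <- function(idx, depth) {
    node_id <- length(nodes) + 1L
    G <- sum(g[idx]); H <- sum(h[idx])
    node <- list(feature = NA_integer_, threshold = NA_real_,
                 left = NA_integer_, right = NA_integer_,
                 weight = -G / (H + lambda))
    nodes[[node_id]] <<- node
    if (depth >= max_depth || length(idx) < 2L) return(node_id)
    best_gain <- 1e-12; best <- NULL
    for (jc in seq_len(ncol(X))) {
      x <- X[idx, jc]
      ord <- order(x)
      xs <- x[ord]
      distinct <- which(diff(xs) > 0)
      if (!length(distinct)) next
      gl <- cumsum(g[idx][ord])[distinct]
      hl <- cumsum(h[idx][ord])[distinct]
      gain <- gain_of(gl, hl) + gain_of(G - gl, H - hl) - gain_of(G, H)
      k <- which.max(gain)
      if (gain[k] > best_gain) {
        best_gain <- gain[k]
        best <- list(feature = jc,
                     threshold = (xs[distinct[k]] + xs[distinct[k] + 1L]) / 2)
      }
    }
    if (is.null(best)) return(node_id)
    go_left <- X[idx, best$feature] <= best$threshold
    nodes[[node_id]]$feature <<- best$feature
    nodes[[node_id]]$threshold <<- best$threshold
    nodes[[node_id]]$left <<- grow(idx[go_left], depth + 1L)
    nodes[[node_id]]$right <<- grow(idx[!go_left], depth + 1L)
    node_id
  }
  grow(seq_along(g), 0L)
  list(feature = vapply(nodes, `[[`, 0L, "feature"),
       threshold = vapply(nodes, `[[`, 0, "threshold"),
       left = vapply(nodes, `[[`, 0L, "left"),
       right = vapply(nodes, `[[`, 0L, "right"),
       prob1 = vapply(nodes, `[[`, 0, "weight"))  # reuse routing slot
}

.gboost_fit <- function(X, y, n_estimators = 200L, learning_rate = 0.0045,
                        max_depth = 4L, lambda = 1) {
  p1 <- mean(y)
  p1 <- min(max(p1, 1e-6), 1 - 1e-6)
  f0 <- log(p1 / (1 - p1))
  f <- rep(f0, nrow(X))
  trees <- vector("list", n_estimators)
  for (m in seq_len(n_estimators)) {
    p <- 1 / (1 + exp(-f))
    g <- p - y          # gradient of logistic loss
    h <- p * (1 - p)    # hessian
    tr <- .gtree_fit(X, g, h, max_depth = max_depth, lambda = lambda)
    trees[[m]] <- tr
    f <- f + learning_rate * .tree_predict(tr, X)
  }
  list(f0 = f0, learning_rate = learning_rate, trees = trees)
}

.gboost_decision <- function(model, X) {
  f <- rep(model$f0, nrow(X))
  for (tr in model$trees)
    f <- f + model$learning_rate * .tree_predict(tr, X)
  f   # log-odds of class 1
}
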