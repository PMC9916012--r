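# Internal gradient-boosted-tree engine for binary outcomes on categorical
# predictors.
#
# Friedman gradient boosting with Bernoulli deviance: trees are fit to the
# gradient residual y - p, leaf values are one Newton step
# sum(r) / sum(p(1-p)), shrinkage and bagging as usual. Splits are binary
# partitions of a predictor's categories: categories are ordered by their
# Newton mean and the best prefix split is taken (optimal for squared error,
# the classic CART device for categoricals). Missing values (code 0) are
# routed per split to whichever side yields the larger gain and the chosen
# default direction is stored — the functional equivalent of surrogate
# splits: no imputation, no row deletion.
#
# Predictors are passed as an integer matrix of category codes, 0 = missing.

MAX_LEAF_VALUE <- 4

gbt_fit <- function(X, y, n_rounds, shrinkage = 0.05, max_depth = 3L,
                    min_bucket = 10L, min_split = 20L, bag_fraction = 0.5,
                    watch_rows = NULL, eval_at = integer(0)) {
  n <- length(y)
  ncat <- apply(X, 2L, max)
  p0 <- min(max(mean(y), 1e-6), 1 - 1e-6)
  f0 <- stats::qlogis(p0)
  F <- rep(f0, n)
  trees <- vector("list", n_rounds)
  train_rows <- if (is.null(watch_rows)) seq_len(n) else
    setdiff(seq_len(n), watch_rows)
  watch_auc <- numeric(0)
  for (m in seq_len(n_rounds)) {
    p <- stats::plogis(F)
    r <- y - p
    h <- pmax(p * (1 - p), 1e-12)
    rows <- train_rows
    if (bag_fraction < 1) {
      size <- min(length(train_rows),
                  max(min_split, floor(bag_fraction * length(train_rows))))
      rows <- sort(sample(train_rows, size))
    }
    tree <- gbt_build_tree(X, ncat, r, h, rows, max_depth,
                           min_bucket, min_split)
    F <- F + shrinkage * gbt_predict_tree(tree, X)
    trees[[m]] <- tree
    if (m %in% eval_at) {
      watch_auc <- c(watch_auc,
                     auc_roc(stats::plogis(F[watch_rows]), y[watch_rows]))
    }
  }
  structure(list(f0 = f0, shrinkage = shrinkage, trees = trees,
                 ncat = ncat, watch_auc = watch_auc,
                 eval_at = eval_at),
            class = "gbt_model")
}

gbt_predict <- function(model, X, n_rounds = length(model$trees)) {
  F <- rep(model$f0, nrow(X))
  for (m in seq_len(n_rounds)) {
    F <- F + model$shrinkage * gbt_predict_tree(model$trees[[m]], X)
  }
  stats::plogis(F)
}

# A tree is a list of nodes; node fields:
#   leaf, value | var, goes_left (logical per category), na_left, left, right
gbt_build_tree <- function(X, ncat, r, h, rows, max_depth, min_bucket,
                           min_split) {
  nodes <- list()
  grow <- function(rows, depth) {
    value <- gbt_leaf_value(r[rows], h[rows])
    if (depth >= max_depth || length(rows) < min_split) {
      nodes[[length(nodes) + 1L]] <<- list(leaf = TRUE, value = value)
      return(length(nodes))
    }
    sp <- gbt_best_split(X, ncat, r, h, rows, min_bucket)
    if (is.null(sp)) {
      nodes[[length(nodes) + 1L]] <<- list(leaf = TRUE, value = value)
      return(length(nodes))
    }
    g <- X[rows, sp$var]
    left <- (g != 0L & sp$goes_left[pmax(g, 1L)]) | (g == 0L & sp$na_left)
    idx <- length(nodes) + 1L
    nodes[[idx]] <<- list(leaf = FALSE, var = sp$var,
                          goes_left = sp$goes_left, na_left = sp$na_left)
    l <- grow(rows[left], depth + 1L)
    rgt <- grow(rows[!left], depth + 1L)
    nodes[[idx]]$left <<- l
    nodes[[idx]]$right <<- rgt
    idx
  }
  root <- grow(rows, 0L)
  structure(list(nodes = nodes, root = root), class = "gbt_tree")
}

gbt_leaf_value <- function(r, h) {
  v <- sum(r) / max(sum(h), 1e-12)
  max(min(v, MAX_LEAF_VALUE), -MAX_LEAF_VALUE)
}

gbt_best_split <- function(X, ncat, r, h, rows, min_bucket) {
  rr <- r[rows]
  hh <- h[rows]
  tot_r <- sum(rr)
  tot_h <- sum(hh)
  parent <- tot_r^2 / tot_h
  best <- NULL
  best_gain <- 1e-10
  for (j in seq_len(ncol(X))) {
    g <- X[rows, j]
    obs <- g != 0L
    k <- ncat[j]
    agg <- rowsum(cbind(rr[obs], hh[obs], 1), g[obs])
    cats <- as.integer(rownames(agg))
    if (length(cats) < 2L) next
    mn <- length(g) - sum(obs)
    mr <- tot_r - sum(agg[, 1L])
    mh <- tot_h - sum(agg[, 2L])
    ord <- order(agg[, 1L] / pmax(agg[, 2L], 1e-12))
    cr <- cumsum(agg[ord, 1L])
    ch <- cumsum(agg[ord, 2L])
    cn <- cumsum(agg[ord, 3L])
    m <- length(ord)
    for (i in seq_len(m - 1L)) {
      for (na_left in if (mn > 0L) c(TRUE, FALSE) else FALSE) {
        nl <- cn[i] + if (na_left) mn else 0L
        nr <- (cn[m] + mn) - nl
        if (nl < min_bucket || nr < min_bucket) next
        rl <- cr[i] + if (na_left) mr else 0
        hl <- ch[i] + if (na_left) mh else 0
        gain <- rl^2 / max(hl, 1e-12) +
          (tot_r - rl)^2 / max(tot_h - hl, 1e-12) - parent
        if (gain > best_gain) {
          goes_left <- rep(FALSE, k)
          goes_left[cats[ord[seq_len(i)]]] <- TRUE
          best_gain <- gain
          best <- list(var = j, goes_left = goes_left, na_left = na_left,
                       gain = gain)
        }
      }
    }
  }
  best
}

gbt_predict_tree <- function(tree, X) {
  out <- numeric(nrow(X))
  walk <- function(idx, rows) {
    node <- tree$nodes[[idx]]
    if (node$leaf) {
      out[rows] <<- node$value
      return(invisible(NULL))
    }
    g <- X[rows, node$var]
    left <- (g != 0L & node$goes_left[pmax(g, 1L)]) | (g == 0L & node$na_left)
    if (any(left)) walk(node$left, rows[left])
    if (any(!left)) walk(node$right, rows[!left])
  }
  walk(tree$root, seq_len(nrow(X)))
  out
}

# 5-fold CV selection of the number of boosting rounds by held-out AUC;
# returns the grid point with the highest mean AUC (ties -> fewer rounds).
gbt_cv_rounds <- function(X, y, grid, folds = 5L, ...) {
  n <- length(y)
  fold_id <- sample(rep_len(seq_len(folds), n))
  grid <- sort(unique(as.integer(grid)))
  aucs <- matrix(NA_real_, folds, length(grid))
  for (f in seq_len(folds)) {
    hold <- which(fold_id == f)
    fit <- gbt_fit(X, y, n_rounds = max(grid), watch_rows = hold,
                   eval_at = grid, ...)
    aucs[f, ] <- fit$watch_auc
  }
  mean_auc <- colMeans(aucs)
  grid[which.max(mean_auc)]
}
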