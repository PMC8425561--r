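# Compact regression random forest (bagged CART with per-node feature
# subsampling and OOB permutation importance). Written in-package because no
# random-forest implementation is available in the target library set; it is
# an analysis backend for the sensitivity harness, where the quantity of
# interest is the importance *ranking*, not absolute importances.

# Grow one variance-reduction CART on (X, y). Nodes are stored in parallel
# vectors; leaves have var = 0. Split points are midpoints between distinct
# sorted feature values; best split minimizes total within-child SSE.
grow_tree <- function(X, y, mtry, min_node = 5L, max_nodes = NULL) {
  n <- nrow(X); p <- ncol(X)
  if (is.null(max_nodes)) max_nodes <- 2L * n + 1L
  var <- integer(max_nodes); split <- numeric(max_nodes)
  left <- integer(max_nodes); right <- integer(max_nodes)
  pred <- numeric(max_nodes)
  nnodes <- 0L

  best_split <- function(rows) {
    yr <- y[rows]; nr <- length(yr)
    feats <- sample.int(p, min(mtry, p))
    best <- NULL; best_sse <- Inf
    for (j in feats) {
      xj <- X[rows, j]
      o <- order(xj)
      xs <- xj[o]; ys <- yr[o]
      cs <- cumsum(ys); css <- cumsum(ys^2)
      tot_s <- cs[nr]; tot_ss <- css[nr]
      i <- seq_len(nr - 1L)
      valid <- xs[i] < xs[i + 1L]
      if (!any(valid)) next
      i <- i[valid]
      sse <- (css[i] - cs[i]^2 / i) +
        ((tot_ss - css[i]) - (tot_s - cs[i])^2 / (nr - i))
      k <- which.min(sse)
      if (sse[k] < best_sse) {
        best_sse <- sse[k]
        ii <- i[k]
        best <- list(var = j, split = (xs[ii] + xs[ii + 1L]) / 2)
      }
    }
    best
  }

  new_node <- function() {
    nnodes <<- nnodes + 1L
    nnodes
  }

  grow <- function(rows) {
    id <- new_node()
    yr <- y[rows]
    pred[id] <<- mean(yr)
    if (length(rows) < 2L * min_node || length(unique(yr)) == 1L) {
      var[id] <<- 0L
      return(id)
    }
    sp <- best_split(rows)
    if (is.null(sp)) { var[id] <<- 0L; return(id) }
    go_left <- X[rows, sp$var] <= sp$split
    if (!any(go_left) || all(go_left)) { var[id] <<- 0L; return(id) }
    var[id] <<- sp$var; split[id] <<- sp$split
    left[id] <<- grow(rows[go_left])
    right[id] <<- grow(rows[!go_left])
    id
  }
  grow(seq_len(n))
  list(var = var[1:nnodes], split = split[1:nnodes],
       left = left[1:nnodes], right = right[1:nnodes], pred = pred[1:nnodes])
}

predict_tree <- function(tree, X) {
  node <- rep(1L, nrow(X))
  repeat {
    v <- tree$var[node]
    act <- which(v != 0L)
    if (length(act) == 0L) break
    va <- v[act]
    goes_left <- X[cbind(act, va)] <= tree$split[node[act]]
    node[act] <- ifelse(goes_left, tree$left[node[act]], tree$right[node[act]])
  }
  tree$pred[node]
}

#' Regression random forest
#'
#' Bagged regression trees with `mtry` candidate variables per split,
#' out-of-bag permutation importance (mean increase in OOB MSE when a
#' predictor is permuted) and OOB percentage of variance explained.
#' Deterministic given the caller's RNG state.
#'
#' @param X Numeric matrix of predictors (columns named).
#' @param y Numeric response.
#' @param num_trees Number of bootstrap trees.
#' @param mtry Variables tried at each split.
#' @param min_node Minimum rows in a splittable node.
#' @return List of class `rf_regression`: `trees`, `importance` (named),
#'   `pct_var_explained`, `oob_mse`.
#' @seealso [run_sensitivity()], which uses this as its analysis backend.
#' @export
rf_regression <- function(X, y, num_trees = 500, mtry = max(1, floor(ncol(X) / 3)),
                          min_node = 5L) {
  X <- data.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(n == length(y), n >= 10, p >= 1)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  trees <- vector("list", num_trees)
  imp <- numeric(p)
  imp_n <- integer(p)
  oob_sum <- numeric(n); oob_cnt <- integer(n)
  for (b in seq_len(num_trees)) {
    boot <- sample.int(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), boot)
    tr <- grow_tree(X[boot, , drop = FALSE], y[boot], mtry = mtry,
                    min_node = min_node)
    trees[[b]] <- tr
    if (length(oob) >= 2) {
      Xo <- X[oob, , drop = FALSE]
      po <- predict_tree(tr, Xo)
      oob_sum[oob] <- oob_sum[oob] + po
      oob_cnt[oob] <- oob_cnt[oob] + 1L
      mse0 <- mean((po - y[oob])^2)
      for (j in seq_len(p)) {
        Xp <- Xo
        Xp[, j] <- Xp[sample.int(nrow(Xp)), j]
        msep <- mean((predict_tree(tr, Xp) - y[oob])^2)
        imp[j] <- imp[j] + (msep - mse0)
        imp_n[j] <- imp_n[j] + 1L
      }
    }
  }
  imp <- ifelse(imp_n > 0, imp / pmax(imp_n, 1L), NA_real_)
  names(imp) <- colnames(X)
  seen <- oob_cnt > 0
  oob_mse <- mean((oob_sum[seen] / oob_cnt[seen] - y[seen])^2)
  pve <- 100 * (1 - oob_mse / mean((y - mean(y))^2))
  structure(list(trees = trees, importance = imp, oob_mse = oob_mse,
                 pct_var_explained = pve, var_names = colnames(X)),
            class = "rf_regression")
}

#' @rdname rf_regression
#' @param object An `rf_regression` fit.
#' @param newdata Matrix or data.frame with the training columns.
#' @param ... Unused.
#' @export
predict.rf_regression <- function(object, newdata, ...) {
  X <- data.matrix(newdata)[, object$var_names, drop = FALSE]
  pm <- matrix(vapply(object$trees, function(tr) predict_tree(tr, X),
                      numeric(nrow(X))),
               nrow = nrow(X))
  unname(rowMeans(pm))
}
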