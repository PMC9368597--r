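#' Parameters for the built-in boosted-tree learner
#'
#' @param n_trees number of boosting iterations.
#' @param max_depth maximum tree depth (0 = root-only leaf).
#' @param learning_rate shrinkage step multiplier in (0, 1].
#' @param min_samples_leaf minimum records per leaf.
#' @param subsample fraction of training records drawn (without
#'   replacement) for each tree, in (0, 1].
#' @param seed integer seed for the subsampling stream.
#' @return list of class `ohppfwa_gbdt_params`.
#' @export
gbdt_params <- function(n_trees = 100L, max_depth = 3L, learning_rate = 0.1,
                        min_samples_leaf = 5L, subsample = 1, seed = 0L) {
  if (n_trees < 1L || max_depth < 0L || min_samples_leaf < 1L ||
      learning_rate <= 0 || learning_rate > 1 || subsample <= 0 || subsample > 1) {
    abort("invalid boosting parameters", "ohppfwa_config_error")
  }
  structure(list(n_trees = as.integer(n_trees), max_depth = as.integer(max_depth),
                 learning_rate = learning_rate,
                 min_samples_leaf = as.integer(min_samples_leaf),
                 subsample = subsample, seed = as.integer(seed)),
            class = "ohppfwa_gbdt_params")
}

# Greedy least-squares regression tree. Nodes are parallel vectors;
# node 1 is the root. Split search is exhaustive over axis-aligned
# thresholds (midpoints between consecutive distinct feature values),
# minimizing the summed squared error of the two children. Ties break on
# the lowest feature index, then the smallest threshold, so growth is
# fully deterministic.
grow_tree <- function(X, y, max_depth, min_leaf) {
  nodes <- list(feature = integer(), threshold = numeric(),
                left = integer(), right = integer(),
                value = numeric(), is_leaf = logical())
  new_node <- function() {
    id <- length(nodes$feature) + 1L
    nodes$feature[id] <<- NA_integer_; nodes$threshold[id] <<- NA_real_
    nodes$left[id] <<- NA_integer_; nodes$right[id] <<- NA_integer_
    nodes$value[id] <<- NA_real_; nodes$is_leaf[id] <<- TRUE
    id
  }
  best_split <- function(idx) {
    n <- length(idx)
    if (n < 2L * min_leaf) return(NULL)
    yv <- y[idx]
    best <- NULL
    for (j in seq_len(ncol(X))) {
      xv <- X[idx, j]
      o <- order(xv, method = "radix")
      xs <- xv[o]; ys <- yv[o]
      cs <- cumsum(ys); css <- cumsum(ys * ys)
      tot <- cs[n]; tots <- css[n]
      k <- seq_len(n - 1L)
      valid <- (xs[k] < xs[k + 1L]) & (k >= min_leaf) & ((n - k) >= min_leaf)
      if (!any(valid)) next
      sse <- (css[k] - cs[k]^2 / k) + ((tots - css[k]) - (tot - cs[k])^2 / (n - k))
      sse[!valid] <- Inf
      kb <- which.min(sse)
      if (is.null(best) || sse[kb] < best$sse - 1e-12) {
        best <- list(feature = j, threshold = (xs[kb] + xs[kb + 1L]) / 2,
                     sse = sse[kb])
      }
    }
    base_sse <- sum((yv - mean(yv))^2)
    if (is.null(best) || best$sse >= base_sse - 1e-12) return(NULL)
    best
  }
  build <- function(idx, depth) {
    id <- new_node()
    nodes$value[id] <<- mean(y[idx])
    if (depth < max_depth) {
      sp <- best_split(idx)
      if (!is.null(sp)) {
        go_left <- X[idx, sp$feature] <= sp$threshold
        nodes$is_leaf[id] <<- FALSE
        nodes$feature[id] <<- sp$feature
        nodes$threshold[id] <<- sp$threshold
        nodes$left[id] <<- build(idx[go_left], depth + 1L)
        nodes$right[id] <<- build(idx[!go_left], depth + 1L)
      }
    }
    id
  }
  build(seq_along(y), 0L)
  nodes
}

predict_tree <- function(nodes, X) {
  out <- numeric(nrow(X))
  walk <- function(id, idx) {
    if (!length(idx)) return(invisible())
    if (nodes$is_leaf[id]) {
      out[idx] <<- nodes$value[id]
      return(invisible())
    }
    go_left <- X[idx, nodes$feature[id]] <= nodes$threshold[id]
    walk(nodes$left[id], idx[go_left])
    walk(nodes$right[id], idx[!go_left])
  }
  walk(1L, seq_len(nrow(X)))
  out
}

#' Fit the built-in gradient-boosted regression-tree ensemble
#'
#' Least-squares boosting: the model starts from the target mean and each
#' depth-limited tree is greedily fit to the current residuals, its
#' prediction added with the learning-rate shrinkage. Training mean squared
#' error is non-increasing per iteration (at `subsample = 1`), and fitting
#' is deterministic for a given parameter seed.
#'
#' @param X numeric feature matrix (records x features).
#' @param y numeric target vector (finite).
#' @param params an [gbdt_params()] object.
#' @return object of class `ohppfwa_gbdt` with fields `initial` (target
#'   mean), `trees`, `train_mse` (per-iteration trace) and `params`.
#'   Predict with [predict.ohppfwa_gbdt()].
#' @export
fit_gbdt <- function(X, y, params = gbdt_params()) {
  stopifnot(inherits(params, "ohppfwa_gbdt_params"))
  X <- as.matrix(X)
  if (!all(is.finite(y))) abort("targets must be finite", "ohppfwa_data_error")
  if (nrow(X) < 2L * params$min_samples_leaf) {
    abort("too few records for the requested min_samples_leaf",
          "ohppfwa_data_error")
  }
  initial <- mean(y)
  model <- structure(list(initial = initial, trees = list(),
                          train_mse = numeric(), params = params,
                          feature_names = colnames(X)),
                     class = "ohppfwa_gbdt")
  if (stats::var(y) == 0) {
    warning("constant target: ensemble of zero trees predicting the mean")
    return(model)
  }
  rng <- rng_stream(params$seed)
  current <- rep(initial, nrow(X))
  for (t in seq_len(params$n_trees)) {
    resid <- y - current
    idx <- if (params$subsample < 1) {
      with_stream(rng, sort(sample.int(nrow(X), max(2L * params$min_samples_leaf,
                                                    floor(params$subsample * nrow(X))))))
    } else seq_len(nrow(X))
    tree <- grow_tree(X[idx, , drop = FALSE], resid[idx],
                      params$max_depth, params$min_samples_leaf)
    current <- current + params$learning_rate * predict_tree(tree, X)
    model$trees[[t]] <- tree
    model$train_mse[t] <- mean((y - current)^2)
  }
  model
}

#' Predict from a fitted boosted-tree ensemble
#'
#' @param object an `ohppfwa_gbdt` model.
#' @param newdata numeric matrix with the training feature columns.
#' @param ... unused.
#' @return numeric vector of predictions
#'   (`initial + learning_rate * sum of tree outputs`).
#' @export
predict.ohppfwa_gbdt <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  out <- rep(object$initial, nrow(X))
  for (tree in object$trees) {
    out <- out + object$params$learning_rate * predict_tree(tree, X)
  }
  out
}
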