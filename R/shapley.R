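#' Exact interventional Shapley attributions
#'
#' Explains one prediction as `f(x) = base_value + sum(phi)` via exact
#' coalition enumeration. The value function is interventional: for a
#' coalition S, `v(S)` is the mean prediction over the background sample
#' with the features in S taken from the explained point and the rest from
#' each background row. The Shapley weight
#' `|S|! (m - |S| - 1)! / m!` combines marginal contributions over all
#' `2^m` coalitions, so the efficiency identity holds exactly (up to
#' floating-point error): `base_value` is the background-mean prediction
#' (`v(empty)`) and `base_value + sum(phi)` equals the model output at the
#' explained point.
#'
#' @param predict_fn function taking a numeric matrix, returning a numeric
#'   vector of predictions.
#' @param background numeric matrix of background rows (same columns as
#'   `x`).
#' @param x numeric vector, the explained point.
#' @param exact_limit maximum feature count for enumeration (default 15,
#'   i.e. 32768 coalitions); above it an error directs the caller to
#'   [sampled_shapley()].
#' @return list of class `ohppfwa_attribution`: `base_value`, `phi`
#'   (named per-feature contributions), `prediction`.
#' @examples
#' f <- function(X) 2 * X[, 1] + X[, 2]
#' bg <- matrix(rnorm(20), ncol = 2, dimnames = list(NULL, c("a", "b")))
#' exact_shapley(f, bg, c(a = 1, b = -1))
#' @export
exact_shapley <- function(predict_fn, background, x, exact_limit = 15L) {
  background <- as.matrix(background)
  m <- length(x)
  stopifnot(ncol(background) == m, nrow(background) >= 1L)
  if (m > exact_limit) {
    abort(sprintf(
      "%d features exceed the exact-mode limit of %d; use sampled_shapley()",
      m, exact_limit), "ohppfwa_limit_error")
  }
  nb <- nrow(background)
  ncoal <- 2L^m
  coal <- 0:(ncoal - 1L)
  mask <- vapply(seq_len(m), function(j) bitwAnd(coal, bitwShiftL(1L, j - 1L)) > 0L,
                 logical(ncoal))                       # ncoal x m
  big <- background[rep(seq_len(nb), times = ncoal), , drop = FALSE]
  on_rows <- mask[rep(seq_len(ncoal), each = nb), , drop = FALSE]
  for (j in seq_len(m)) big[on_rows[, j], j] <- x[j]
  preds <- predict_fn(big)
  v <- unname(rowsum(preds, group = rep(seq_len(ncoal), each = nb),
                     reorder = TRUE)[, 1]) / nb

  size <- rowSums(mask)
  w <- exp(lfactorial(size) + lfactorial(m - size - 1) - lfactorial(m))
  phi <- numeric(m)
  for (j in seq_len(m)) {
    s_wo <- which(!mask[, j])                          # coalitions without j
    s_w <- s_wo + 2L^(j - 1L)                          # same + j (1-based)
    phi[j] <- sum(w[s_wo] * (v[s_w] - v[s_wo]))
  }
  names(phi) <- names(x) %||% colnames(background)
  structure(list(base_value = v[1L], phi = phi, prediction = v[ncoal]),
            class = "ohppfwa_attribution")
}

#' Permutation-sampled Shapley attributions
#'
#' Monte-Carlo estimator of the interventional Shapley values: each drawn
#' permutation walks the features in order, switching them from a sampled
#' background row to the explained point, and records the marginal
#' prediction changes. The estimator is unbiased for the exact values;
#' standard errors shrink as `1/sqrt(n_permutations)`. The small closure
#' residual is then distributed over the features proportionally to
#' `|phi|` so that the additive efficiency identity holds exactly.
#'
#' @inheritParams exact_shapley
#' @param n_permutations number of sampled permutations (>= 2).
#' @param seed integer seed; output is deterministic given it.
#' @return `ohppfwa_attribution` with an extra `se` field of per-feature
#'   standard errors.
#' @export
sampled_shapley <- function(predict_fn, background, x, n_permutations = 2000L,
                            seed = 1L) {
  background <- as.matrix(background)
  m <- length(x)
  stopifnot(ncol(background) == m, n_permutations >= 2L)
  np <- as.integer(n_permutations)
  rng <- rng_stream(seed)
  draws <- with_stream(rng, {
    list(rows = sample.int(nrow(background), np, replace = TRUE),
         ranks = t(vapply(seq_len(np), function(i) sample.int(m),
                          integer(m))))                # np x m: rank of feature j
  })
  B <- background[draws$rows, , drop = FALSE]
  kk <- rep(0:m, times = np)                           # prefix length per row
  pp <- rep(seq_len(np), each = m + 1L)
  big <- B[pp, , drop = FALSE]
  for (j in seq_len(m)) {
    on <- draws$ranks[pp, j] <= kk
    big[on, j] <- x[j]
  }
  preds <- predict_fn(big)
  base_row <- (seq_len(np) - 1L) * (m + 1L)
  deltas <- matrix(0, np, m)
  for (j in seq_len(m)) {
    at <- base_row + draws$ranks[, j] + 1L             # row where j switches on
    deltas[, j] <- preds[at] - preds[at - 1L]
  }
  phi <- colMeans(deltas)
  se <- apply(deltas, 2L, stats::sd) / sqrt(np)
  base_value <- mean(predict_fn(background))
  prediction <- predict_fn(matrix(x, nrow = 1L,
                                  dimnames = list(NULL, colnames(background))))[1L]
  residual <- (prediction - base_value) - sum(phi)
  denom <- sum(abs(phi))
  phi <- phi + if (denom > 0) residual * abs(phi) / denom else residual / m
  names(phi) <- names(se) <- names(x) %||% colnames(background)
  structure(list(base_value = base_value, phi = phi, prediction = prediction,
                 se = se),
            class = "ohppfwa_attribution")
}

#' Attribution summary data
#'
#' The numeric content of summary/bar plots: features ranked by mean
#' absolute contribution (descending; ties broken alphabetically) and the
#' signed (feature value, phi) pairs behind a beeswarm rendering.
#'
#' @param attributions list of `ohppfwa_attribution` over records.
#' @param feature_values numeric matrix of the explained points
#'   (records x features), optional.
#' @return list with `ranking` (data.frame `feature`, `mean_abs_phi`,
#'   `rank`) and `pairs` (data.frame `record`, `feature`, `value`, `phi`).
#' @export
summary_data <- function(attributions, feature_values = NULL) {
  if (!length(attributions)) abort("empty attribution set", "ohppfwa_data_error")
  phis <- t(vapply(attributions, function(a) a$phi,
                   numeric(length(attributions[[1L]]$phi))))
  feats <- names(attributions[[1L]]$phi)
  colnames(phis) <- feats
  mean_abs <- colMeans(abs(phis))
  ord <- order(-mean_abs, feats)
  ranking <- data.frame(feature = feats[ord], mean_abs_phi = mean_abs[ord],
                        rank = seq_along(feats), stringsAsFactors = FALSE)
  rownames(ranking) <- NULL
  pairs <- data.frame(
    record = rep(seq_len(nrow(phis)), times = length(feats)),
    feature = rep(feats, each = nrow(phis)),
    value = if (is.null(feature_values)) NA_real_ else
      as.vector(feature_values[, feats, drop = FALSE]),
    phi = as.vector(phis),
    stringsAsFactors = FALSE
  )
  list(ranking = ranking, pairs = pairs)
}

#' Decision-path data for one attribution
#'
#' The cumulative sequence behind a decision plot: starting from the base
#' value, each step adds one feature's contribution in the given order,
#' ending exactly at the model prediction.
#'
#' @param attribution an `ohppfwa_attribution`.
#' @param order permutation of the feature names (default: decreasing
#'   `|phi|`).
#' @return data.frame with `step` (0 = base), `feature`, `cumulative`.
#' @export
decision_path <- function(attribution, order = NULL) {
  feats <- names(attribution$phi)
  if (is.null(order)) order <- feats[base::order(-abs(attribution$phi))]
  if (!setequal(order, feats) || length(order) != length(feats)) {
    abort("'order' must be a permutation of the feature names",
          "ohppfwa_data_error")
  }
  data.frame(
    step = 0:length(feats),
    feature = c(NA_character_, order),
    cumulative = attribution$base_value + cumsum(c(0, attribution$phi[order])),
    stringsAsFactors = FALSE
  )
}
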