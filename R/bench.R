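#' Model registry for the regression bench
#'
#' The bench runs any set of regressors behind one adapter interface
#' (`fit(X, y, seed)` / `predict(model, X)`). The built-in boosted-tree
#' learner (`"gbdt"`) is always available; single regression tree
#' (`"tree"`, rpart), random forest (`"rf"`, randomForest) and xgboost
#' (`"xgb"`) adapters are added when the corresponding package is
#' installed, and silently skipped (with a warning) otherwise.
#'
#' @param models character vector of adapter names to include.
#' @param params [gbdt_params()] for the built-in learner.
#' @return named list of adapters.
#' @export
model_registry <- function(models = c("gbdt", "tree", "rf", "xgb"),
                           params = gbdt_params()) {
  reg <- list()
  for (m in models) {
    adapter <- switch(m,
      gbdt = list(
        fit = function(X, y, seed) {
          p <- params; p$seed <- as.integer(seed)
          fit_gbdt(X, y, p)
        },
        predict = function(model, X) predict(model, X)
      ),
      tree = if (requireNamespace("rpart", quietly = TRUE)) list(
        fit = function(X, y, seed) {
          df <- data.frame(y = y, X)
          rpart::rpart(y ~ ., data = df, method = "anova",
                       control = rpart::rpart.control(cp = 0.001, xval = 0))
        },
        predict = function(model, X) unname(predict(model, data.frame(X)))
      ),
      rf = if (requireNamespace("randomForest", quietly = TRUE)) list(
        fit = function(X, y, seed) {
          old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
          set.seed(as.integer(seed))
          on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
          randomForest::randomForest(X, y, ntree = 200)
        },
        predict = function(model, X) unname(predict(model, X))
      ),
      xgb = if (requireNamespace("xgboost", quietly = TRUE)) list(
        fit = function(X, y, seed) {
          xgboost::xgb.train(
            params = list(max_depth = 3, eta = 0.1, nthread = 1,
                          seed = as.integer(seed)),
            data = xgboost::xgb.DMatrix(X, label = y), nrounds = 100,
            verbose = 0)
        },
        predict = function(model, X) predict(model, xgboost::xgb.DMatrix(X))
      ),
      abort(sprintf("unknown model adapter '%s'", m), "ohppfwa_config_error")
    )
    if (is.null(adapter)) {
      warning(sprintf("adapter '%s' skipped: package not installed", m))
    } else {
      reg[[m]] <- adapter
    }
  }
  if (!length(reg)) abort("registry is empty", "ohppfwa_config_error")
  reg
}

bench_targets <- function(records, scenario, part = NULL) {
  if (scenario == "interval") {
    records$target_interval
  } else {
    records[[paste0("next_score_", part)]]
  }
}

eval_one <- function(adapter, name, X, y, train_idx, test_idx, folds, seed) {
  res <- data.frame(Model = name, RMSLE = NA_real_, R2 = NA_real_,
                    MAE = NA_real_, CV_R2_mean = NA_real_, CV_R2_sd = NA_real_,
                    status = "ok", stringsAsFactors = FALSE)
  tryCatch({
    model <- adapter$fit(X[train_idx, , drop = FALSE], y[train_idx], seed)
    pred <- adapter$predict(model, X[test_idx, , drop = FALSE])
    m <- suppressWarnings(regression_metrics(y[test_idx], pred))
    res$RMSLE <- m$rmsle; res$R2 <- m$r2; res$MAE <- m$mae
    cv <- numeric()
    for (f in seq_along(folds)) {
      hold <- folds[[f]]
      fit_idx <- setdiff(train_idx, hold)
      hold <- intersect(hold, train_idx)
      if (length(hold) < 2L || length(fit_idx) < 10L) next
      fm <- adapter$fit(X[fit_idx, , drop = FALSE], y[fit_idx], seed + f)
      fp <- adapter$predict(fm, X[hold, , drop = FALSE])
      cv <- c(cv, suppressWarnings(regression_metrics(y[hold], fp))$r2)
    }
    if (length(cv)) {
      res$CV_R2_mean <- mean(cv)
      res$CV_R2_sd <- stats::sd(cv)
    }
    res
  }, error = function(e) {
    res$status <- paste("failed:", conditionMessage(e))
    res
  })
}

#' Run the two-scenario regression benchmark
#'
#' Fits every registry model on the training side of the split, reports
#' test-set RMSLE / R2 / MAE and worker-disjoint cross-validated R2
#' (mean and sd over folds), in the published result-table layout. The
#' `"interval"` scenario predicts weeks to the next appointment; the
#' `"severity"` scenario fits one model per body part predicting that
#' part's next-visit score, trained only on records where the part has a
#' positive score history (current or next visit).
#'
#' @param registry a [model_registry()].
#' @param records record table from [assemble_features()], with encoded
#'   categoricals.
#' @param plan an `ohppfwa_split_plan`.
#' @param folds worker-disjoint folds from [make_folds()].
#' @param scenario `"interval"` or `"severity"`.
#' @param use_categoricals include worker attributes as features.
#' @param seed integer seed forwarded to adapters.
#' @return `"interval"`: one data.frame (columns Model, RMSLE, R2, MAE,
#'   CV_R2_mean, CV_R2_sd, status). `"severity"`: named list of 14 such
#'   data.frames, one per body part.
#' @export
evaluate_models <- function(registry, records, plan, folds,
                            scenario = c("interval", "severity"),
                            use_categoricals = TRUE, seed = 1L) {
  scenario <- match.arg(scenario)
  if (!length(registry)) abort("registry is empty", "ohppfwa_config_error")
  X <- feature_matrix(records, use_categoricals)
  id <- records$record_id
  tr <- match(intersect(plan$train, id), id)
  te <- match(intersect(plan$test, id), id)
  fold_idx <- lapply(folds, function(f) match(intersect(f, id), id))
  if (scenario == "interval") {
    y <- bench_targets(records, "interval")
    out <- do.call(rbind, lapply(names(registry), function(nm) {
      eval_one(registry[[nm]], nm, X, y, tr, te, fold_idx, seed)
    }))
    rownames(out) <- NULL
    return(out)
  }
  parts <- part_ids()
  res <- stats::setNames(vector("list", length(parts)), parts)
  for (p in parts) {
    hist <- records[[paste0("score_", p)]] > 0 |
      records[[paste0("next_score_", p)]] > 0
    keep <- which(hist)
    y <- bench_targets(records, "severity", p)
    tr_p <- intersect(tr, keep); te_p <- intersect(te, keep)
    folds_p <- lapply(fold_idx, function(f) intersect(f, keep))
    if (length(tr_p) < 20L || length(te_p) < 2L) {
      res[[p]] <- data.frame(Model = names(registry), RMSLE = NA_real_,
                             R2 = NA_real_, MAE = NA_real_,
                             CV_R2_mean = NA_real_, CV_R2_sd = NA_real_,
                             status = "skipped: too few records with history",
                             stringsAsFactors = FALSE)
      next
    }
    res[[p]] <- do.call(rbind, lapply(names(registry), function(nm) {
      eval_one(registry[[nm]], nm, X, y, tr_p, te_p, folds_p, seed)
    }))
    rownames(res[[p]]) <- NULL
  }
  res
}

#' Learning curve for one registry model
#'
#' Evaluates the model on a fixed validation set (the plan's test side)
#' while the training set grows through `train_sizes` nested subsets of a
#' seeded shuffle of the training records.
#'
#' @param adapter one registry entry.
#' @param records encoded record table.
#' @param plan an `ohppfwa_split_plan`.
#' @param train_sizes increasing record counts (duplicates are dropped
#'   with a warning; sizes below 10 records are skipped with a warning).
#' @param scenario,use_categoricals,seed as in [evaluate_models()].
#' @return data.frame with `size`, `train_r2`, `valid_r2`.
#' @export
learning_curve <- function(adapter, records, plan, train_sizes,
                           scenario = "interval", use_categoricals = TRUE,
                           seed = 1L) {
  if (anyDuplicated(train_sizes)) {
    warning("duplicate train sizes removed")
    train_sizes <- unique(train_sizes)
  }
  train_sizes <- sort(train_sizes)
  X <- feature_matrix(records, use_categoricals)
  y <- bench_targets(records, scenario)
  id <- records$record_id
  tr <- match(intersect(plan$train, id), id)
  te <- match(intersect(plan$test, id), id)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  tr <- sample(tr)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  rows <- list()
  for (s in train_sizes) {
    if (s < 10L) {
      warning(sprintf("train size %d too small: skipped", s))
      next
    }
    s <- min(s, length(tr))
    sub <- tr[seq_len(s)]
    model <- adapter$fit(X[sub, , drop = FALSE], y[sub], seed)
    tr_m <- suppressWarnings(
      regression_metrics(y[sub], adapter$predict(model, X[sub, , drop = FALSE])))
    va_m <- suppressWarnings(
      regression_metrics(y[te], adapter$predict(model, X[te, , drop = FALSE])))
    rows[[length(rows) + 1L]] <- data.frame(size = s, train_r2 = tr_m$r2,
                                            valid_r2 = va_m$r2)
    if (s == length(tr)) break
  }
  do.call(rbind, rows)
}
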