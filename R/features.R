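#' Assemble model-ready records from scored timelines
#'
#' One record per appointment that has a successor: the features are the
#' current visit's 14 per-part scores plus worker attributes, the targets
#' are the whole-week interval to the next appointment (days / 7, rounded
#' half-up) and the next visit's 14 per-part scores. Workers with a single
#' appointment contribute no records; a worker's final appointment has no
#' targets and is dropped (right-censored, as in the modelling setup).
#'
#' @param scores per-appointment score table with `worker_id`, `date`,
#'   metadata columns and `score_<part>` columns ([score_corpus()] or
#'   [corpus_to_table()] output).
#' @return data.frame of records: `worker_id`, metadata, `score_<part>`
#'   features, `target_interval`, `next_score_<part>` targets.
#' @export
assemble_features <- function(scores) {
  score_cols <- paste0("score_", part_ids())
  stopifnot(all(score_cols %in% names(scores)), "worker_id" %in% names(scores))
  scores$date <- as.Date(scores$date)
  out <- list()
  for (w in unique(scores$worker_id)) {
    tl <- scores[scores$worker_id == w, , drop = FALSE]
    tl <- tl[order(tl$date), , drop = FALSE]
    if (anyDuplicated(tl$date) || is.unsorted(tl$date, strictly = TRUE)) {
      abort(sprintf("non-monotone appointment dates for worker '%s'", w),
            "ohppfwa_data_error")
    }
    if (nrow(tl) < 2L) next
    for (j in seq_len(nrow(tl) - 1L)) {
      rec <- tl[j, setdiff(names(tl), c("total", "wai_category")), drop = FALSE]
      rec$target_interval <- round_half_up(
        as.numeric(tl$date[j + 1L] - tl$date[j]) / 7)
      nxt <- tl[j + 1L, score_cols, drop = FALSE]
      names(nxt) <- paste0("next_", score_cols)
      out[[length(out) + 1L]] <- cbind(rec, nxt)
    }
  }
  if (!length(out)) {
    return(data.frame())
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$record_id <- seq_len(nrow(res))
  res
}

#' Encode categorical worker attributes as stable integer codes
#'
#' The built-in boosted-tree learner consumes numeric features only;
#' categorical attributes (area, function, schedule, gender) are mapped to
#' integer codes from a vocabulary that can be persisted and reapplied so
#' codes stay stable across runs. Unseen levels code as `NA`.
#'
#' @param records data.frame of records.
#' @param vocab existing vocabulary (named list of level vectors) or
#'   `NULL` to build one from the data (sorted unique levels).
#' @param columns categorical columns to encode.
#' @return list with `records` (encoded copy, `<col>_code` columns added)
#'   and `vocab`.
#' @export
encode_categoricals <- function(records, vocab = NULL,
                                columns = c("area", "func", "schedule", "gender")) {
  columns <- intersect(columns, names(records))
  if (is.null(vocab)) {
    vocab <- lapply(records[columns], function(x) sort(unique(as.character(x))))
    names(vocab) <- columns
  }
  for (cc in columns) {
    records[[paste0(cc, "_code")]] <- match(as.character(records[[cc]]), vocab[[cc]])
  }
  list(records = records, vocab = vocab)
}

#' Numeric feature matrix for the learners
#'
#' @param records encoded records ([encode_categoricals()] output).
#' @param use_categoricals include encoded categorical codes and seniority
#'   alongside the 14 part scores.
#' @return numeric matrix with named columns.
#' @export
feature_matrix <- function(records, use_categoricals = TRUE) {
  cols <- paste0("score_", part_ids())
  if (use_categoricals) {
    extra <- intersect(c("seniority_years", "area_code", "func_code",
                         "schedule_code", "gender_code"), names(records))
    cols <- c(cols, extra)
  }
  as.matrix(records[, cols, drop = FALSE])
}

#' Worker-level train/test split
#'
#' Splitting is performed on workers, never records, so no worker's history
#' leaks across the split. Workers are shuffled deterministically by seed
#' and accumulated into the test side until the realized record fraction is
#' as close as possible to the target.
#'
#' @param records record table from [assemble_features()].
#' @param test_fraction target fraction of records in the test side.
#' @param seed integer seed.
#' @return list of class `ohppfwa_split_plan`: `train` / `test` record ids,
#'   `seed`, and `folds` (filled by [make_folds()]).
#' @export
split_by_worker <- function(records, test_fraction = 0.2, seed = 1L) {
  workers <- unique(records$worker_id)
  if (length(workers) < 2L) {
    abort("need at least 2 distinct workers to split", "ohppfwa_split_error")
  }
  if (test_fraction == 0) {
    warning("test_fraction is 0: empty test set")
    return(structure(list(train = records$record_id, test = integer(),
                          folds = NULL, seed = as.integer(seed)),
                     class = "ohppfwa_split_plan"))
  }
  target <- test_fraction * nrow(records)
  counts <- table(records$worker_id)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  shuffled <- sample(workers)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  test_workers <- character()
  cum <- 0
  for (w in shuffled) {
    nw <- as.integer(counts[[w]])
    if (abs(cum + nw - target) < abs(cum - target)) {
      test_workers <- c(test_workers, w)
      cum <- cum + nw
    }
    if (cum >= target) break
  }
  test_idx <- records$record_id[records$worker_id %in% test_workers]
  structure(list(train = setdiff(records$record_id, test_idx),
                 test = test_idx, folds = NULL, seed = as.integer(seed)),
            class = "ohppfwa_split_plan")
}

#' Worker-disjoint cross-validation folds
#'
#' Partitions the training records into `k` folds of near-equal record
#' counts such that all records of one worker fall in exactly one fold
#' (longest-processing-time assignment over shuffled workers).
#'
#' @param records record table.
#' @param plan an `ohppfwa_split_plan` (folds are built over its train
#'   side) or `NULL` to fold all records.
#' @param k number of folds (>= 2, <= number of distinct workers).
#' @param seed integer seed.
#' @return list of `k` integer vectors of record ids, also stored in
#'   `plan$folds` when a plan is supplied.
#' @export
make_folds <- function(records, plan = NULL, k = 10L, seed = 1L) {
  train <- if (is.null(plan)) records else
    records[records$record_id %in% plan$train, , drop = FALSE]
  workers <- unique(train$worker_id)
  if (k < 2L) abort("k must be at least 2 (no held-out fold otherwise)",
                    "ohppfwa_fold_error")
  if (k > length(workers)) {
    abort(sprintf("k = %d exceeds the %d distinct workers", k, length(workers)),
          "ohppfwa_fold_error")
  }
  counts <- table(train$worker_id)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  shuffled <- sample(workers)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  ord <- shuffled[order(-as.integer(counts[shuffled]))]
  fold_of <- stats::setNames(integer(length(ord)), ord)
  load <- integer(k)
  for (w in ord) {
    f <- which.min(load)
    fold_of[[w]] <- f
    load[f] <- load[f] + as.integer(counts[[w]])
  }
  folds <- lapply(seq_len(k), function(f) {
    train$record_id[train$worker_id %in% names(fold_of)[fold_of == f]]
  })
  folds
}

#' Persist / load a split plan as JSON
#' @param plan an `ohppfwa_split_plan`.
#' @param path file path.
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = FALSE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  structure(list(train = as.integer(raw$train), test = as.integer(raw$test),
                 folds = if (is.null(raw$folds)) NULL else
                   lapply(raw$folds, as.integer),
                 seed = as.integer(raw$seed)),
            class = "ohppfwa_split_plan")
}
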