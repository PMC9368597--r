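#' Seniority bins for stratified summaries
#'
#' Fixed bins 1-10, 10-20 and >20 years; the boundary values 10 and 20
#' fall in the upper bin.
#'
#' @param years numeric seniority in years.
#' @return factor with levels `"1-10"`, `"10-20"`, `">20"`.
#' @export
seniority_bin <- function(years) {
  cut(years, breaks = c(-Inf, 10, 20, Inf), labels = c("1-10", "10-20", ">20"),
      right = FALSE)
}

#' Per-body-part severity shares within a stratum
#'
#' The pie-chart statistic: each part's percentage of the summed predicted
#' severity over the records of one stratum,
#' `share_p = 100 * sum(pred_p) / sum over all parts`. Shares are
#' non-negative and sum to 100.
#'
#' @param preds numeric matrix of per-part severities (records x 14, part
#'   ids as column names).
#' @param records data.frame aligned with `preds` rows, used to resolve
#'   the stratum.
#' @param dimension `"gender"`, `"seniority"` or `"area"`.
#' @param level stratum level (e.g. `"female"`, `"10-20"`, `"Assembly"`).
#' @return list of class `ohppfwa_stratum_share`: `stratum`, `n_records`,
#'   `shares` (named percentages).
#' @export
severity_shares <- function(preds, records, dimension = c("gender", "seniority", "area"),
                            level) {
  dimension <- match.arg(dimension)
  stopifnot(nrow(preds) == nrow(records))
  member <- switch(dimension,
    gender = records$gender == level,
    seniority = as.character(seniority_bin(records$seniority_years)) == level,
    area = records$area == level
  )
  member <- which(!is.na(member) & member)
  if (!length(member)) {
    abort(sprintf("empty stratum: %s = '%s'", dimension, level),
          "ohppfwa_data_error")
  }
  sub <- preds[member, , drop = FALSE]
  if (any(sub < 0)) abort("predicted severities must be non-negative",
                          "ohppfwa_data_error")
  totals <- colSums(sub)
  shares <- 100 * totals / sum(totals)
  structure(list(stratum = c(dimension = dimension, level = level),
                 n_records = length(member), shares = shares),
            class = "ohppfwa_stratum_share")
}

#' Severity shares over all strata of the standard dimensions
#'
#' @inheritParams severity_shares
#' @return long data.frame: `dimension`, `level`, `n_records`, `part`,
#'   `share`.
#' @export
all_severity_shares <- function(preds, records) {
  rows <- list()
  levels_of <- list(
    gender = sort(unique(records$gender)),
    seniority = levels(seniority_bin(records$seniority_years)),
    area = sort(unique(records$area))
  )
  for (dim in names(levels_of)) {
    for (lv in levels_of[[dim]]) {
      ss <- tryCatch(severity_shares(preds, records, dim, lv),
                     ohppfwa_data_error = function(e) NULL)
      if (is.null(ss)) next
      rows[[length(rows) + 1L]] <- data.frame(
        dimension = dim, level = lv, n_records = ss$n_records,
        part = names(ss$shares), share = unname(ss$shares),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pipeline configuration
#'
#' @param n_workers,seed forwarded to [generator_config()]; both are
#'   required.
#' @param test_fraction,k_folds split parameters.
#' @param models registry adapters to benchmark.
#' @param n_explain number of test records to explain.
#' @param language corpus language.
#' @param shares_from compute severity shares from `"predicted"` next-visit
#'   scores (the reporting convention) or `"observed"` scores
#'   (diagnostics).
#' @param generator extra arguments for [generator_config()].
#' @param gbdt [gbdt_params()] for the built-in learner.
#' @return list of class `ohppfwa_pipeline_config`.
#' @export
pipeline_config <- function(n_workers, seed, test_fraction = 0.2, k_folds = 10L,
                            models = "gbdt", n_explain = 20L, language = "en",
                            shares_from = c("predicted", "observed"),
                            generator = list(),
                            gbdt = gbdt_params(n_trees = 60L)) {
  if (missing(n_workers)) abort("pipeline config is missing 'n_workers'",
                                "ohppfwa_config_error")
  if (missing(seed)) abort("pipeline config is missing 'seed'",
                           "ohppfwa_config_error")
  shares_from <- match.arg(shares_from)
  structure(list(n_workers = n_workers, seed = seed,
                 test_fraction = test_fraction, k_folds = as.integer(k_folds),
                 models = models, n_explain = as.integer(n_explain),
                 language = language, shares_from = shares_from,
                 generator = generator, gbdt = gbdt),
            class = "ohppfwa_pipeline_config")
}

write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the four-phase pipeline end to end
#'
#' Simulate -> extract -> score -> assemble features -> benchmark ->
#' explain -> stratified severity shares, writing every artifact plus a
#' manifest (seed, per-stage row counts, file checksums) to `out_dir`.
#' The run is deterministic per seed; a stage failure halts with the
#' stage name while earlier artifacts are retained.
#'
#' @param config an [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisible list with the in-memory artifacts and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "ohppfwa_pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("ohppfwa")),
                   seed = config$seed, stages = list())
  files <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            "ohppfwa_stage_error")
    })
  }

  lexicon <- load_lexicon()
  corpus <- stage("simulate", {
    gen_args <- c(list(n_workers = config$n_workers, seed = config$seed,
                       language = config$language), config$generator)
    generate_cohort(do.call(generator_config, gen_args), lexicon)
  })
  files["corpus"] <- file.path(out_dir, "corpus.jsonl")
  write_corpus(corpus, files[["corpus"]])
  manifest$stages$simulate <- list(rows = length(corpus))

  profiles <- stage("extract", extract_corpus(corpus, lexicon, config$language))
  files["profiles"] <- write_table(profiles, file.path(out_dir, "profiles.csv"))
  files["extract_report"] <- write_table(attr(profiles, "report"),
                                         file.path(out_dir, "extract_report.csv"))
  manifest$stages$extract <- list(rows = nrow(profiles),
                                  unparsed = nrow(attr(profiles, "report")))

  scores <- stage("score", score_corpus(corpus, lexicon, config$language))
  files["scores"] <- write_table(scores, file.path(out_dir, "scores.csv"))
  manifest$stages$score <- list(rows = nrow(scores))

  enc <- stage("features", {
    records <- assemble_features(scores)
    encode_categoricals(records)
  })
  records <- enc$records
  files["features"] <- write_table(records, file.path(out_dir, "features.csv"))
  files["vocab"] <- file.path(out_dir, "vocab.json")
  jsonlite::write_json(enc$vocab, files[["vocab"]], auto_unbox = FALSE)
  manifest$stages$features <- list(rows = nrow(records))

  bench <- stage("train", {
    plan <- split_by_worker(records, config$test_fraction, config$seed)
    folds <- make_folds(records, plan, k = min(config$k_folds,
                                               length(unique(records$worker_id[
                                                 records$record_id %in% plan$train])) - 1L),
                        seed = config$seed)
    registry <- model_registry(config$models, config$gbdt)
    interval_tab <- evaluate_models(registry, records, plan, folds, "interval",
                                    seed = config$seed)
    severity_tabs <- evaluate_models(registry, records, plan, folds, "severity",
                                     seed = config$seed)
    list(plan = plan, folds = folds, registry = registry,
         interval = interval_tab, severity = severity_tabs)
  })
  files["split"] <- file.path(out_dir, "split.json")
  write_split_plan(bench$plan, files[["split"]])
  files["eval_interval"] <- write_table(bench$interval,
                                        file.path(out_dir, "eval_interval.csv"))
  sev_long <- do.call(rbind, lapply(names(bench$severity), function(p) {
    cbind(part = p, bench$severity[[p]])
  }))
  files["eval_severity"] <- write_table(sev_long,
                                        file.path(out_dir, "eval_severity.csv"))
  manifest$stages$train <- list(train_records = length(bench$plan$train),
                                test_records = length(bench$plan$test),
                                folds = length(bench$folds))

  explained <- stage("explain", {
    X <- feature_matrix(records, use_categoricals = FALSE)
    y <- records$target_interval
    id <- records$record_id
    tr <- match(intersect(bench$plan$train, id), id)
    te <- match(intersect(bench$plan$test, id), id)
    p <- config$gbdt; p$seed <- config$seed
    model <- fit_gbdt(X[tr, , drop = FALSE], y[tr], p)
    bg <- X[tr, , drop = FALSE]
    if (nrow(bg) > 100L) bg <- bg[seq_len(100L), , drop = FALSE]
    pick <- te[seq_len(min(config$n_explain, length(te)))]
    atts <- lapply(pick, function(i) {
      exact_shapley(function(M) predict(model, M), bg, X[i, ])
    })
    list(model = model, records_idx = pick, attributions = atts)
  })
  att_tab <- do.call(rbind, lapply(seq_along(explained$attributions), function(k) {
    a <- explained$attributions[[k]]
    cbind(data.frame(record_id = records$record_id[explained$records_idx[k]],
                     base_value = a$base_value, prediction = a$prediction),
          as.data.frame(as.list(a$phi)))
  }))
  files["attributions"] <- write_table(att_tab,
                                       file.path(out_dir, "attributions.csv"))
  manifest$stages$explain <- list(rows = nrow(att_tab))

  shares <- stage("report", {
    if (config$shares_from == "observed") {
      preds <- as.matrix(records[, paste0("score_", part_ids())])
    } else {
      X <- feature_matrix(records)
      id <- records$record_id
      tr <- match(intersect(bench$plan$train, id), id)
      preds <- vapply(part_ids(), function(pp) {
        yv <- records[[paste0("next_score_", pp)]]
        p <- config$gbdt; p$seed <- config$seed
        mdl <- fit_gbdt(X[tr, , drop = FALSE], yv[tr], p)
        pmax(predict(mdl, X), 0)
      }, numeric(nrow(records)))
    }
    colnames(preds) <- part_ids()
    all_severity_shares(preds, records)
  })
  files["shares"] <- write_table(shares, file.path(out_dir, "shares.csv"))
  manifest$stages$report <- list(rows = nrow(shares))

  manifest$files <- as.list(tools::md5sum(files))
  names(manifest$files) <- names(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(corpus = corpus, profiles = profiles, scores = scores,
                 records = records, bench = bench, explained = explained,
                 shares = shares, manifest = manifest))
}
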