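make_timeline <- function(worker, dates, base = 0.5) {
  sc <- matrix(base, nrow = length(dates), ncol = 14,
               dimnames = list(NULL, paste0("score_", part_ids())))
  cbind(data.frame(worker_id = worker, date = as.Date(dates),
                   area = "Assembly", func = "welder", schedule = "normal",
                   seniority_years = 10, gender = "male",
                   stringsAsFactors = FALSE),
        as.data.frame(sc))
}

test_that("each appointment with a successor yields one record; singletons yield none", {
  tl <- rbind(make_timeline("A", c("2019-01-01", "2019-03-12", "2019-08-01")),
              make_timeline("B", "2019-02-01"))
  recs <- assemble_features(tl)
  expect_equal(nrow(recs), 2L)
  expect_true(all(recs$worker_id == "A"))
  expect_equal(recs$record_id, 1:2)
  # interval: whole weeks, days / 7 rounded half-up
  tl2 <- make_timeline("C", c("2019-01-01", "2019-03-12"))  # 70 days
  expect_equal(assemble_features(tl2)$target_interval, 10)
  tl3 <- make_timeline("D", c("2019-01-01", "2019-01-25"))  # 24 days -> 3.43
  expect_equal(assemble_features(tl3)$target_interval, 3)
})

test_that("next-visit scores are carried as targets", {
  tl <- make_timeline("A", c("2019-01-01", "2019-06-01"))
  tl$score_trunk <- c(1, 2.5)
  recs <- assemble_features(tl)
  expect_equal(recs$score_trunk, 1)
  expect_equal(recs$next_score_trunk, 2.5)
})

test_that("non-monotone or duplicated dates fail naming the worker", {
  tl <- make_timeline("W13", c("2019-05-01", "2019-05-01"))
  expect_error(assemble_features(tl), "W13", class = "ohppfwa_data_error")
})

test_that("splits are worker-disjoint, deterministic and close to the target fraction", {
  recs <- cohort_records(150, 21)
  plan <- split_by_worker(recs, 0.2, seed = 3)
  expect_length(intersect(plan$train, plan$test), 0L)
  expect_setequal(c(plan$train, plan$test), recs$record_id)
  tr_workers <- unique(recs$worker_id[recs$record_id %in% plan$train])
  te_workers <- unique(recs$worker_id[recs$record_id %in% plan$test])
  expect_length(intersect(tr_workers, te_workers), 0L)
  frac <- length(plan$test) / nrow(recs)
  expect_lt(abs(frac - 0.2), 0.05)
  expect_identical(plan, split_by_worker(recs, 0.2, seed = 3))
  expect_false(identical(plan$test, split_by_worker(recs, 0.2, seed = 4)$test))
})

test_that("degenerate splits are handled: zero fraction warns, one worker errors", {
  recs <- cohort_records(150, 21)
  expect_warning(plan0 <- split_by_worker(recs, 0, seed = 1), "empty test")
  expect_length(plan0$test, 0L)
  one <- recs[recs$worker_id == recs$worker_id[1], ]
  expect_error(split_by_worker(one, 0.2, 1), class = "ohppfwa_split_error")
})

test_that("folds partition the training records worker-disjointly", {
  recs <- cohort_records(150, 21)
  plan <- split_by_worker(recs, 0.2, seed = 3)
  folds <- make_folds(recs, plan, k = 10, seed = 3)
  expect_length(folds, 10L)
  expect_setequal(unlist(folds), plan$train)
  expect_equal(sum(lengths(folds)), length(plan$train))
  for (i in 1:9) for (j in (i + 1):10) {
    expect_length(intersect(folds[[i]], folds[[j]]), 0L)
  }
  fold_workers <- lapply(folds, function(f) unique(recs$worker_id[recs$record_id %in% f]))
  expect_equal(length(unique(unlist(fold_workers))), length(unlist(fold_workers)))
  expect_lt(max(lengths(folds)) - min(lengths(folds)), max(lengths(folds)))

  expect_error(make_folds(recs, plan, k = 1, seed = 1), class = "ohppfwa_fold_error")
  expect_error(make_folds(recs, plan, k = 10000, seed = 1),
               class = "ohppfwa_fold_error")
})

test_that("categorical encoding is stable under a persisted vocabulary", {
  recs <- cohort_records(40, 22)
  enc <- encode_categoricals(assemble_features(corpus_to_table(
    generate_cohort(generator_config(n_workers = 40, seed = 22)))))
  again <- encode_categoricals(enc$records, vocab = enc$vocab)
  expect_equal(again$records$area_code, enc$records$area_code)
  # unseen level codes as NA
  odd <- enc$records[1, ]
  odd$area <- "Warp Drive Assembly"
  expect_true(is.na(encode_categoricals(odd, vocab = enc$vocab)$records$area_code))
})

test_that("split plans persist losslessly as JSON", {
  recs <- cohort_records(60, 23)
  plan <- split_by_worker(recs, 0.25, seed = 5)
  plan$folds <- make_folds(recs, plan, k = 5, seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_split_plan(plan, path)
  back <- read_split_plan(path)
  expect_equal(back$train, plan$train)
  expect_equal(back$test, plan$test)
  expect_equal(back$folds, plan$folds)
  expect_equal(back$seed, plan$seed)
})
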