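lex <- load_lexicon()

test_that("generator configuration is validated with the offending field named", {
  expect_error(generator_config(p_female = 1.2), "p_female",
               class = "ohppfwa_config_error")
  expect_error(generator_config(area_weights = c(a = 0.5, b = 0.2)),
               "area_weights", class = "ohppfwa_config_error")
  bad_dist <- c("1" = 0.5, "2" = 0.3, "8" = 0.2)
  expect_error(generator_config(appointment_count_dist = bad_dist),
               "appointment_count_dist", class = "ohppfwa_config_error")
  expect_error(generator_config(interval_model = list(beta0 = -1)),
               "beta0", class = "ohppfwa_config_error")
  expect_error(generator_config(n_workers = -3), "n_workers",
               class = "ohppfwa_config_error")
})

test_that("zero workers give an empty corpus; same seed gives identical corpora", {
  expect_length(generate_cohort(generator_config(n_workers = 0)), 0L)
  a <- generate_cohort(generator_config(n_workers = 40, seed = 9))
  b <- generate_cohort(generator_config(n_workers = 40, seed = 9))
  expect_identical(a, b)
  c <- generate_cohort(generator_config(n_workers = 40, seed = 10))
  expect_false(identical(a, c))
})

test_that("demography matches calibration: female share, seniority bounds, appointment counts", {
  corpus <- generate_cohort(generator_config(n_workers = 638, seed = 1))
  ids <- vapply(corpus, `[[`, character(1), "worker_id")
  first <- !duplicated(ids)
  female <- mean(vapply(corpus, `[[`, character(1), "gender")[first] == "female")
  ci <- 1.96 * sqrt(0.233 * 0.767 / 638)
  expect_lt(abs(female - 0.233), ci)

  sen <- vapply(corpus, `[[`, numeric(1), "seniority_years")[first]
  gender <- vapply(corpus, `[[`, character(1), "gender")[first]
  expect_true(all(sen[gender == "female"] >= 4 & sen[gender == "female"] <= 27))
  expect_true(all(sen[gender == "male"] >= 4 & sen[gender == "male"] <= 29))

  counts <- table(table(ids))
  expect_false("8" %in% names(counts))            # nobody has exactly 8 visits
  expect_gt(counts[["1"]], counts[["2"]])         # monotone-decreasing histogram
  expect_gt(counts[["2"]], counts[["4"]])
})

test_that("noise channels draw from independent streams", {
  base <- generate_cohort(generator_config(n_workers = 20, seed = 6))
  louder <- generate_cohort(generator_config(
    n_workers = 20, seed = 6,
    noise = list(p_label_at_end = 0.9, p_misspell_token = 0.3,
                 p_extra_space = 0.5, p_nonword_symbol = 0.5,
                 p_caps_error = 0.5)))
  # text differs, but ground truth (demography, restrictions, intervals) is untouched
  strip <- function(corpus) lapply(corpus, function(a) a[names(a) != "sentences"])
  expect_identical(strip(base), strip(louder))
  expect_false(identical(vapply(base, function(a) a$sentences[1], character(1)),
                         vapply(louder, function(a) a$sentences[1], character(1))))
})

test_that("canonical rendering matches the published template and noise channels act as stated", {
  canon <- render_sentence("MN", c("shoulder_L", "shoulder_R"), lex, "en", noise_off())
  expect_equal(canon, "Must not perform tasks that involve movements above both shoulders.")

  set.seed(2)
  noise <- noise_off(); noise$p_label_at_end <- 1
  ended <- render_sentence("MN", c("shoulder_L", "shoulder_R"), lex, "en", noise)
  expect_match(tolower(ended), "shoulders.*must not")  # cue after the part phrase

  expect_error(render_sentence("MN", character(), lex, process = "welding"),
               class = "ohppfwa_data_error")
})

test_that("token misspelling rate matches its probability over a Monte-Carlo sample", {
  set.seed(9)
  canon <- strsplit(render_sentence("MN", c("shoulder_L", "shoulder_R"), lex,
                                    "en", noise_off()), " ")[[1]]
  noise <- noise_off(); noise$p_misspell_token <- 0.2
  n_tok <- n_mis <- 0
  for (i in 1:1000) {
    toks <- strsplit(render_sentence("MN", c("shoulder_L", "shoulder_R"), lex,
                                     "en", noise), " ")[[1]]
    n_tok <- n_tok + length(canon)
    n_mis <- n_mis + sum(toks != canon)
  }
  ci <- 1.96 * sqrt(0.2 * 0.8 / n_tok)
  expect_lt(abs(n_mis / n_tok - 0.2), ci)
})

test_that("interval model: baseline at zero severity, monotone in scores, calibrated mean", {
  model <- generator_config()$interval_model
  model$sigma <- 0
  zero <- stats::setNames(rep(0, 14), part_ids())
  expect_equal(sample_interval(zero, model), 64)

  # raising one score never raises the noise-free interval
  sc <- zero
  prev <- sample_interval(sc, model)
  for (s in c(0.5, 1, 2.5)) {
    sc[["shoulder_R"]] <- s
    cur <- sample_interval(sc, model)
    expect_lte(cur, prev)
    prev <- cur
  }

  # with noise on, a zero-severity cohort still averages ~ beta0 = 64 weeks
  model$sigma <- 2
  set.seed(4)
  draws <- replicate(400, sample_interval(zero, model))
  expect_lt(abs(mean(draws) - 64), 1.96 * 2 / sqrt(400))
})

test_that("generated ground-truth scores stay within the published population envelope", {
  corpus <- generate_cohort(generator_config(n_workers = 300, seed = 12))
  scores <- as.matrix(corpus_to_table(corpus)[, paste0("score_", part_ids())])
  nonzero <- scores[scores > 0]
  expect_gte(min(nonzero), 0.19)
  expect_lte(max(nonzero), 5.33)
})

test_that("ground-truth scores equal the scoring allocation applied to true protections", {
  corpus <- quiet_cohort(15, 8)
  for (app in corpus) {
    expect_equal(app$true_scores, allocate_scores(app$groups, scoring_config()))
  }
})

test_that("JSON-lines serialization round-trips the corpus", {
  corpus <- generate_cohort(generator_config(n_workers = 12, seed = 13))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(corpus, path)
  back <- read_corpus(path)
  expect_equal(length(back), length(corpus))
  for (i in seq_along(corpus)) {
    expect_equal(back[[i]]$worker_id, corpus[[i]]$worker_id)
    expect_equal(back[[i]]$date, corpus[[i]]$date)
    expect_equal(back[[i]]$sentences, corpus[[i]]$sentences)
    expect_equal(back[[i]]$true_scores, corpus[[i]]$true_scores)
    expect_equal(back[[i]]$true_interval_weeks, corpus[[i]]$true_interval_weeks)
  }
  # byte-identical on re-serialization
  path2 <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("multi-visit filtering keeps exactly the workers with two or more appointments", {
  corpus <- generate_cohort(generator_config(n_workers = 60, seed = 14))
  multi <- filter_multi_visit(corpus)
  ids <- vapply(multi, `[[`, character(1), "worker_id")
  expect_true(all(table(ids) >= 2))
  all_ids <- vapply(corpus, `[[`, character(1), "worker_id")
  expect_setequal(unique(ids), names(which(table(all_ids) >= 2)))
})
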