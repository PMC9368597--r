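lex <- load_lexicon()

test_that("normalization collapses case, symbols and spaces, and is idempotent", {
  expect_equal(normalize_sentence("MUST   not perform tasks!!"),
               "must not perform tasks")
  norm <- normalize_sentence("Não pode executar tarefas — flexão do tronco.")
  expect_equal(norm, normalize_sentence(norm))         # idempotent
  expect_match(norm, "não")                             # diacritics preserved
  expect_error(normalize_sentence("   "), class = "ohppfwa_empty_sentence")
  expect_error(normalize_sentence("!!"), class = "ohppfwa_empty_sentence")
})

test_that("the published example sentences yield exactly the printed flags", {
  row1 <- c("Should not perform tasks that involve movements of the right elbow.",
            "Must not perform tasks that involve movements above both shoulders.")
  p1 <- build_profile(row1, lex)
  expect_equal(sort(names(p1)[p1 == 1]),
               sort(c("shoulder_L_MN", "shoulder_R_MN", "elbow_R_SN")))

  row2 <- c("Must not perform tasks that involve movements of the left wrist and left fingers.",
            "Must not perform tasks that require force with fingers of both hands.")
  p2 <- build_profile(row2, lex)
  expect_equal(sort(names(p2)[p2 == 1]),
               sort(c("wrist_L_MN", "fingers_L_MN", "fingers_R_MN")))
})

test_that("process-only restrictions yield an empty part list, not a guess", {
  vib <- extract_protections(
    "Must not perform tasks that imply performing tasks using tools with associated vibration",
    lex)
  expect_equal(nrow(vib$protections), 0L)
  expect_true(vib$process_only)
  expect_false(vib$unparsed)
  expect_equal(vib$cue_level, "MN")

  mmh <- extract_protections("Should not perform tasks that involve manual material handling", lex)
  expect_true(mmh$process_only)

  prof <- build_profile(
    "Must not perform tasks that imply performing tasks using tools with associated vibration",
    lex)
  expect_true(all(prof == 0L))
})

test_that("level cues are found at either end and laterality resolves coordinated phrases", {
  at_end <- extract_protections(
    "Perform tasks that involve movements of the right elbow - must not.", lex)
  expect_equal(at_end$protections$part, "elbow_R")
  expect_equal(at_end$protections$level, "MN")

  both_lat <- extract_protections(
    "Should not perform tasks that involve performing left and right wrist rotation movements", lex)
  expect_setequal(both_lat$protections$part, c("wrist_L", "wrist_R"))

  plural <- extract_protections(
    "Must not perform tasks that involve movements of the knees", lex)
  expect_setequal(plural$protections$part, c("knee_L", "knee_R"))
})

test_that("a cue with no recognizable content is flagged unparsed, never dropped silently", {
  res <- extract_protections("Must not perform strenuous overtime duties", lex)
  expect_true(res$unparsed)
  expect_equal(nrow(res$protections), 0L)

  # a sided region with no laterality marker is reported, not guessed
  res2 <- extract_protections("Must not perform tasks that involve movements of the elbow", lex)
  expect_true(res2$unparsed)
})

test_that("MN takes precedence over SN when both tag the same part in one appointment", {
  both <- c("Should not perform tasks that involve movements of the right elbow.",
            "Must not perform tasks that involve movements of the right elbow.")
  prof <- build_profile(both, lex)
  expect_equal(prof[["elbow_R_MN"]], 1L)
  expect_equal(prof[["elbow_R_SN"]], 0L)
})

test_that("extraction on noise-free synthetic corpora recovers ground truth exactly", {
  for (language in c("en", "pt")) {
    corpus <- generate_cohort(generator_config(n_workers = 25, seed = 3,
                                               language = language,
                                               noise = noise_off()))
    expect_equal(extraction_f1(corpus, lex, language), 1,
                 info = paste("language", language))
  }
})

test_that("extraction F1 degrades continuously with misspelling noise, no cliff", {
  probs <- c(0, 0.03, 0.06, 0.1)
  f1 <- vapply(probs, function(p) {
    noise <- noise_off()
    noise$p_misspell_token <- p
    corpus <- generate_cohort(generator_config(n_workers = 30, seed = 5,
                                               noise = noise))
    extraction_f1(corpus, lex)
  }, numeric(1))
  expect_equal(f1[1], 1)
  expect_gt(f1[length(f1)], 0.75)
  expect_true(all(diff(f1) > -0.12))   # no single-step cliff
})

test_that("the 28-column schema is fixed, ordered and round-trips through the flat table", {
  expect_length(flag_columns(), 28L)
  expect_equal(flag_columns()[1:4], c("neck_MN", "neck_SN", "trunk_MN", "trunk_SN"))
  corpus <- quiet_cohort(6, 11)
  tab <- extract_corpus(corpus, lex)
  expect_true(all(flag_columns() %in% names(tab)))
  expect_equal(nrow(tab), length(corpus))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, path, row.names = FALSE)
  back <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(as.matrix(back[, flag_columns()]), as.matrix(tab[, flag_columns()]))
})
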