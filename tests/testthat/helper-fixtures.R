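# Shared fixtures and oracles, built in code at test time.

# The published worked example, structured as sentence groups:
# two MN sentences with parts (both shoulders; both hands' fingers),
# one process-only MN sentence (vibration tools), two SN sentences
# (trunk; both wrists).
worked_example_groups <- function() {
  list(
    list(level = "MN", parts = c("shoulder_L", "shoulder_R")),
    list(level = "SN", parts = "trunk"),
    list(level = "MN", parts = character()),
    list(level = "SN", parts = c("wrist_L", "wrist_R")),
    list(level = "MN", parts = c("fingers_L", "fingers_R"))
  )
}

# The worked example as the five printed restriction sentences.
worked_example_sentences <- function() {
  c("Must not perform tasks that involve movements above both shoulder line",
    "Should not perform tasks that involve performing flexion/rotation movements of the trunk",
    "Must not perform tasks that imply performing tasks using tools with associated vibration",
    "Should not perform tasks that involve performing left and right wrist rotation movements",
    "Must not perform tasks that involve performing tasks that require force with application point on the fingers of both hands")
}

noise_off <- function() {
  list(p_label_at_end = 0, p_misspell_token = 0, p_extra_space = 0,
       p_nonword_symbol = 0, p_caps_error = 0)
}

quiet_cohort <- function(n_workers, seed, ...) {
  generate_cohort(generator_config(n_workers = n_workers, seed = seed,
                                   noise = noise_off(), ...))
}

# ground-truth flag names (part_LEVEL) for one appointment
truth_flags <- function(app) {
  sort(unlist(lapply(app$groups, function(g) {
    if (length(g$parts)) paste0(g$parts, "_", g$level)
  })))
}

# records table (encoded) from a generated corpus; memoized because several
# test files reuse the same fixture cohorts
.cohort_cache <- new.env(parent = emptyenv())
cohort_records <- function(n_workers, seed, ...) {
  key <- paste(n_workers, seed, sep = "_")
  if (!length(list(...)) && !is.null(.cohort_cache[[key]])) {
    return(.cohort_cache[[key]])
  }
  corpus <- generate_cohort(generator_config(n_workers = n_workers,
                                             seed = seed, ...))
  out <- encode_categoricals(assemble_features(corpus_to_table(corpus)))$records
  if (!length(list(...))) .cohort_cache[[key]] <- out
  out
}

# Brute-force Shapley oracle: full m! permutation enumeration over the
# interventional value function. Independent of the coalition-weight
# implementation under test.
brute_force_shapley <- function(predict_fn, background, x) {
  m <- length(x)
  v <- function(S) {
    B <- background
    for (j in S) B[, j] <- x[j]
    mean(predict_fn(B))
  }
  all_perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(all_perms(v[-i]), function(p) c(v[i], p))
    }))
  }
  perms <- all_perms(seq_len(m))
  phi <- numeric(m)
  for (p in perms) {
    S <- integer()
    for (j in p) {
      phi[j] <- phi[j] + v(c(S, j)) - v(S)
      S <- c(S, j)
    }
  }
  stats::setNames(phi / length(perms), names(x))
}

# extraction F1 against ground truth over a corpus
extraction_f1 <- function(corpus, lexicon, language = "en") {
  tp <- fp <- fn <- 0
  for (app in corpus) {
    truth <- truth_flags(app)
    prof <- build_profile(app$sentences, lexicon, language)
    got <- names(prof)[prof == 1]
    tp <- tp + length(intersect(got, truth))
    fp <- fp + length(setdiff(got, truth))
    fn <- fn + length(setdiff(truth, got))
  }
  2 * tp / (2 * tp + fp + fn)
}
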