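#' Scoring configuration
#'
#' Severity scoring allocates a per-category pool of points over the body
#' parts named in an appointment's restriction sentences. The per-sentence
#' weights are anchored to the published worked example, whose printed
#' pools are 2 for two must-not (MN) sentences and 5 for two should-not
#' (SN) sentences — hence MN 1.0 and SN 2.5 points per sentence.
#'
#' Three allocation modes are provided. `"sentence"` (the default) divides
#' each category pool equally over that category's sentences and then over
#' each sentence's parts; it conserves the pools exactly and is internally
#' consistent. `"slot"` divides the pool by the total number of body-part
#' slots in the category. `"paper_compat"` mixes the two — MN by sentence,
#' SN by slot — which is the only combination that reproduces every printed
#' cell of the published scoring table (trunk 5/3, wrists 5/6); it is kept
#' for fidelity, without any claim about intent.
#'
#' @param mn_sentence_weight points per MN sentence (default 1.0).
#' @param sn_sentence_weight points per SN sentence (default 2.5).
#' @param allocation_mode one of `"sentence"`, `"slot"`, `"paper_compat"`.
#' @param good_range,poor_range inclusive work-ability index category
#'   bounds on the 0-10 scale.
#' @return list of class `ohppfwa_scoring_config`.
#' @export
scoring_config <- function(mn_sentence_weight = 1.0,
                           sn_sentence_weight = 2.5,
                           allocation_mode = c("sentence", "slot", "paper_compat"),
                           good_range = c(8, 10),
                           poor_range = c(0, 7)) {
  allocation_mode <- match.arg(allocation_mode)
  if (mn_sentence_weight <= 0 || sn_sentence_weight <= 0) {
    abort("sentence weights must be positive", "ohppfwa_config_error")
  }
  if (poor_range[2] >= good_range[1]) {
    abort("category ranges must be disjoint and ordered", "ohppfwa_config_error")
  }
  structure(
    list(mn_sentence_weight = mn_sentence_weight,
         sn_sentence_weight = sn_sentence_weight,
         allocation_mode = allocation_mode,
         good_range = good_range, poor_range = poor_range),
    class = "ohppfwa_scoring_config"
  )
}

# sentences of one category that carry at least one mapped body part
category_sentences <- function(groups, level) {
  Filter(function(g) identical(g$level, level) && length(g$parts) > 0L, groups)
}

#' Category score pools
#'
#' Each protection category contributes a pool equal to the number of its
#' sentences that name at least one body part, times the per-sentence
#' weight. Process-only sentences (no body part) are excluded from the
#' counts.
#'
#' @param groups sentence-grouped protections: a list of
#'   `list(level, parts)` as returned by [sentence_groups()].
#' @param config a [scoring_config()].
#' @return named numeric vector `c(MN =, SN =)`.
#' @examples
#' groups <- list(
#'   list(level = "MN", parts = c("shoulder_L", "shoulder_R")),
#'   list(level = "SN", parts = "trunk"),
#'   list(level = "MN", parts = character()),  # process-only
#'   list(level = "SN", parts = c("wrist_L", "wrist_R")),
#'   list(level = "MN", parts = c("fingers_L", "fingers_R"))
#' )
#' category_pools(groups, scoring_config())   # MN 2, SN 5
#' @export
category_pools <- function(groups, config = scoring_config()) {
  stopifnot(inherits(config, "ohppfwa_scoring_config"))
  c(MN = length(category_sentences(groups, "MN")) * config$mn_sentence_weight,
    SN = length(category_sentences(groups, "SN")) * config$sn_sentence_weight)
}

#' Allocate per-part severity scores
#'
#' Distributes the category pools over body parts according to the
#' configured allocation mode (see [scoring_config()]). Parts hit by
#' multiple sentences accumulate additively.
#'
#' @inheritParams category_pools
#' @return named numeric vector of the 14 per-part scores.
#' @export
allocate_scores <- function(groups, config = scoring_config()) {
  stopifnot(inherits(config, "ohppfwa_scoring_config"))
  pools <- category_pools(groups, config)
  scores <- stats::setNames(numeric(14L), part_ids())
  mode_for <- switch(config$allocation_mode,
    sentence = c(MN = "sentence", SN = "sentence"),
    slot = c(MN = "slot", SN = "slot"),
    paper_compat = c(MN = "sentence", SN = "slot")
  )
  for (lev in c("MN", "SN")) {
    sents <- category_sentences(groups, lev)
    if (!length(sents)) next
    share <- switch(mode_for[[lev]],
      sentence = pools[[lev]] / length(sents),
      slot = pools[[lev]] / sum(vapply(sents, function(g) length(g$parts), integer(1)))
    )
    for (g in sents) {
      bad <- setdiff(g$parts, part_ids())
      if (length(bad)) {
        abort(sprintf("unknown body part(s): %s", paste(bad, collapse = ", ")),
              "ohppfwa_data_error")
      }
      scores[g$parts] <- scores[g$parts] + share / length(g$parts)
    }
  }
  scores
}

#' Work-ability index category
#'
#' Classifies a total score on the 0-10 work-ability scale into the two
#' published categories: poor (0-7) and good (8-10). Fractional totals
#' strictly between 7 and 8 are rounded half-up to the nearest integer
#' before classification.
#'
#' @param total total severity score, in `[0, 10]`.
#' @return `"poor"` or `"good"`.
#' @export
wai_category <- function(total) {
  stopifnot(is.numeric(total), length(total) == 1L)
  if (is.na(total) || total < 0 || total > 10) {
    abort(sprintf("total score %s outside the 0-10 scale", format(total)),
          "ohppfwa_range_error")
  }
  if (total > 7 && total < 8) total <- round_half_up(total)
  if (total <= 7) "poor" else "good"
}

#' Score one appointment
#'
#' @inheritParams category_pools
#' @return list with `scores` (14 per-part scores), `total` (their sum) and
#'   `wai_category` (`NA` with a warning if the total exceeds the 0-10
#'   scale).
#' @export
score_profile <- function(groups, config = scoring_config()) {
  scores <- allocate_scores(groups, config)
  total <- sum(scores)
  cat <- if (total <= 10) wai_category(total) else {
    warning("total score ", format(total), " exceeds the 0-10 scale; category NA")
    NA_character_
  }
  list(scores = scores, total = total, wai_category = cat)
}

#' Extract and score a corpus
#'
#' Runs text extraction and severity scoring over a corpus and returns the
#' flat per-appointment score table (the shape of the published population
#' descriptives: one `score_<part>` column per body part).
#'
#' @param corpus list of appointments (see [extract_corpus()]).
#' @param lexicon,language,fuzzy see [extract_protections()].
#' @param config a [scoring_config()].
#' @return data.frame: metadata columns, `score_<part>` columns, `total`,
#'   `wai_category`.
#' @export
score_corpus <- function(corpus, lexicon, language = "en", fuzzy = TRUE,
                         config = scoring_config()) {
  meta_cols <- c("worker_id", "date", "area", "func", "schedule",
                 "seniority_years", "gender")
  rows <- vector("list", length(corpus))
  for (i in seq_along(corpus)) {
    app <- corpus[[i]]
    prof <- build_profile(app$sentences, lexicon, language, fuzzy)
    sp <- score_profile(attr(prof, "groups"), config)
    meta <- lapply(meta_cols, function(cc) app[[cc]] %||% NA)
    names(meta) <- meta_cols
    sc <- as.data.frame(as.list(sp$scores))
    names(sc) <- paste0("score_", part_ids())
    rows[[i]] <- cbind(as.data.frame(meta, stringsAsFactors = FALSE), sc,
                       data.frame(total = sp$total,
                                  wai_category = sp$wai_category,
                                  stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
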