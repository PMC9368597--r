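#' Normalize a restriction sentence
#'
#' Physicians' free text shows clerical deviations: stray non-word symbols,
#' repeated spaces and inconsistent capitalisation. Normalization lower-cases
#' the text, strips symbols that are neither letters, digits nor whitespace
#' (diacritics are preserved), collapses runs of whitespace and trims the
#' ends. The operation is idempotent.
#'
#' @param raw character vector of raw sentences.
#' @return character vector of normalized sentences.
#' @examples
#' normalize_sentence("MUST   not perform tasks!!")
#' @export
normalize_sentence <- function(raw) {
  if (!is.character(raw) || length(raw) == 0L) {
    abort("sentence must be a non-empty character vector", "ohppfwa_empty_sentence")
  }
  out <- tolower(raw)
  out <- gsub("[^\\p{L}\\p{N}\\s]", " ", out, perl = TRUE)
  out <- gsub("\\s+", " ", out, perl = TRUE)
  out <- trimws(out)
  if (any(!nzchar(out))) {
    abort("sentence is empty after normalization", "ohppfwa_empty_sentence")
  }
  out
}

# Fuzzy token match: exact for short tokens, bounded edit distance (<= 1)
# for tokens of >= 5 characters. Absorbs single-character misspellings
# without letting short function words collide.
token_matches <- function(token, keywords, fuzzy = TRUE) {
  if (token %in% keywords) return(TRUE)
  if (!fuzzy || nchar(token) < 5L) return(FALSE)
  long <- keywords[nchar(keywords) >= 5L]
  length(long) > 0L && any(utils::adist(token, long) <= 1L)
}

# Locate cue phrases (token sequences) in a token vector; returns a
# data.frame of (pos, level) for the first token of each match.
find_cues <- function(tokens, levels, fuzzy = TRUE) {
  hits <- list()
  for (lev in names(levels)) {
    for (cue in levels[[lev]]) {
      ctoks <- strsplit(cue, " ", fixed = TRUE)[[1]]
      nc <- length(ctoks)
      if (length(tokens) < nc) next
      for (start in seq_len(length(tokens) - nc + 1L)) {
        ok <- all(vapply(seq_len(nc), function(k) {
          token_matches(tokens[start + k - 1L], ctoks[k], fuzzy)
        }, logical(1)))
        if (ok) hits[[length(hits) + 1L]] <- data.frame(pos = start, level = lev)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(pos = integer(), level = character()))
  }
  out <- do.call(rbind, hits)
  out <- out[!duplicated(out$pos), , drop = FALSE]
  out[order(out$pos), , drop = FALSE]
}

#' Extract body-part protections from one sentence
#'
#' Applies the rule-based protocol: detect the protection-level cue
#' (`"must not"` / `"should not"` or the Portuguese equivalents) whether it
#' sits at the start, the end, or mid-sentence; find body-part keywords with
#' bounded-edit-distance fuzzy matching; resolve laterality from `left` /
#' `right` / `both` markers near each part (markers before the part take
#' precedence, so coordinated phrases such as "left wrist and left fingers"
#' resolve correctly); expand "both" and bare plurals to left + right.
#' Process-only restrictions (vibration tools, manual material handling)
#' legitimately carry no body part and yield an empty part list. A sentence
#' with a level cue but no recognizable content is returned with an
#' `unparsed` marker for manual review, never silently dropped.
#'
#' @param sentence a single raw or normalized sentence.
#' @param lexicon an [load_lexicon()] object.
#' @param language language code present in the lexicon (`"en"` or `"pt"`).
#' @param fuzzy enable fuzzy keyword matching (edit distance <= 1 for tokens
#'   of >= 5 characters).
#' @return A list with elements `protections` (data.frame of `part`,
#'   `level`), `process_only`, `unparsed` and `sentence` (the normalized
#'   text).
#' @examples
#' lex <- load_lexicon()
#' extract_protections(
#'   "Must not perform tasks that involve movements above both shoulders.",
#'   lex
#' )$protections
#' @export
extract_protections <- function(sentence, lexicon, language = "en", fuzzy = TRUE) {
  stopifnot(inherits(lexicon, "ohppfwa_lexicon"), length(sentence) == 1L)
  lx <- lexicon[[language]]
  if (is.null(lx)) {
    abort(sprintf("language '%s' not in lexicon", language), "ohppfwa_config_error")
  }
  norm <- normalize_sentence(sentence)
  tokens <- strsplit(norm, " ", fixed = TRUE)[[1]]

  cues <- find_cues(tokens, lx$levels, fuzzy)

  # region keyword hits
  region_hit <- character(length(tokens))
  plural_hit <- logical(length(tokens))
  for (i in seq_along(tokens)) {
    for (region in names(lx$regions)) {
      kws <- lx$regions[[region]]
      if (token_matches(tokens[i], kws, fuzzy)) {
        region_hit[i] <- region
        base <- kws[[1]]
        matched <- if (tokens[i] %in% kws) tokens[i] else
          kws[which.min(utils::adist(tokens[i], kws))]
        plural_hit[i] <- endsWith(matched, "s") && !endsWith(base, "s")
        break
      }
    }
  }
  hit_pos <- which(nzchar(region_hit))

  lat_side <- character(length(tokens))
  for (i in seq_along(tokens)) {
    for (side in names(lx$laterality)) {
      if (tokens[i] %in% lx$laterality[[side]]) {
        lat_side[i] <- side
        break
      }
    }
  }

  level_at <- function(pos) {
    if (!nrow(cues)) return(NA_character_)
    before <- cues$pos[cues$pos <= pos]
    if (length(before)) return(cues$level[match(max(before), cues$pos)])
    after <- cues$pos[cues$pos > pos]
    cues$level[match(min(after), cues$pos)]
  }

  rows <- list()
  unparsed <- FALSE
  for (i in hit_pos) {
    region <- region_hit[i]
    lev <- level_at(i)
    if (is.na(lev)) {
      unparsed <- TRUE
      next
    }
    if (region %in% c("neck", "trunk")) {
      parts <- region
    } else {
      prev_hit <- hit_pos[hit_pos < i]
      next_hit <- hit_pos[hit_pos > i]
      lo <- max(1L, i - 3L, if (length(prev_hit)) max(prev_hit) + 1L else 1L)
      hi <- min(length(tokens), i + 4L,
                if (length(next_hit)) min(next_hit) - 1L else length(tokens))
      before <- lat_side[lo:max(lo, i - 1L)]
      after <- if (hi > i) lat_side[(i + 1L):hi] else character()
      marks <- before[nzchar(before)]
      if (!length(marks)) marks <- after[nzchar(after)]
      sides <- if ("both" %in% marks) c("L", "R") else
        c(if ("left" %in% marks) "L", if ("right" %in% marks) "R")
      if (!length(sides)) {
        if (plural_hit[i]) sides <- c("L", "R") else {
          unparsed <- TRUE
          next
        }
      }
      parts <- paste(region, sides, sep = "_")
    }
    for (p in parts) rows[[length(rows) + 1L]] <- data.frame(part = p, level = lev)
  }

  protections <- if (length(rows)) {
    out <- do.call(rbind, rows)
    out[!duplicated(out[, c("part", "level")]), , drop = FALSE]
  } else {
    data.frame(part = character(), level = character())
  }

  process_only <- FALSE
  if (!length(hit_pos)) {
    proc <- vapply(lx$process_keywords %||% character(), function(kw) {
      if (grepl(" ", kw, fixed = TRUE)) {
        grepl(kw, norm, fixed = TRUE)
      } else {
        any(vapply(tokens, token_matches, logical(1), keywords = kw, fuzzy = fuzzy))
      }
    }, logical(1))
    process_only <- any(proc)
    if (!process_only && nrow(cues)) unparsed <- TRUE
  }

  list(
    protections = protections,
    process_only = process_only,
    unparsed = unparsed,
    cue_level = if (nrow(cues)) cues$level[1L] else NA_character_,
    sentence = norm
  )
}

#' Extract all sentences of one appointment
#'
#' @param sentences character vector of the appointment's restriction
#'   sentences.
#' @inheritParams extract_protections
#' @return list of [extract_protections()] results, one per sentence.
#' @export
extract_appointment <- function(sentences, lexicon, language = "en", fuzzy = TRUE) {
  lapply(sentences, extract_protections, lexicon = lexicon,
         language = language, fuzzy = fuzzy)
}

#' Sentence-grouped protections
#'
#' Reduces per-sentence extraction results (or generator ground truth) to
#' the structure the scoring allocation consumes: one `(level, parts)`
#' group per sentence, unparsed sentences dropped.
#'
#' @param extractions list of per-sentence results from
#'   [extract_appointment()], or a list of `list(level =, parts =)` groups.
#' @return list of `list(level, parts)`; `parts` may be empty for
#'   process-only sentences.
#' @export
sentence_groups <- function(extractions) {
  out <- lapply(extractions, function(e) {
    if (!is.null(e$level)) {                      # already a ground-truth group
      return(list(level = e$level, parts = as.character(e$parts)))
    }
    if (isTRUE(e$unparsed)) return(NULL)
    lev <- unique(e$protections$level)
    if (isTRUE(e$process_only) || !nrow(e$protections)) {
      return(list(level = if (length(lev)) lev[1] else e$cue_level,
                  parts = character()))
    }
    # one group per level present in the sentence (mid-sentence cues can
    # attach different levels to different parts)
    lapply(lev, function(l) {
      list(level = l, parts = e$protections$part[e$protections$level == l])
    })
  })
  flat <- list()
  for (o in out) {
    if (is.null(o)) next
    if (!is.null(o$level)) flat[[length(flat) + 1L]] <- o
    else for (g in o) flat[[length(flat) + 1L]] <- g
  }
  flat
}

#' Build a 28-flag protection profile from an appointment's sentences
#'
#' Takes the union of all protections extracted across the appointment's
#' sentences. When the same part is tagged with both levels, the more
#' severe `MN` wins and the `SN` flag is set to 0.
#'
#' @param sentences character vector of restriction sentences.
#' @param lexicon,language,fuzzy see [extract_protections()].
#' @return named integer vector of the 28 flags (see [flag_columns()]),
#'   with attributes `groups` (sentence-grouped protections) and
#'   `unparsed` (indices of sentences flagged for manual review).
#' @export
build_profile <- function(sentences, lexicon, language = "en", fuzzy = TRUE) {
  ex <- extract_appointment(sentences, lexicon, language, fuzzy)
  flags <- stats::setNames(integer(28L), flag_columns())
  for (e in ex) {
    if (isTRUE(e$unparsed)) next
    for (k in seq_len(nrow(e$protections))) {
      flags[paste(e$protections$part[k], e$protections$level[k], sep = "_")] <- 1L
    }
  }
  for (p in part_ids()) {
    if (flags[paste0(p, "_MN")] == 1L) flags[paste0(p, "_SN")] <- 0L
  }
  structure(flags,
            groups = sentence_groups(ex),
            unparsed = which(vapply(ex, function(e) isTRUE(e$unparsed), logical(1))))
}

#' Extract a corpus into the flat 28-flag profile table
#'
#' @param corpus list of appointments as produced by [generate_cohort()]
#'   (each with `worker_id`, `date`, metadata and `sentences`), or read
#'   back from JSON-lines with [read_corpus()].
#' @inheritParams extract_protections
#' @return data.frame with one row per appointment: metadata columns
#'   followed by the 28 ordered flag columns. Attribute `report` lists
#'   appointment/sentence pairs flagged as unparsed.
#' @export
extract_corpus <- function(corpus, lexicon, language = "en", fuzzy = TRUE) {
  meta_cols <- c("worker_id", "date", "area", "func", "schedule",
                 "seniority_years", "gender")
  rows <- vector("list", length(corpus))
  report <- list()
  for (i in seq_along(corpus)) {
    app <- corpus[[i]]
    prof <- build_profile(app$sentences, lexicon, language, fuzzy)
    meta <- lapply(meta_cols, function(cc) app[[cc]] %||% NA)
    names(meta) <- meta_cols
    rows[[i]] <- cbind(as.data.frame(meta, stringsAsFactors = FALSE),
                       as.data.frame(as.list(prof)))
    un <- attr(prof, "unparsed")
    if (length(un)) {
      report[[length(report) + 1L]] <- data.frame(
        appointment = i, sentence_index = un,
        sentence = app$sentences[un], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "report") <- if (length(report)) do.call(rbind, report) else
    data.frame(appointment = integer(), sentence_index = integer(),
               sentence = character())
  out
}
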