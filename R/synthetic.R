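#' Generator configuration for synthetic protection-profile corpora
#'
#' The generator emulates the statistical structure of a proprietary
#' automotive-plant cohort of occupational health protection profiles:
#' a 23.3% female share; per-gender seniority distributions (female mean
#' 13.95 sd 7.78 years in 4-27, male 18.62 sd 8.33 in 4-29); a
#' monotone-decreasing appointment-count distribution with no worker at
#' exactly 8 appointments; production-area mix; clerical text noise
#' (misspellings, extra spaces, non-word symbols, capitalisation errors,
#' level labels written at the end of the sentence); and a planted linear
#' interval model `weeks = max(min_interval, beta0 - sum(beta_p * score_p)
#' + eps)`, `eps ~ N(0, sigma)`, whose dominant coefficient sits on the
#' right shoulder so that high severity there shortens the predicted time
#' to the next appointment.
#'
#' @param n_workers number of workers to simulate.
#' @param seed integer master seed; four independent sub-streams
#'   (demography, restrictions, text noise, intervals) are derived from it
#'   so that changing one channel's rates leaves the other draws unchanged.
#' @param p_female probability a worker is female (default 0.233).
#' @param seniority_params per-gender `list(mean, sd, min, max)` in years.
#' @param area_weights named probabilities over production areas (sum 1).
#' @param appointment_count_dist named probabilities over appointment
#'   counts; must sum to 1 and assign 0 to k = 8. Default: truncated
#'   geometric over {1..7, 9..12} renormalised.
#' @param noise list of text-noise probabilities: `p_label_at_end`,
#'   `p_misspell_token`, `p_extra_space`, `p_nonword_symbol`,
#'   `p_caps_error`.
#' @param interval_model list `beta0` (weeks), `beta` (named per-part
#'   weeks per score unit), `sigma` (noise sd, weeks), `min_interval`.
#' @param restriction list controlling restriction structure:
#'   `n_sentence_probs` (distribution of body-part sentences per
#'   appointment), `p_process_sentence`, `p_mn`, `p_both_sides`,
#'   `p_carry` (probability a restricted region persists to the next
#'   visit).
#' @param language `"en"` or `"pt"`.
#' @param scoring a [scoring_config()] used to derive ground-truth scores.
#' @return list of class `ohppfwa_generator_config`.
#' @export
generator_config <- function(n_workers = 638L,
                             seed = 1L,
                             p_female = 0.233,
                             seniority_params = list(
                               female = list(mean = 13.95, sd = 7.78, min = 4, max = 27),
                               male = list(mean = 18.62, sd = 8.33, min = 4, max = 29)
                             ),
                             area_weights = c(
                               "Assembly" = 0.42, "Body Construction" = 0.20,
                               "Paint" = 0.12, "Quality Assurance" = 0.10,
                               "Metal Stamping" = 0.08, "Special Projects" = 0.08
                             ),
                             appointment_count_dist = NULL,
                             noise = list(p_label_at_end = 0.10,
                                          p_misspell_token = 0.02,
                                          p_extra_space = 0.10,
                                          p_nonword_symbol = 0.10,
                                          p_caps_error = 0.10),
                             interval_model = list(
                               beta0 = 64,
                               beta = c(neck = 2, trunk = 3, shoulder_L = 3,
                                        shoulder_R = 8, elbow_L = 2, elbow_R = 2,
                                        wrist_L = 2, wrist_R = 2, fingers_L = 1,
                                        fingers_R = 1, knee_L = 1, knee_R = 1,
                                        foot_L = 1, foot_R = 1),
                               sigma = 2, min_interval = 1
                             ),
                             restriction = list(
                               n_sentence_probs = c(0.45, 0.30, 0.17, 0.08),
                               p_process_sentence = 0.08,
                               p_mn = 0.5, p_both_sides = 0.35, p_carry = 0.6
                             ),
                             language = "en",
                             scoring = scoring_config()) {
  if (is.null(appointment_count_dist)) {
    k <- c(1:7, 9:12)
    p <- 0.55^(k - 1)
    appointment_count_dist <- stats::setNames(c(p / sum(p), 0), c(k, 8))
    appointment_count_dist <- appointment_count_dist[order(as.integer(names(appointment_count_dist)))]
  }
  check_prob <- function(x, field) {
    if (!is.numeric(x) || any(is.na(x)) || any(x < 0 | x > 1)) {
      abort(sprintf("'%s' must be a probability in [0, 1]", field),
            "ohppfwa_config_error")
    }
  }
  if (!is.numeric(n_workers) || length(n_workers) != 1L || n_workers < 0) {
    abort("'n_workers' must be a non-negative count", "ohppfwa_config_error")
  }
  check_prob(p_female, "p_female")
  for (nm in names(noise)) check_prob(noise[[nm]], nm)
  check_prob(restriction$n_sentence_probs, "restriction$n_sentence_probs")
  if (abs(sum(area_weights) - 1) > 1e-8) {
    abort("'area_weights' must sum to 1", "ohppfwa_config_error")
  }
  if (abs(sum(appointment_count_dist) - 1) > 1e-8) {
    abort("'appointment_count_dist' must sum to 1", "ohppfwa_config_error")
  }
  if (!"8" %in% names(appointment_count_dist) ||
      appointment_count_dist[["8"]] != 0) {
    abort("'appointment_count_dist' must assign probability 0 to k = 8",
          "ohppfwa_config_error")
  }
  if (is.null(interval_model$beta0) || interval_model$beta0 <= 0) {
    abort("'interval_model$beta0' must be positive", "ohppfwa_config_error")
  }
  if (is.null(interval_model$min_interval) || interval_model$min_interval < 1) {
    abort("'interval_model$min_interval' must be >= 1 week", "ohppfwa_config_error")
  }
  if (!all(part_ids() %in% names(interval_model$beta))) {
    abort("'interval_model$beta' must name all 14 body parts", "ohppfwa_config_error")
  }
  structure(
    list(n_workers = as.integer(n_workers), seed = as.integer(seed),
         p_female = p_female, seniority_params = seniority_params,
         area_weights = area_weights,
         appointment_count_dist = appointment_count_dist,
         noise = noise, interval_model = interval_model,
         restriction = restriction, language = language, scoring = scoring),
    class = "ohppfwa_generator_config"
  )
}

#' Sample a visit interval from the planted linear model
#'
#' `weeks = max(min_interval, beta0 - sum(beta_p * score_p) + eps)` with
#' `eps ~ N(0, sigma)` drawn from the current RNG state. With the noise
#' term held fixed the interval is monotone non-increasing in every score.
#'
#' @param scores named per-part severity scores (missing parts count 0).
#' @param interval_model list with `beta0`, `beta`, `sigma`, `min_interval`.
#' @return interval length in weeks (numeric scalar).
#' @export
sample_interval <- function(scores, interval_model) {
  stopifnot(all(scores >= 0))
  beta <- interval_model$beta
  effect <- sum(beta[names(scores)[names(scores) %in% names(beta)]] *
                  scores[names(scores) %in% names(beta)])
  eps <- if (interval_model$sigma > 0) stats::rnorm(1, 0, interval_model$sigma) else 0
  max(interval_model$min_interval, interval_model$beta0 - effect + eps)
}

# truncated normal via rejection (clamped after 100 tries)
rtnorm1 <- function(mean, sd, lo, hi) {
  for (i in 1:100) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(stats::rnorm(1, mean, sd), lo), hi)
}

misspell_token <- function(tok) {
  n <- nchar(tok)
  if (n == 1L) return(paste0(tok, tok))          # duplicate the only char
  for (try in 1:10) {
    op <- sample(c("swap", "delete", "duplicate"), 1L)
    i <- sample.int(n - (op == "swap"), 1L)
    ch <- strsplit(tok, "")[[1]]
    out <- switch(op,
      swap = paste0(c(ch[seq_len(i - 1)], ch[i + 1], ch[i],
                      if (i + 2 <= n) ch[(i + 2):n]), collapse = ""),
      delete = paste0(ch[-i], collapse = ""),
      duplicate = paste0(c(ch[seq_len(i)], ch[i:n]), collapse = "")
    )
    if (out != tok) return(out)
  }
  paste0(tok, tok)
}

#' Render one restriction sentence
#'
#' Produces the canonical template for a `(level, parts)` group and then
#' perturbs it through five independent clerical-noise channels: level
#' label moved to the end of the sentence, per-token misspellings, extra
#' spaces, inserted non-word symbols, and capitalisation errors. With all
#' noise probabilities zero the output is exactly the canonical template.
#' Draws come from the current RNG state.
#'
#' @param level `"MN"` or `"SN"`.
#' @param parts character vector of part ids forming one sentence; empty
#'   only for the designated process-only templates.
#' @param lexicon an [load_lexicon()] object.
#' @param language language code.
#' @param noise list of noise probabilities (see [generator_config()]).
#' @param process for empty `parts`, which process template to use
#'   (`"vibration"` or `"manual_material_handling"`).
#' @return a single sentence string.
#' @export
render_sentence <- function(level, parts, lexicon, language = "en",
                            noise = list(p_label_at_end = 0, p_misspell_token = 0,
                                         p_extra_space = 0, p_nonword_symbol = 0,
                                         p_caps_error = 0),
                            process = "vibration") {
  lx <- lexicon[[language]]
  if (is.null(lx)) abort(sprintf("language '%s' not in lexicon", language),
                         "ohppfwa_config_error")
  if (length(parts) == 0L) {
    body <- lx$process_phrases[[process]]
    if (is.null(body)) {
      abort("empty parts allowed only for process-only templates",
            "ohppfwa_data_error")
    }
  } else {
    pt <- body_parts()
    idx <- match(parts, pt$part)
    if (anyNA(idx)) abort("unknown body part", "ohppfwa_data_error")
    regions <- unique(pt$region[idx])
    phrases <- vapply(regions, function(rg) {
      sides <- pt$side[idx][pt$region[idx] == rg]
      key <- if ("none" %in% sides) "none" else
        if (all(c("L", "R") %in% sides)) "both" else sides[1]
      lx$body_phrases[[rg]][[key]]
    }, character(1))
    body <- paste(phrases, collapse = paste0(" ", (lx$connectors %||% "and")[1], " "))
  }
  cue <- lx$levels[[level]][1]
  at_end <- stats::runif(1) < (noise$p_label_at_end %||% 0)
  frame <- if (at_end) lx$frame_level_end else lx$frame
  sent <- sub("{cue}", cue, sub("{body}", body, frame, fixed = TRUE), fixed = TRUE)
  substr(sent, 1, 1) <- toupper(substr(sent, 1, 1))

  p_mis <- noise$p_misspell_token %||% 0
  if (p_mis > 0) {
    toks <- strsplit(sent, " ", fixed = TRUE)[[1]]
    hit <- stats::runif(length(toks)) < p_mis
    toks[hit] <- vapply(toks[hit], misspell_token, character(1))
    sent <- paste(toks, collapse = " ")
  }
  if (stats::runif(1) < (noise$p_caps_error %||% 0)) {
    toks <- strsplit(sent, " ", fixed = TRUE)[[1]]
    i <- sample.int(length(toks), 1L)
    toks[i] <- toupper(toks[i])
    sent <- paste(toks, collapse = " ")
  }
  if (stats::runif(1) < (noise$p_extra_space %||% 0)) {
    sent <- sub(" ", "   ", sent, fixed = TRUE)
  }
  if (stats::runif(1) < (noise$p_nonword_symbol %||% 0)) {
    sent <- paste0(sent, sample(c("!!", "..", " #", " ;"), 1L))
  }
  sent
}

# sample the (level, parts) groups for one appointment, given the previous
# visit's groups (restriction persistence) or NULL for the first visit
sample_groups <- function(prev, cfg) {
  rst <- cfg$restriction
  pt <- body_parts()
  paired <- setdiff(unique(pt$region), c("neck", "trunk"))
  groups <- list()
  used_regions <- character()

  if (!is.null(prev)) {
    for (g in prev) {
      if (!length(g$parts)) next
      if (stats::runif(1) < rst$p_carry) {
        lev <- if (stats::runif(1) < 0.8) g$level else
          setdiff(c("MN", "SN"), g$level)
        groups[[length(groups) + 1L]] <- list(level = lev, parts = g$parts)
        used_regions <- c(used_regions, unique(pt$region[match(g$parts, pt$part)]))
      }
    }
  }
  n_new <- sample.int(length(rst$n_sentence_probs), 1L, prob = rst$n_sentence_probs)
  if (!is.null(prev)) n_new <- max(0L, n_new - length(groups))
  avail <- setdiff(unique(pt$region), used_regions)
  n_new <- min(n_new, length(avail))
  if (!length(groups) && n_new == 0L) n_new <- 1L
  if (n_new > 0L) {
    regions <- sample(avail, n_new)
    for (rg in regions) {
      lev <- if (stats::runif(1) < rst$p_mn) "MN" else "SN"
      parts <- if (rg %in% c("neck", "trunk")) rg else {
        if (stats::runif(1) < rst$p_both_sides) paste(rg, c("L", "R"), sep = "_")
        else paste(rg, sample(c("L", "R"), 1L), sep = "_")
      }
      groups[[length(groups) + 1L]] <- list(level = lev, parts = parts)
    }
  }
  if (stats::runif(1) < rst$p_process_sentence) {
    groups[[length(groups) + 1L]] <- list(
      level = if (stats::runif(1) < rst$p_mn) "MN" else "SN",
      parts = character(),
      process = sample(c("vibration", "manual_material_handling"), 1L))
  }
  groups
}

#' Generate a seeded synthetic cohort
#'
#' Simulates workers (gender, seniority, area, function, schedule), their
#' appointment timelines, per-appointment restriction groups with rendered
#' sentences, ground-truth per-part scores (the scoring allocation applied
#' to the true protections) and visit intervals from the planted linear
#' model. Deterministic given the config seed.
#'
#' @param config a [generator_config()].
#' @param lexicon an [load_lexicon()] object (packaged default if `NULL`).
#' @return list of appointments (class `ohppfwa_corpus`), date-ordered per
#'   worker. Each appointment carries `worker_id`, `date`, `area`, `func`,
#'   `schedule`, `seniority_years`, `gender`, `sentences` (rendered text),
#'   `groups` (true protections grouped by sentence), `true_scores` and
#'   `true_interval_weeks` (`NA` for a worker's final appointment).
#' @examples
#' corpus <- generate_cohort(generator_config(n_workers = 5, seed = 42))
#' length(corpus)
#' @export
generate_cohort <- function(config, lexicon = NULL) {
  stopifnot(inherits(config, "ohppfwa_generator_config"))
  if (is.null(lexicon)) lexicon <- load_lexicon()
  if (config$n_workers == 0L) {
    return(structure(list(), class = "ohppfwa_corpus"))
  }
  demo_rng <- rng_stream(derive_seed(config$seed, "demography"))
  rest_rng <- rng_stream(derive_seed(config$seed, "restrictions"))
  noise_rng <- rng_stream(derive_seed(config$seed, "noise"))
  int_rng <- rng_stream(derive_seed(config$seed, "intervals"))

  funcs <- c("assembly operator", "team leader", "welder", "painter",
             "quality inspector", "press operator", "logistics operator",
             "maintenance technician")
  schedules <- c("3-shift", "2-shift", "normal")

  corpus <- list()
  for (w in seq_len(config$n_workers)) {
    demo <- with_stream(demo_rng, {
      gender <- if (stats::runif(1) < config$p_female) "female" else "male"
      sp <- config$seniority_params[[gender]]
      list(
        gender = gender,
        seniority = round(rtnorm1(sp$mean, sp$sd, sp$min, sp$max), 1),
        area = sample(names(config$area_weights), 1L, prob = config$area_weights),
        func = sample(funcs, 1L),
        schedule = sample(schedules, 1L),
        n_app = as.integer(sample(names(config$appointment_count_dist), 1L,
                                  prob = config$appointment_count_dist)),
        start = as.Date("2019-01-01") + sample.int(365L, 1L) - 1L
      )
    })

    groups_list <- with_stream(rest_rng, {
      out <- vector("list", demo$n_app)
      prev <- NULL
      for (j in seq_len(demo$n_app)) {
        out[[j]] <- sample_groups(prev, config)
        prev <- out[[j]]
      }
      out
    })

    date <- demo$start
    for (j in seq_len(demo$n_app)) {
      groups <- groups_list[[j]]
      sentences <- with_stream(noise_rng, {
        vapply(groups, function(g) {
          render_sentence(g$level, g$parts, lexicon, config$language,
                          config$noise, process = g$process %||% "vibration")
        }, character(1))
      })
      scores <- allocate_scores(groups, config$scoring)
      interval <- if (j < demo$n_app) {
        with_stream(int_rng, {
          round_half_up(sample_interval(scores, config$interval_model))
        })
      } else NA_real_
      interval <- max(interval, config$interval_model$min_interval, na.rm = FALSE)
      corpus[[length(corpus) + 1L]] <- list(
        worker_id = sprintf("W%04d", w),
        date = date,
        area = demo$area, func = demo$func, schedule = demo$schedule,
        seniority_years = demo$seniority, gender = demo$gender,
        sentences = sentences,
        groups = groups,
        true_scores = scores,
        true_interval_weeks = interval
      )
      if (!is.na(interval)) date <- date + interval * 7L
    }
  }
  structure(corpus, class = "ohppfwa_corpus")
}

#' Keep only workers with at least two appointments
#'
#' The modelling cohort drops single-appointment workers (their record has
#' no next visit to predict); this helper exposes that second cohort view.
#'
#' @param corpus an `ohppfwa_corpus`.
#' @return filtered `ohppfwa_corpus`.
#' @export
filter_multi_visit <- function(corpus) {
  ids <- vapply(corpus, `[[`, character(1), "worker_id")
  keep <- ids %in% names(which(table(ids) >= 2L))
  structure(corpus[keep], class = "ohppfwa_corpus")
}

#' Write / read a corpus as JSON-lines
#'
#' One appointment per line; dates as ISO-8601 strings; `NA` intervals as
#' JSON null. `read_corpus()` restores the exact structure.
#'
#' @param corpus an `ohppfwa_corpus`.
#' @param path file path.
#' @return `write_corpus()` returns `path` invisibly; `read_corpus()` an
#'   `ohppfwa_corpus`.
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(corpus, function(app) {
    app$date <- format(app$date)
    app$true_scores <- as.list(app$true_scores)
    jsonlite::toJSON(app, auto_unbox = TRUE, null = "null", na = "null",
                     digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  corpus <- lapply(lines, function(ln) {
    app <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    app$date <- as.Date(app$date)
    app$sentences <- as.character(unlist(app$sentences))
    app$groups <- lapply(app$groups, function(g) {
      out <- list(level = g$level, parts = as.character(unlist(g$parts)))
      if (!is.null(g$process)) out$process <- g$process
      out
    })
    app$true_scores <- unlist(app$true_scores)
    app$true_interval_weeks <- if (is.null(app$true_interval_weeks))
      NA_real_ else as.numeric(app$true_interval_weeks)
    app$seniority_years <- as.numeric(app$seniority_years)
    app
  })
  structure(corpus, class = "ohppfwa_corpus")
}

#' Flat table view of a corpus
#'
#' @param corpus an `ohppfwa_corpus`.
#' @return data.frame with metadata, ground-truth `score_<part>` columns
#'   and `true_interval_weeks`.
#' @export
corpus_to_table <- function(corpus) {
  rows <- lapply(corpus, function(app) {
    sc <- as.data.frame(as.list(app$true_scores))
    names(sc) <- paste0("score_", part_ids())
    cbind(data.frame(worker_id = app$worker_id, date = app$date,
                     area = app$area, func = app$func,
                     schedule = app$schedule,
                     seniority_years = app$seniority_years,
                     gender = app$gender, stringsAsFactors = FALSE),
          sc,
          data.frame(true_interval_weeks = app$true_interval_weeks))
  })
  do.call(rbind, rows)
}
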