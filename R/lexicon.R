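#' Load a restriction-sentence lexicon
#'
#' The lexicon is an editable YAML file holding, per language, the
#' protection-level cue phrases, body-part keywords, laterality markers,
#' process-only keywords and the canonical sentence templates used by the
#' synthetic generator. The packaged default covers Portuguese (the language
#' protection profiles are written in) and an English mirror.
#'
#' @param path path to a lexicon YAML file; `NULL` loads the packaged default.
#' @return A list with one entry per language code; class `ohppfwa_lexicon`.
#' @examples
#' lex <- load_lexicon()
#' names(lex)
#' @export
load_lexicon <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "lexicon.yaml", package = "ohppfwa")
  }
  if (!nzchar(path) || !file.exists(path)) {
    abort(sprintf("lexicon file not found: '%s'", path), "ohppfwa_config_error")
  }
  raw <- yaml::read_yaml(path)
  langs <- raw$languages
  if (is.null(langs) || !length(langs)) {
    abort("lexicon file has no 'languages' section", "ohppfwa_config_error")
  }
  for (lang in names(langs)) {
    lx <- langs[[lang]]
    for (field in c("levels", "frame", "regions", "laterality", "body_phrases")) {
      if (is.null(lx[[field]])) {
        abort(sprintf("lexicon language '%s' is missing '%s'", lang, field),
              "ohppfwa_config_error")
      }
    }
  }
  structure(langs, class = "ohppfwa_lexicon")
}
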