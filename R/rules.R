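# Rule engine: case-insensitive regular-expression concept extraction per
# sentence, with exclusion contexts suppressing a rule's matches when any
# of its exclusion expressions also matches the sentence, and
# source-specific applicability. Overlapping matches within an element
# are resolved leftmost-longest.

#' Load an extraction ruleset
#'
#' Reads a rule configuration from YAML (see the shipped
#' `extdata/ruleset.yaml`). Each rule carries an element, a
#' case-insensitive Perl regular expression, the capture group holding
#' the value to normalize (0 for the whole match), the sources it applies
#' to, and zero or more exclusion-context expressions. Every pattern must
#' compile and every element must have at least one rule unless
#' `partial = TRUE`.
#'
#' @param path Path to a YAML rule configuration, or `NULL` for the
#'   shipped default.
#' @param partial Allow a ruleset that does not cover all six elements
#'   (such a ruleset can only be used for the elements it covers).
#' @return A tibble of class `lc_ruleset` with columns `element`,
#'   `rule_id`, `pattern`, `capture`, and list-columns `sources` and
#'   `exclusions`; the configured negation cues (disabled by default at
#'   extraction time) are attached as attribute `negation_cues`.
#' @export
load_ruleset <- function(path = NULL, partial = FALSE) {
  if (is.null(path)) {
    path <- system.file("extdata", "ruleset.yaml", package = "lungnlp")
  }
  if (!file.exists(path)) {
    abort(paste0("Rule configuration not found: ", path),
          class = "lungnlp_config_error")
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$rules) || !length(cfg$rules)) {
    abort("Rule configuration has no rules.", class = "lungnlp_config_error")
  }
  rules <- purrr::map_dfr(cfg$rules, function(r) {
    for (f in c("element", "id", "pattern", "capture", "sources")) {
      if (is.null(r[[f]])) {
        abort(paste0("Rule '", r$id %||% "<unnamed>",
                     "' is missing field '", f, "'."),
              class = "lungnlp_config_error")
      }
    }
    tibble(
      element = r$element, rule_id = r$id, pattern = r$pattern,
      capture = as.integer(r$capture),
      sources = list(unlist(r$sources)),
      exclusions = list(as.character(unlist(r$exclusions)))
    )
  })
  bad_el <- setdiff(unique(rules$element), lc_elements())
  if (length(bad_el)) {
    abort(paste0("Rules for unknown element(s): ",
                 paste(bad_el, collapse = ", ")),
          class = "lungnlp_config_error")
  }
  bad_src <- setdiff(unique(unlist(rules$sources)), lc_sources())
  if (length(bad_src)) {
    abort(paste0("Rules name unknown source(s): ",
                 paste(bad_src, collapse = ", ")),
          class = "lungnlp_config_error")
  }
  for (i in seq_len(nrow(rules))) {
    for (p in c(rules$pattern[i], rules$exclusions[[i]])) {
      ok <- tryCatch({
        suppressWarnings(regexpr(p, "probe", perl = TRUE,
                                 ignore.case = TRUE))
        TRUE
      }, error = function(e) FALSE)
      if (!ok) {
        abort(paste0("Pattern for rule '", rules$rule_id[i],
                     "' does not compile: ", p),
              class = "lungnlp_config_error")
      }
    }
  }
  if (!partial) {
    uncovered <- setdiff(lc_elements(), unique(rules$element))
    if (length(uncovered)) {
      abort(paste0("Ruleset has no rules for: ",
                   paste(uncovered, collapse = ", "),
                   " (use partial = TRUE for a restricted ruleset)."),
            class = "lungnlp_config_error")
    }
  }
  structure(rules,
            class = c("lc_ruleset", class(rules)),
            version = cfg$version %||% "unversioned",
            negation_cues = as.character(unlist(cfg$negation_cues)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The shipped default ruleset
#'
#' Loads (and caches) the rule configuration shipped with the package.
#'
#' @return An `lc_ruleset` tibble; see [load_ruleset()].
#' @export
default_ruleset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_ruleset()
    cache
  }
})

#' Drop exclusion contexts from a ruleset
#'
#' Returns the same ruleset with every exclusion-context list emptied;
#' useful for studying how much the suppression mechanism contributes.
#'
#' @param ruleset An `lc_ruleset`.
#' @return The ruleset without exclusions.
#' @export
strip_exclusions <- function(ruleset) {
  ruleset$exclusions <- purrr::map(ruleset$exclusions, ~character(0))
  ruleset
}

# All matches of one pattern in one string, with 0-based offsets and the
# requested capture group (falls back to the whole match for group 0 or
# an unmatched group).
harvest_matches <- function(match_obj, text, capture) {
  starts <- as.integer(match_obj)
  if (starts[1] == -1L) return(NULL)
  lens <- attr(match_obj, "match.length")
  full <- substring(text, starts, starts + lens - 1L)
  value <- full
  if (capture > 0L && !is.null(attr(match_obj, "capture.start"))) {
    cs <- attr(match_obj, "capture.start")[, capture]
    cl <- attr(match_obj, "capture.length")[, capture]
    got <- cs > 0L
    value[got] <- substring(text, cs[got], cs[got] + cl[got] - 1L)
  }
  tibble(start = starts - 1L, end = starts + lens - 1L,
         raw_text = full, value_text = value)
}

# Leftmost-longest selection of non-overlapping spans: sort by start,
# then by descending length, and keep a span only if it starts at or
# after the end of the last kept span.
resolve_overlaps <- function(df) {
  if (nrow(df) <= 1L) return(df)
  df <- df[order(df$start, -(df$end - df$start)), ]
  keep <- logical(nrow(df))
  last_end <- -1L
  for (i in seq_len(nrow(df))) {
    if (df$start[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- df$end[i]
    }
  }
  df[keep, ]
}

#' Extract concept mentions from sentences
#'
#' Runs every applicable rule over each sentence. A rule applies when the
#' sentence's source is in the rule's source list and none of the rule's
#' exclusion contexts matches anywhere in the sentence. Matching is
#' case-insensitive; overlapping matches within one element are resolved
#' leftmost-longest; each surviving match is normalized to its canonical
#' value.
#'
#' @param sentences A sentence table as produced by [segment_sentences()],
#'   plus a `source` column (use [extract_document()] to go straight from
#'   documents).
#' @param ruleset An [load_ruleset()] ruleset.
#' @param normalization A normalization table.
#' @param apply_negation Also suppress matches in sentences containing one
#'   of the ruleset's negation cues (off by default, mirroring a system
#'   with no general negation detection).
#' @return A tibble of mentions: `doc_id`, `sentence_id`, `source`,
#'   `element`, `rule_id`, `raw_text`, `value_text`, `start`, `end`
#'   (0-based, sentence-relative), `normalized`.
#' @examples
#' sents <- tibble::tibble(doc_id = "d1", sentence_id = 1L, start = 0L,
#'                         end = 44L, source = "pathology_report",
#'                         text = "Pathology showed stage IIIa adenocarcinoma.")
#' extract_mentions(sents)
#' @export
extract_mentions <- function(sentences, ruleset = default_ruleset(),
                             normalization = the_default_norm_table(),
                             apply_negation = FALSE) {
  stopifnot(all(c("doc_id", "sentence_id", "text", "source") %in%
                  names(sentences)))
  texts <- sentences$text
  n <- length(texts)
  if (!n) return(empty_mentions())
  cues <- attr(ruleset, "negation_cues")
  negated <- if (apply_negation && length(cues)) {
    Reduce(`|`, lapply(cues, function(p) {
      grepl(p, texts, perl = TRUE, ignore.case = TRUE)
    }))
  } else rep(FALSE, n)

  out <- vector("list", nrow(ruleset))
  for (i in seq_len(nrow(ruleset))) {
    idx <- which(sentences$source %in% ruleset$sources[[i]] & !negated)
    if (!length(idx)) next
    for (ex in ruleset$exclusions[[i]]) {
      if (!length(idx)) break
      hit <- grepl(ex, texts[idx], perl = TRUE, ignore.case = TRUE)
      idx <- idx[!hit]
    }
    if (!length(idx)) next
    mo <- gregexpr(ruleset$pattern[i], texts[idx], perl = TRUE,
                   ignore.case = TRUE)
    found <- purrr::imap(mo, function(m, j) {
      h <- harvest_matches(m, texts[idx[j]], ruleset$capture[i])
      if (is.null(h)) return(NULL)
      h$row <- idx[j]
      h
    })
    found <- dplyr::bind_rows(found)
    if (!nrow(found)) next
    found$element <- ruleset$element[i]
    found$rule_id <- ruleset$rule_id[i]
    out[[i]] <- found
  }
  cand <- dplyr::bind_rows(out)
  if (!nrow(cand)) return(empty_mentions())

  cand <- cand %>%
    group_by(.data$row, .data$element) %>%
    dplyr::group_modify(~resolve_overlaps(.x)) %>%
    ungroup()

  cand$doc_id <- sentences$doc_id[cand$row]
  cand$sentence_id <- sentences$sentence_id[cand$row]
  cand$source <- sentences$source[cand$row]
  cand$normalized <- NA_character_
  for (el in unique(cand$element)) {
    sel <- cand$element == el
    cand$normalized[sel] <- normalize_value(cand$value_text[sel], el,
                                            normalization)
  }
  cand %>%
    select("doc_id", "sentence_id", "source", "element", "rule_id",
           "raw_text", "value_text", "start", "end", "normalized") %>%
    arrange(.data$doc_id, .data$sentence_id, .data$start)
}

empty_mentions <- function() {
  tibble(doc_id = character(), sentence_id = integer(),
         source = character(), element = character(),
         rule_id = character(), raw_text = character(),
         value_text = character(), start = integer(), end = integer(),
         normalized = character())
}

#' Extract mentions from whole documents
#'
#' Segments each document into sentences and extracts normalized concept
#' mentions; the union over sentences of [extract_mentions()].
#'
#' @param documents A document table ([clinical_documents()]).
#' @param ruleset,normalization,apply_negation See [extract_mentions()].
#' @return A mention tibble with `patient_id` and document `date` joined
#'   on.
#' @export
extract_document <- function(documents, ruleset = default_ruleset(),
                             normalization = the_default_norm_table(),
                             apply_negation = FALSE) {
  documents <- clinical_documents(documents)
  sents <- segment_sentences(documents)
  sents <- left_join(sents,
                     documents[, c("doc_id", "patient_id", "source", "date")],
                     by = "doc_id")
  mentions <- extract_mentions(sents, ruleset, normalization, apply_negation)
  left_join(mentions,
            documents[, c("doc_id", "patient_id", "date")],
            by = "doc_id")
}
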