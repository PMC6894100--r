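# Corpus model: dated clinical documents tied to patients, sentence
# segmentation, and diagnosis-anchored time-window document selection.
#
# Documents live in a tibble (doc_id, patient_id, source,
# pathology_subtype, date, text); patients in a tibble (patient_id,
# diagnosis_date). Sources are clinical notes (used without any time
# limitation), pathology reports (cytology / general pathology /
# consultation; windowed; stage/histology/grade only) and surgery
# reports (windowed; all elements).

#' Validate a clinical-document table
#'
#' Checks and coerces a data frame of clinical documents to the layout
#' used throughout the package: columns `doc_id`, `patient_id`, `source`
#' (one of [lc_sources()]), `pathology_subtype` (present iff the source is
#' a pathology report), `date` (`Date`) and `text` (non-empty).
#'
#' @param documents A data frame of documents.
#' @return A validated tibble.
#' @export
clinical_documents <- function(documents) {
  documents <- as_tibble(documents)
  required <- c("doc_id", "patient_id", "source", "date", "text")
  missing_cols <- setdiff(required, names(documents))
  if (length(missing_cols)) {
    abort(paste0("Document table is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "lungnlp_config_error")
  }
  if (!"pathology_subtype" %in% names(documents)) {
    documents$pathology_subtype <- NA_character_
  }
  documents$date <- as.Date(documents$date)
  bad_source <- setdiff(unique(documents$source), lc_sources())
  if (length(bad_source)) {
    abort(paste0("Unknown document source(s): ",
                 paste(bad_source, collapse = ", ")),
          class = "lungnlp_config_error")
  }
  if (any(!nzchar(documents$text) | is.na(documents$text))) {
    abort("Every document must have non-empty text.",
          class = "lungnlp_config_error")
  }
  is_path <- documents$source == "pathology_report"
  if (any(is_path & is.na(documents$pathology_subtype))) {
    abort("Pathology reports must carry a pathology_subtype.",
          class = "lungnlp_config_error")
  }
  if (any(!is_path & !is.na(documents$pathology_subtype))) {
    abort("pathology_subtype is only valid for pathology reports.",
          class = "lungnlp_config_error")
  }
  bad_sub <- setdiff(stats::na.omit(unique(documents$pathology_subtype)),
                     lc_pathology_subtypes())
  if (length(bad_sub)) {
    abort(paste0("Unknown pathology subtype(s): ",
                 paste(bad_sub, collapse = ", ")),
          class = "lungnlp_config_error")
  }
  if (anyDuplicated(documents$doc_id)) {
    abort("doc_id values must be unique.", class = "lungnlp_config_error")
  }
  documents
}

#' Validate a patient table
#'
#' @param patients A data frame with `patient_id` and `diagnosis_date`.
#' @return A validated tibble with `diagnosis_date` as `Date`.
#' @export
patient_records <- function(patients) {
  patients <- as_tibble(patients)
  if (!all(c("patient_id", "diagnosis_date") %in% names(patients))) {
    abort("Patient table needs patient_id and diagnosis_date.",
          class = "lungnlp_config_error")
  }
  patients$diagnosis_date <- as.Date(patients$diagnosis_date)
  if (anyNA(patients$diagnosis_date)) {
    abort("Every patient needs a diagnosis_date.",
          class = "lungnlp_config_error")
  }
  if (anyDuplicated(patients$patient_id)) {
    abort("patient_id values must be unique.",
          class = "lungnlp_config_error")
  }
  patients
}

#' Diagnosis-anchored time window
#'
#' A window of whole days around the diagnosis date, inclusive on both
#' boundaries: a document dated between `diagnosis_date - days_before` and
#' `diagnosis_date + days_after` falls inside.
#'
#' @param days_before Non-negative days before diagnosis (default 14).
#' @param days_after Non-negative days after diagnosis.
#' @return An object of class `time_window`.
#' @examples
#' time_window(14, 90)
#' @export
time_window <- function(days_before = 14, days_after = 90) {
  if (days_before < 0 || days_after < 0) {
    abort("Window days must be non-negative.",
          class = "lungnlp_config_error")
  }
  structure(list(days_before = as.integer(days_before),
                 days_after = as.integer(days_after)),
            class = "time_window")
}

#' @export
print.time_window <- function(x, ...) {
  cat(sprintf("<time_window: %d days before to %d days after diagnosis>\n",
              x$days_before, x$days_after))
  invisible(x)
}

#' Is a document date inside a diagnosis-anchored window?
#'
#' Both boundaries are inclusive; missing document dates return `FALSE`.
#'
#' @param doc_date,diagnosis_date `Date` vectors (recycled).
#' @param window A [time_window()].
#' @return Logical vector.
#' @examples
#' is_within_window(as.Date("2005-05-18"), as.Date("2005-06-01"),
#'                  time_window(14, 90))
#' @export
is_within_window <- function(doc_date, diagnosis_date, window) {
  stopifnot(inherits(window, "time_window"))
  doc_date <- as.Date(doc_date)
  diagnosis_date <- as.Date(diagnosis_date)
  delta <- as.integer(doc_date - diagnosis_date)
  out <- delta >= -window$days_before & delta <= window$days_after
  out[is.na(out)] <- FALSE
  out
}

# Sentence segmentation -------------------------------------------------

# Deterministic rule-based splitter: a terminal-punctuation run followed
# by whitespace starts a new sentence when the next non-space character is
# an uppercase letter or a digit, unless the token ending at the
# punctuation is a known abbreviation or a single-letter initial.
lc_abbreviations <- function() {
  c("dr", "mr", "mrs", "ms", "st", "vs", "e.g", "i.e", "etc", "no", "fig")
}

split_sentence_spans <- function(text, abbreviations = lc_abbreviations()) {
  if (is.na(text) || !nzchar(text)) {
    abort("Cannot segment empty text.", class = "lungnlp_empty_input")
  }
  n <- nchar(text)
  m <- stringr::str_locate_all(text, "[.!?]+(?=\\s)")[[1]]
  cuts <- integer(0)
  if (nrow(m)) {
    for (i in seq_len(nrow(m))) {
      end <- m[i, "end"]
      rest <- substr(text, end + 1L, n)
      nxt <- stringr::str_match(rest, "^\\s+(\\S)")[, 2]
      if (is.na(nxt) || !grepl("[A-Z0-9]", nxt)) next
      prefix <- substr(text, 1L, end)
      word <- stringr::str_match(prefix, "([A-Za-z][A-Za-z.]*)[.!?]+$")[, 2]
      if (!is.na(word)) {
        if (tolower(word) %in% abbreviations) next
        # single capitals read as name initials, except Roman-numeral
        # letters, which end clinical sentences ("grade I.")
        if (nchar(word) == 1L && grepl("[A-Z]", word) &&
            !word %in% c("I", "V", "X")) next
      }
      cuts <- c(cuts, end)
    }
  }
  starts0 <- c(0L, cuts)              # 0-based candidate starts
  ends0 <- c(cuts, n)
  spans <- purrr::map2(starts0, ends0, function(s, e) {
    piece <- substr(text, s + 1L, e)
    lead <- nchar(piece) - nchar(sub("^\\s+", "", piece))
    trail <- nchar(piece) - nchar(sub("\\s+$", "", piece))
    s2 <- s + lead
    e2 <- e - trail
    if (e2 <= s2) return(NULL)
    tibble(start = s2, end = e2, text = substr(text, s2 + 1L, e2))
  })
  out <- dplyr::bind_rows(spans)
  if (!nrow(out)) {
    abort("Text contains no non-whitespace characters.",
          class = "lungnlp_empty_input")
  }
  out$sentence_id <- seq_len(nrow(out))
  out[, c("sentence_id", "start", "end", "text")]
}

#' Segment documents into sentences
#'
#' A deterministic rule-based splitter: sentences break after terminal
#' punctuation (`.`, `!`, `?`) followed by whitespace and an uppercase
#' letter or digit, with a configurable abbreviation stop-list
#' ("Dr.", "vs.", ...). Offsets are 0-based with half-open ends, relative
#' to the document text; spans exclude surrounding whitespace.
#'
#' @param documents A document table ([clinical_documents()]) or any data
#'   frame with `doc_id` and `text`.
#' @param abbreviations Lower-cased tokens that never end a sentence.
#' @return A tibble with `doc_id`, `sentence_id`, `start`, `end`, `text`.
#' @examples
#' docs <- tibble::tibble(doc_id = "d1", text = "Stage IIIa. Patient declined chemo.")
#' segment_sentences(docs)
#' @export
segment_sentences <- function(documents,
                              abbreviations = lc_abbreviations()) {
  stopifnot(all(c("doc_id", "text") %in% names(documents)))
  purrr::map2_dfr(documents$doc_id, documents$text, function(id, txt) {
    spans <- split_sentence_spans(txt, abbreviations)
    spans$doc_id <- id
    spans[, c("doc_id", "sentence_id", "start", "end", "text")]
  })
}

# Source applicability --------------------------------------------------

# Which sources may contribute to which element: pathology reports never
# feed the therapy elements; clinical notes and surgery reports feed all
# six.
element_sources <- function(element) {
  element <- match_element(element)
  if (element %in% c("stage", "histology", "grade")) {
    lc_sources()
  } else {
    c("clinical_note", "surgery_report")
  }
}

#' Select a patient's documents for one element and window
#'
#' Applies the source-applicability and time-window rules: clinical notes
#' are always included without any time limitation; pathology reports are
#' included only for stage, histology and grade, and only within the
#' window; surgery reports are included within the window for every
#' element (callers typically pass a 14/365-day window for the therapy
#' elements). Documents with a missing date are dropped from the windowed
#' sources but clinical notes are retained.
#'
#' @param documents A document table.
#' @param patients A patient table (supplies `diagnosis_date`).
#' @param element One of [lc_elements()].
#' @param window A [time_window()].
#' @return The eligible subset of `documents` (a tibble).
#' @export
select_documents <- function(documents, patients, element,
                             window = time_window(14, 90)) {
  element <- match_element(element)
  stopifnot(inherits(window, "time_window"))
  docs <- dplyr::left_join(
    as_tibble(documents),
    patient_records(patients)[, c("patient_id", "diagnosis_date")],
    by = "patient_id"
  )
  keep_source <- docs$source %in% element_sources(element)
  windowed <- docs$source != "clinical_note"
  in_win <- is_within_window(docs$date, docs$diagnosis_date, window)
  keep <- keep_source & (!windowed | in_win)
  out <- docs[keep, setdiff(names(docs), "diagnosis_date")]
  as_tibble(out)
}

# Corpus I/O ------------------------------------------------------------

#' Read / write a corpus directory
#'
#' A corpus directory holds `documents.csv` (doc_id, patient_id, source,
#' pathology_subtype, date ISO-8601, text) and `patients.csv` (patient_id,
#' diagnosis_date ISO-8601); document bodies are stored inline as UTF-8
#' text.
#'
#' @param dir Directory path.
#' @param documents,patients Validated tables (see [clinical_documents()],
#'   [patient_records()]).
#' @return `read_corpus()` returns `list(documents, patients)`;
#'   `write_corpus()` returns `dir` invisibly.
#' @export
read_corpus <- function(dir) {
  docs <- readr::read_csv(file.path(dir, "documents.csv"),
                          col_types = readr::cols(
                            date = readr::col_date(),
                            .default = readr::col_character()
                          ), progress = FALSE)
  pats <- readr::read_csv(file.path(dir, "patients.csv"),
                          col_types = readr::cols(
                            diagnosis_date = readr::col_date(),
                            .default = readr::col_character()
                          ), progress = FALSE)
  list(documents = clinical_documents(docs),
       patients = patient_records(pats))
}

#' @rdname read_corpus
#' @export
write_corpus <- function(documents, patients, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(clinical_documents(documents),
                   file.path(dir, "documents.csv"))
  readr::write_csv(patient_records(patients),
                   file.path(dir, "patients.csv"))
  invisible(dir)
}
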