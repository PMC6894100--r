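# Discordance resolution.
#
# Within one source, the most frequently extracted concept wins; a
# frequency tie is broken by preferring an exact stage over a nonexact
# stage and then the more severe concept. Across sources, disagreement is
# settled by the priority pathology report > clinical note > surgery
# report. Therapy elements are flagged true on any eligible mention.

#' Resolve discordant mentions within one source
#'
#' Picks the modal value from a multiset of normalized values. Frequency
#' ties are broken by the severity order ([severity_rank()]); for stage,
#' an exact stage is preferred over a nonexact stage first. A stage tie
#' spanning the SCLC and NSCLC value sets falls back to whichever disease
#' class carries more mentions overall (NSCLC on a class tie), then to
#' severity within that class.
#'
#' @param values Character vector (with repeats) of normalized values for
#'   one element; `NA`s are dropped.
#' @param element One of `stage`, `histology`, `grade`.
#' @return The resolved canonical value, or `NA_character_` for an empty
#'   multiset.
#' @examples
#' resolve_within_source(c("Ia", "Ia", "Ia", "Ib"), "stage")
#' resolve_within_source(c("Ia", "EarlyStage"), "stage")   # exact wins
#' resolve_within_source(c("Ia", "Ia", "IIIa", "IIIa"), "stage") # severity
#' @export
resolve_within_source <- function(values, element) {
  element <- match_element(element)
  if (!element %in% c("stage", "histology", "grade")) {
    abort("resolve_within_source() applies to stage, histology and grade.",
          class = "lungnlp_domain_error")
  }
  values <- values[!is.na(values)]
  if (!length(values)) return(NA_character_)
  legal <- lc_element_values(element)
  bad <- setdiff(values, legal)
  if (length(bad)) {
    abort(paste0("Values not valid for element '", element, "': ",
                 paste(bad, collapse = ", ")),
          class = "lungnlp_domain_error")
  }
  tab <- table(values)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1L) return(top)
  if (element == "stage") {
    classes <- stage_disease_class(top)
    if (length(unique(classes)) > 1L) {
      all_classes <- stage_disease_class(values)
      n_nsclc <- sum(all_classes == "NSCLC")
      n_sclc <- sum(all_classes == "SCLC")
      chosen <- if (n_sclc > n_nsclc) "SCLC" else "NSCLC"
      top <- top[classes == chosen]
    }
    exact <- top[stage_exactness(top) == "exact"]
    if (length(exact)) top <- exact
  }
  top[which.max(severity_rank(top, element))]
}

#' Combine per-source results across sources
#'
#' When a patient's resolved per-source values disagree, the pathology
#' report result is used; failing that, the clinical-note result; failing
#' that, the surgery-report result. Agreement (or a single available
#' source) returns that value; all-absent returns `NA`.
#'
#' @param per_source A named character vector (or 1-row data frame /
#'   named list) with entries for any of `clinical_note`,
#'   `pathology_report`, `surgery_report`; missing or `NA` entries mean
#'   the source yielded nothing.
#' @return A single canonical value or `NA_character_`.
#' @examples
#' combine_across_sources(c(pathology_report = "Adenocarcinoma",
#'                          clinical_note = "NSCLCUnspecified"))
#' @export
combine_across_sources <- function(per_source) {
  per_source <- unlist(per_source)
  if (is.null(names(per_source)) && length(per_source)) {
    abort("per_source must be named by source.",
          class = "lungnlp_domain_error")
  }
  bad <- setdiff(names(per_source), lc_sources())
  if (length(bad)) {
    abort(paste0("Unknown source(s): ", paste(bad, collapse = ", ")),
          class = "lungnlp_domain_error")
  }
  present <- per_source[!is.na(per_source)]
  if (!length(present)) return(NA_character_)
  if (length(unique(present)) == 1L) return(unname(present[1]))
  for (src in c("pathology_report", "clinical_note", "surgery_report")) {
    if (src %in% names(present)) return(unname(present[[src]]))
  }
  NA_character_
}

#' Resolve therapy flags from mentions
#'
#' Each therapy is flagged true iff at least one mention of it exists in
#' the (already source- and window-filtered) mention set.
#'
#' @param mentions A mention tibble ([extract_mentions()] layout); only
#'   rows for the therapy elements are consulted.
#' @return A one-row tibble with logical `chemotherapy`, `radiotherapy`,
#'   `surgery`.
#' @export
resolve_therapies <- function(mentions) {
  tibble(
    chemotherapy = any(mentions$element == "chemotherapy"),
    radiotherapy = any(mentions$element == "radiotherapy"),
    surgery = any(mentions$element == "surgery")
  )
}

# Full per-patient pipeline ---------------------------------------------

#' Extract resolved data elements for every patient
#'
#' Runs the whole pipeline: select eligible documents per element
#' (clinical notes unwindowed; pathology and surgery reports inside
#' `window` for stage/histology/grade; clinical notes plus surgery
#' reports inside `therapy_window` for the therapy elements), extract and
#' normalize mentions, resolve discordance within each source, and
#' combine across sources by pathology-first priority.
#'
#' @param documents,patients Corpus tables.
#' @param ruleset,normalization,apply_negation See [extract_mentions()].
#' @param window [time_window()] for stage/histology/grade document
#'   selection (default 14 days before to 90 after diagnosis).
#' @param therapy_window [time_window()] for surgery-report eligibility on
#'   the therapy elements (default 14 before to 365 after).
#' @return A tibble with one row per patient: `patient_id`, combined
#'   `stage`, `histology`, `grade`, logical `chemotherapy`,
#'   `radiotherapy`, `surgery`, plus per-source columns
#'   `<element>_<source>` for the categorical elements.
#' @export
extract_patients <- function(documents, patients,
                             ruleset = default_ruleset(),
                             normalization = the_default_norm_table(),
                             window = time_window(14, 90),
                             therapy_window = time_window(14, 365),
                             apply_negation = FALSE) {
  documents <- clinical_documents(documents)
  patients <- patient_records(patients)
  mentions <- if (nrow(documents)) {
    extract_document(documents, ruleset, normalization, apply_negation)
  } else empty_mentions()

  out <- tibble(patient_id = patients$patient_id)
  categorical <- c("stage", "histology", "grade")
  for (el in categorical) {
    eligible <- select_documents(documents, patients, el, window)
    sub <- mentions[mentions$element == el &
                      mentions$doc_id %in% eligible$doc_id, ]
    per_source <- sub %>%
      group_by(.data$patient_id, .data$source) %>%
      summarise(value = resolve_within_source(.data$normalized, .env$el),
                .groups = "drop")
    wide <- tidyr::pivot_wider(per_source, names_from = "source",
                               values_from = "value")
    for (src in lc_sources()) {
      if (!src %in% names(wide)) wide[[src]] <- NA_character_
    }
    combined <- purrr::pmap_chr(
      wide[, lc_sources()],
      function(clinical_note, pathology_report, surgery_report) {
        combine_across_sources(c(clinical_note = clinical_note,
                                 pathology_report = pathology_report,
                                 surgery_report = surgery_report))
      })
    res <- tibble(patient_id = wide$patient_id, combined = combined)
    names(res)[2] <- el
    for (src in lc_sources()) {
      res[[paste0(el, "_", src)]] <- wide[[src]]
    }
    out <- left_join(out, res, by = "patient_id")
  }

  for (el in c("chemotherapy", "radiotherapy", "surgery")) {
    eligible <- select_documents(documents, patients, el, therapy_window)
    sub <- mentions[mentions$element == el &
                      mentions$doc_id %in% eligible$doc_id, ]
    out[[el]] <- out$patient_id %in% unique(sub$patient_id)
  }
  out
}

#' Write / read a patient-extraction table
#'
#' CSV round-trip for the output of [extract_patients()].
#'
#' @param extractions Extraction tibble.
#' @param path CSV path.
#' @return `write_extractions()` returns `path` invisibly;
#'   `read_extractions()` the tibble.
#' @export
write_extractions <- function(extractions, path) {
  readr::write_csv(extractions, path)
  invisible(path)
}

#' @rdname write_extractions
#' @export
read_extractions <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    chemotherapy = readr::col_logical(),
    radiotherapy = readr::col_logical(),
    surgery = readr::col_logical(),
    .default = readr::col_character()
  ), progress = FALSE)
}
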