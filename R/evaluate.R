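# Patient-level evaluation against a reference standard.
#
# For each element: A = patients carrying the element in the reference,
# B = patients whose extracted value is true under the element's matching
# rule, C = patients with any extracted value. Precision1 = B/A,
# Precision2 = B/C, Recall = C/A, so Precision1 = Precision2 x Recall
# identically. Histology matching is hierarchical (a predicted NSCLC
# subtype is a true positive against a reference that only says
# non-small cell); stage matching maps an exact prediction onto the
# early/late band when the reference is nonexact; grade and the therapy
# flags use exact equality.

#' Read / write a reference standard
#'
#' CSV with columns `patient_id`, `stage`, `histology`, `grade`,
#' `chemotherapy`, `radiotherapy`, `surgery`; canonical value names,
#' empty cells for elements absent from the reference.
#'
#' @param path CSV path.
#' @param reference Reference tibble.
#' @return `read_reference()` returns the tibble; `write_reference()`
#'   returns `path` invisibly.
#' @export
read_reference <- function(path) {
  ref <- readr::read_csv(path, col_types = readr::cols(
    chemotherapy = readr::col_logical(),
    radiotherapy = readr::col_logical(),
    surgery = readr::col_logical(),
    .default = readr::col_character()
  ), progress = FALSE)
  validate_reference(ref)
}

#' @rdname read_reference
#' @export
write_reference <- function(reference, path) {
  readr::write_csv(validate_reference(reference), path)
  invisible(path)
}

validate_reference <- function(reference) {
  reference <- as_tibble(reference)
  if (!"patient_id" %in% names(reference)) {
    abort("Reference standard needs a patient_id column.",
          class = "lungnlp_config_error")
  }
  for (el in c("stage", "histology", "grade")) {
    if (!el %in% names(reference)) next
    bad <- setdiff(stats::na.omit(unique(reference[[el]])),
                   lc_element_values(el))
    if (length(bad)) {
      abort(paste0("Non-canonical ", el, " values in reference: ",
                   paste(bad, collapse = ", ")),
            class = "lungnlp_config_error")
    }
  }
  reference
}

#' Does a predicted value match the reference value?
#'
#' Implements the hierarchical matching rules: histology matches on
#' equality, or when the reference holds only the general
#' `NSCLCUnspecified` type and the prediction is any non-small-cell
#' subtype; stage matches on equality, or when the reference is a
#' nonexact band and the band derived from the exact prediction equals
#' it (an exact reference is never satisfied by a nonexact prediction);
#' grade and the therapy flags require exact equality.
#'
#' @param element The data element.
#' @param gold,predicted Canonical values (vectors recycle).
#' @return Logical vector; `NA` gold or prediction gives `FALSE`.
#' @examples
#' match_value("histology", "NSCLCUnspecified", "Adenocarcinoma")  # TRUE
#' match_value("stage", "EarlyStage", "Ib")                        # TRUE
#' match_value("grade", "PoorlyDifferentiated", "ModeratelyDifferentiated")
#' @export
match_value <- function(element, gold, predicted) {
  element <- match_element(element)
  n <- max(length(gold), length(predicted))
  gold <- rep_len(gold, n)
  predicted <- rep_len(predicted, n)
  out <- logical(n)
  ok <- !is.na(gold) & !is.na(predicted)
  if (element == "histology") {
    check_values("histology", gold[ok], predicted[ok])
    hier <- ok & gold == "NSCLCUnspecified" &
      !is.na(predicted)
    hier[hier] <- histology_supertype(predicted[hier]) == "non_small_cell"
    out <- (ok & gold == predicted) | hier
  } else if (element == "stage") {
    check_values("stage", gold[ok], predicted[ok])
    eq <- ok & gold == predicted
    band <- ok & gold %in% c("EarlyStage", "LateStage") &
      stage_exactness(replace(predicted, !ok, "Ia")) == "exact"
    band[band] <- derive_nonexact_stage(predicted[band]) == gold[band]
    out <- eq | band
  } else if (element == "grade") {
    check_values("grade", gold[ok], predicted[ok])
    out <- ok & gold == predicted
  } else {
    out <- ok & as.logical(gold) == as.logical(predicted)
  }
  out[is.na(out)] <- FALSE
  out
}

check_values <- function(element, ...) {
  vals <- c(...)
  bad <- setdiff(vals, lc_element_values(element))
  if (length(bad)) {
    abort(paste0("Not canonical ", element, " values: ",
                 paste(bad, collapse = ", ")),
          class = "lungnlp_domain_error")
  }
  invisible(TRUE)
}

#' Metrics from raw patient counts
#'
#' The arithmetic of the evaluation table: Precision1 = B/A,
#' Precision2 = B/C, Recall = C/A. A zero denominator yields `NA` with a
#' warning.
#'
#' @param A Patients with the element in the reference.
#' @param B Patients with a true extracted value.
#' @param C Patients with any extracted value.
#' @return A one-row tibble `A`, `B`, `C`, `precision1`, `precision2`,
#'   `recall` (unrounded).
#' @examples
#' metrics_from_counts(2127, 1330, 1883)
#' @export
metrics_from_counts <- function(A, B, C) {
  stopifnot(B <= C, B >= 0)
  if (A == 0 || C == 0) {
    warn("Zero denominator in evaluation metrics; reporting NA.")
  }
  tibble(
    A = A, B = B, C = C,
    precision1 = if (A > 0) B / A else NA_real_,
    precision2 = if (C > 0) B / C else NA_real_,
    recall = if (A > 0) C / A else NA_real_
  )
}

#' Score extractions against the reference for one element
#'
#' Counts A, B and C at patient level over the reference cohort.
#' Patients carrying the element in the reference define A; patients for
#' whom the system extracted a value but who lack the element in the
#' reference contribute to none of the counts. For the boolean therapy
#' elements, A counts reference-positive patients and an extraction
#' "exists" when the flag is true.
#'
#' @param extractions Output of [extract_patients()] (or a compatible
#'   tibble with `patient_id` and one column per element).
#' @param reference Reference-standard tibble.
#' @param element The element to score.
#' @param window_label Free-text label recorded in the result row.
#' @return A one-row `lc_eval` tibble: `element`, `window`, `A`, `B`,
#'   `C`, `precision1`, `precision2`, `recall`.
#' @export
compute_metrics <- function(extractions, reference, element,
                            window_label = NA_character_) {
  element <- match_element(element)
  reference <- validate_reference(reference)
  if (!nrow(reference)) {
    abort("Empty reference standard.", class = "lungnlp_config_error")
  }
  ref <- reference[, c("patient_id", element)]
  names(ref)[2] <- "gold"
  ext <- extractions[, c("patient_id", element)]
  names(ext)[2] <- "pred"
  joined <- left_join(ref, ext, by = "patient_id")
  if (element %in% c("chemotherapy", "radiotherapy", "surgery")) {
    joined$gold <- as.logical(joined$gold)
    joined$pred <- as.logical(joined$pred)
    joined$pred[is.na(joined$pred)] <- FALSE
    pos <- joined[!is.na(joined$gold) & joined$gold, ]
    A <- nrow(pos)
    C <- sum(pos$pred)
    B <- sum(pos$pred & pos$gold)
  } else {
    present <- joined[!is.na(joined$gold), ]
    A <- nrow(present)
    C <- sum(!is.na(present$pred))
    B <- sum(match_value(element, present$gold, present$pred))
  }
  res <- metrics_from_counts(A, B, C)
  res <- dplyr::bind_cols(tibble(element = element, window = window_label),
                          res)
  class(res) <- c("lc_eval", class(res))
  res
}

#' Score all six elements at once
#'
#' @inheritParams compute_metrics
#' @param elements Elements to score (default all six).
#' @return An `lc_eval` tibble, one row per element.
#' @export
evaluate_extractions <- function(extractions, reference,
                                 elements = lc_elements(),
                                 window_label = NA_character_) {
  rows <- purrr::map(elements, function(el) {
    compute_metrics(extractions, reference, el, window_label)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("lc_eval", class(out))
  out
}

#' Full windowed evaluation of a corpus
#'
#' Re-runs the extraction pipeline at each pathology/surgery time window
#' and scores stage, histology and grade per window; the therapy
#' elements are scored once with the long surgery-report window.
#'
#' @param documents,patients,reference Corpus and reference tables.
#' @param ruleset,normalization See [extract_mentions()].
#' @param windows Days-after-diagnosis values for the categorical
#'   elements (each paired with `days_before`).
#' @param therapy_days_after Days after diagnosis for therapy
#'   surgery-report eligibility.
#' @param days_before Days before diagnosis (shared by all windows).
#' @return An `lc_eval` tibble mirroring the evaluation-report layout:
#'   one row per element and window.
#' @export
evaluate_windows <- function(documents, patients, reference,
                             ruleset = default_ruleset(),
                             normalization = the_default_norm_table(),
                             windows = c(30, 60, 90),
                             therapy_days_after = 365,
                             days_before = 14) {
  rows <- purrr::map(windows, function(w) {
    ext <- extract_patients(documents, patients, ruleset, normalization,
                            window = time_window(days_before, w),
                            therapy_window = time_window(days_before,
                                                         therapy_days_after))
    evaluate_extractions(ext, reference,
                         elements = c("stage", "histology", "grade"),
                         window_label = paste0(w, " days"))
  })
  ext365 <- extract_patients(documents, patients, ruleset, normalization,
                             window = time_window(days_before, max(windows)),
                             therapy_window = time_window(days_before,
                                                          therapy_days_after))
  therapy <- evaluate_extractions(
    ext365, reference,
    elements = c("chemotherapy", "radiotherapy", "surgery"),
    window_label = paste0(therapy_days_after, " days"))
  out <- dplyr::bind_rows(c(rows, list(therapy)))
  class(out) <- c("lc_eval", class(out))
  out
}

#' Source coverage
#'
#' Number of cohort patients having at least one document of a source,
#' within the time window for pathology and surgery reports; clinical
#' notes are counted without a window.
#'
#' @param documents,patients Corpus tables.
#' @param source One of [lc_sources()].
#' @param window A [time_window()], or `NULL` for no restriction
#'   (mandatory meaning for clinical notes).
#' @return Integer patient count.
#' @export
compute_coverage <- function(documents, patients, source, window = NULL) {
  stopifnot(source %in% lc_sources())
  documents <- clinical_documents(documents)
  patients <- patient_records(patients)
  docs <- documents[documents$source == source, ]
  if (source == "pathology_report") {
    docs <- docs[docs$pathology_subtype %in% lc_pathology_subtypes(), ]
  }
  if (!is.null(window) && source != "clinical_note") {
    docs <- left_join(docs,
                      patients[, c("patient_id", "diagnosis_date")],
                      by = "patient_id")
    docs <- docs[is_within_window(docs$date, docs$diagnosis_date, window), ]
  }
  length(intersect(unique(docs$patient_id), patients$patient_id))
}

#' Coverage table across sources and windows
#'
#' @param documents,patients Corpus tables.
#' @param windows Days-after values for the windowed sources.
#' @param days_before Days before diagnosis.
#' @return A tibble `source`, `window`, `coverage`.
#' @export
coverage_table <- function(documents, patients,
                           windows = c(30, 60, 90, 365),
                           days_before = 14) {
  rows <- list(tibble(source = "clinical_note", window = "all",
                      coverage = compute_coverage(documents, patients,
                                                  "clinical_note")))
  for (src in c("pathology_report", "surgery_report")) {
    for (w in windows) {
      rows[[length(rows) + 1L]] <- tibble(
        source = src, window = paste0(w, " days"),
        coverage = compute_coverage(documents, patients, src,
                                    time_window(days_before, w)))
    }
  }
  dplyr::bind_rows(rows)
}

#' Round an evaluation table for reporting
#'
#' @param evaluation An `lc_eval` tibble.
#' @param digits Decimal places (reports use 3).
#' @return The tibble with rounded metric columns.
#' @export
round_metrics <- function(evaluation, digits = 3) {
  mutate(evaluation, across(c("precision1", "precision2", "recall"),
                            ~round(.x, digits)))
}

#' @export
#' @importFrom ggplot2 autoplot
#' @method autoplot lc_eval
autoplot.lc_eval <- function(object, ...) {
  long <- tidyr::pivot_longer(object,
                              c("precision1", "precision2", "recall"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$element, y = .data$value,
                               fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~window) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Patient-level extraction performance") +
    ggplot2::theme_minimal()
}
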