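# Shared fixture builders: tiny corpora constructed in code.

make_sentence <- function(text, source = "clinical_note", doc_id = "d1",
                          sentence_id = 1L) {
  tibble::tibble(doc_id = doc_id, sentence_id = sentence_id,
                 start = 0L, end = nchar(text), source = source,
                 text = text)
}

make_doc <- function(text, source = "clinical_note", doc_id = "d1",
                     patient_id = "p1", date = as.Date("2005-06-01"),
                     pathology_subtype = NA_character_) {
  if (source == "pathology_report" && is.na(pathology_subtype)) {
    pathology_subtype <- "general_pathology"
  }
  tibble::tibble(doc_id = doc_id, patient_id = patient_id, source = source,
                 pathology_subtype = pathology_subtype, date = date,
                 text = text)
}

make_patient <- function(patient_id = "p1",
                         diagnosis_date = as.Date("2005-06-01")) {
  tibble::tibble(patient_id = patient_id, diagnosis_date = diagnosis_date)
}

# Enumerate all multisets of sizes 0..max_size over a value set.
all_multisets <- function(values, max_size) {
  out <- list(character(0))
  for (k in seq_len(max_size)) {
    combos <- utils::combn(length(values) + k - 1, k, simplify = FALSE)
    for (cb in combos) {
      out[[length(out) + 1L]] <- values[cb - seq_len(k) + 1L]
    }
  }
  out
}
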