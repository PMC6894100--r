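# Synthetic EHR cohort generator.
#
# Emulates a multi-document, multi-source lung-cancer corpus with known
# gold labels: each patient draws gold values for the six elements from
# configurable distributions, then receives templated clinical notes,
# pathology reports and (when operated on) surgery reports whose
# sentences plant surface forms of those values. Cross-document
# discordance, non-lung distractor sentences and per-element corpus
# omission are injectable at configurable rates. A per-sentence ledger
# records exactly what was planted where, so extraction can be checked
# against ground truth.

#' Default gold-label distributions
#'
#' The default histology distribution follows the training-split class
#' counts of a 2006-patient abstracted lung-cancer cohort
#' (adenocarcinoma 897, squamous 358, small cell 339, NSCLC-unspecified
#' 342, ...); therapy prevalences follow the same cohort's abstracted
#' therapy counts over 2311 patients (chemotherapy 1674, radiotherapy
#' 769, surgery 312). Stage and grade default to uniform over their
#' canonical sets (no published distribution).
#'
#' @return A named probability vector / list.
#' @export
default_histology_distribution <- function() {
  counts <- c(Adenocarcinoma = 897, Adenosquamous = 16, Carcinoid = 1,
              CarcinoidTypicalAtypical = 15, LargeNeuroendocrine = 23,
              NSCLCUnspecified = 342, OtherUnknown = 1, OtherNSCLC = 14,
              SmallCell = 339, Squamous = 358)
  counts[lc_histology_values()] / sum(counts)
}

#' @rdname default_histology_distribution
#' @export
default_therapy_prevalences <- function() {
  c(chemotherapy = 1674 / 2311, radiotherapy = 769 / 2311,
    surgery = 312 / 2311)
}

#' Synthetic-cohort configuration
#'
#' @param n_patients Number of patients to generate.
#' @param histology_distribution Named probabilities over the ten
#'   canonical histologies.
#' @param stage_distribution Named probabilities over NSCLC stages (exact
#'   stages and/or bands); SCLC patients draw from
#'   `sclc_stage_distribution` instead.
#' @param sclc_stage_distribution Probabilities over Limited/Extensive.
#' @param grade_distribution Probabilities over the four grades.
#' @param therapy_prevalences Named probabilities for chemotherapy,
#'   radiotherapy, surgery.
#' @param docs_per_patient List with `notes_lambda` (clinical notes per
#'   patient are `1 + Poisson(notes_lambda)`) and `extra_pathology_prob`
#'   (chance of a second pathology report).
#' @param offset_ranges List of `c(min, max)` day offsets from diagnosis
#'   per source.
#' @param discordance_rate Probability that a planted categorical value in
#'   a document is replaced by a non-gold value of the same element (and,
#'   for stage, the same disease class).
#' @param distractor_rate Probability that a clinical note carries a
#'   family-history sentence mentioning a non-lung primary.
#' @param missing_element_rates Named per-element probabilities that the
#'   corpus omits the element entirely for a patient (the reference
#'   standard keeps the gold value, so extraction recall drops).
#' @param surface_variants Sample among surface realizations (`TRUE`) or
#'   always use the canonical first surface (`FALSE`).
#' @param seed Integer seed; the corpus is a deterministic function of
#'   the configuration.
#' @return A validated `lc_synth_config` list.
#' @export
synthetic_config <- function(n_patients = 100,
                             histology_distribution = default_histology_distribution(),
                             stage_distribution = NULL,
                             sclc_stage_distribution = c(Limited = 0.5, Extensive = 0.5),
                             grade_distribution = NULL,
                             therapy_prevalences = default_therapy_prevalences(),
                             docs_per_patient = list(notes_lambda = 2,
                                                     extra_pathology_prob = 0.4),
                             offset_ranges = list(clinical_note = c(-30, 200),
                                                  pathology_report = c(-14, 30),
                                                  surgery_report = c(0, 60)),
                             discordance_rate = 0,
                             distractor_rate = 0,
                             missing_element_rates = NULL,
                             surface_variants = TRUE,
                             seed = 1L) {
  if (is.null(stage_distribution)) {
    stage_distribution <- setNames(rep(1 / 7, 7), lc_exact_stages())
  }
  if (is.null(grade_distribution)) {
    grade_distribution <- setNames(rep(0.25, 4), lc_grade_values())
  }
  if (is.null(missing_element_rates)) {
    missing_element_rates <- setNames(rep(0, 6), lc_elements())
  }
  cfg <- list(
    n_patients = as.integer(n_patients),
    histology_distribution = histology_distribution,
    stage_distribution = stage_distribution,
    sclc_stage_distribution = sclc_stage_distribution,
    grade_distribution = grade_distribution,
    therapy_prevalences = therapy_prevalences,
    docs_per_patient = docs_per_patient,
    offset_ranges = offset_ranges,
    discordance_rate = discordance_rate,
    distractor_rate = distractor_rate,
    missing_element_rates = missing_element_rates,
    surface_variants = isTRUE(surface_variants),
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "lc_synth_config")
}

validate_synth_config <- function(cfg) {
  if (is.na(cfg$n_patients) || cfg$n_patients < 1L) {
    abort("n_patients must be at least 1.", class = "lungnlp_config_error")
  }
  check_probvec <- function(p, legal, what) {
    if (is.null(names(p)) || !all(names(p) %in% legal)) {
      abort(paste0(what, " must be named by canonical values."),
            class = "lungnlp_config_error")
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      abort(paste0(what, " must be non-negative and sum to 1."),
            class = "lungnlp_config_error")
    }
  }
  check_probvec(cfg$histology_distribution, lc_histology_values(),
                "histology_distribution")
  check_probvec(cfg$stage_distribution,
                c(lc_exact_stages(), "EarlyStage", "LateStage"),
                "stage_distribution")
  check_probvec(cfg$sclc_stage_distribution, c("Limited", "Extensive"),
                "sclc_stage_distribution")
  check_probvec(cfg$grade_distribution, lc_grade_values(),
                "grade_distribution")
  rates <- c(cfg$therapy_prevalences, cfg$discordance_rate,
             cfg$distractor_rate, cfg$missing_element_rates)
  if (any(rates < 0 | rates > 1)) {
    abort("All rates and prevalences must lie in [0, 1].",
          class = "lungnlp_config_error")
  }
  invisible(cfg)
}

#' Load the synthetic-note template library
#'
#' @param path YAML template file, or `NULL` for the shipped library.
#' @return A list with `surfaces` and per-source `templates`.
#' @export
load_templates <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "templates.yaml", package = "lungnlp")
  }
  yaml::read_yaml(path)
}

pick <- function(x, variants = TRUE) {
  if (!length(x)) {
    abort("Template or surface list is empty.",
          class = "lungnlp_config_error")
  }
  if (variants && length(x) > 1L) x[[sample.int(length(x), 1L)]] else x[[1L]]
}

surface_for <- function(templates, element, value, variants = TRUE) {
  s <- templates$surfaces[[element]][[value]]
  if (is.null(s)) {
    abort(paste0("No surface realization for ", element, " value '",
                 value, "'."), class = "lungnlp_config_error")
  }
  pick(s, variants)
}

# Sample a non-gold replacement value of the same element (and disease
# class, for stage) -- the discordant mention planted in a document.
discordant_value <- function(element, gold, cfg) {
  pool <- switch(element,
    stage = {
      if (stage_disease_class(gold) == "SCLC") c("Limited", "Extensive")
      else c(lc_exact_stages(), "EarlyStage", "LateStage")
    },
    histology = lc_histology_values(),
    grade = lc_grade_values())
  pool <- setdiff(pool, gold)
  pool[sample.int(length(pool), 1L)]
}

#' Render one synthetic document
#'
#' Assembles a document of templated single-sentence lines: an opening
#' sentence, one sentence per planted element, optional filler and (for
#' clinical notes) an optional family-history distractor. Returns the
#' text together with the generator's own sentence boundaries and a
#' per-sentence ledger of planted values.
#'
#' @param gold Named list of the patient's gold values (canonical names;
#'   therapies logical).
#' @param source Document source.
#' @param templates Template library ([load_templates()]).
#' @param elements Elements to plant (default: all elements applicable to
#'   the source and present in `gold`).
#' @param discordance_rate,distractor_rate,surface_variants See
#'   [synthetic_config()].
#' @return A list with `text`, `sentences` (start/end offsets, 0-based
#'   half-open) and `ledger` (sentence_id, element, value, is_gold).
#' @export
render_document <- function(gold, source, templates = load_templates(),
                            elements = NULL,
                            discordance_rate = 0, distractor_rate = 0,
                            surface_variants = TRUE) {
  tpl <- templates$templates[[source]]
  if (is.null(tpl)) {
    abort(paste0("No templates for source '", source, "'."),
          class = "lungnlp_config_error")
  }
  if (is.null(elements)) {
    elements <- intersect(names(tpl), names(gold))
  }
  sentences <- character(0)
  ledger <- list()
  add <- function(sent, element = NA_character_, value = NA_character_,
                  is_gold = NA) {
    sentences[[length(sentences) + 1L]] <<- sent
    ledger[[length(ledger) + 1L]] <<- tibble(
      sentence_id = length(sentences), element = element,
      value = value, is_gold = is_gold)
  }
  add(pick(tpl$opening, surface_variants))
  for (el in elements) {
    if (is.null(tpl[[el]])) {
      abort(paste0("Source '", source, "' has no template for element '",
                   el, "'."), class = "lungnlp_config_error")
    }
    gv <- gold[[el]]
    if (is.null(gv) || is.na(gv)) next
    if (el %in% c("chemotherapy", "radiotherapy", "surgery")) {
      if (!isTRUE(as.logical(gv))) next
      sent <- pick(tpl[[el]], surface_variants)
      if (grepl("{surgery_type}", sent, fixed = TRUE)) {
        sent <- stringr::str_replace_all(
          sent, stringr::fixed("{surgery_type}"),
          pick(templates$surfaces$surgery_type, surface_variants))
      }
      add(sent, el, el, TRUE)
    } else {
      value <- gv
      is_gold <- TRUE
      if (discordance_rate > 0 && runif(1) < discordance_rate) {
        value <- discordant_value(el, gv, NULL)
        is_gold <- FALSE
      }
      surf <- surface_for(templates, el, value, surface_variants)
      sent <- stringr::str_replace_all(
        pick(tpl[[el]], surface_variants),
        stringr::fixed(paste0("{", el, "}")), surf)
      add(sent, el, value, is_gold)
    }
  }
  if (source == "clinical_note" && distractor_rate > 0 &&
      runif(1) < distractor_rate) {
    add(pick(tpl$distractor, surface_variants), "histology",
        "distractor", FALSE)
  }
  if (!is.null(tpl$filler) && runif(1) < 0.6) {
    add(pick(tpl$filler, surface_variants))
  }
  text <- paste(sentences, collapse = " ")
  lens <- nchar(sentences)
  starts <- cumsum(c(0L, head(lens + 1L, -1L)))
  list(
    text = text,
    sentences = tibble(sentence_id = seq_along(sentences),
                       start = starts, end = starts + lens,
                       text = sentences),
    ledger = dplyr::bind_rows(ledger)
  )
}

#' Draw gold labels only
#'
#' Samples per-patient gold values from the configured distributions
#' without rendering any documents; [generate_cohort()] uses the same
#' sampler, so empirical distribution checks can run at large n cheaply.
#'
#' @param config An [synthetic_config()].
#' @return A tibble of gold values, one row per patient.
#' @export
draw_gold_labels <- function(config) {
  validate_synth_config(config)
  withr::with_seed(config$seed, draw_gold_labels_impl(config))
}

draw_gold_labels_impl <- function(cfg) {
  n <- cfg$n_patients
  hist_p <- cfg$histology_distribution
  histology <- sample(names(hist_p), n, replace = TRUE, prob = hist_p)
  stage <- character(n)
  sclc <- histology == "SmallCell"
  if (any(sclc)) {
    stage[sclc] <- sample(names(cfg$sclc_stage_distribution), sum(sclc),
                          replace = TRUE,
                          prob = cfg$sclc_stage_distribution)
  }
  if (any(!sclc)) {
    stage[!sclc] <- sample(names(cfg$stage_distribution), sum(!sclc),
                           replace = TRUE, prob = cfg$stage_distribution)
  }
  grade <- sample(names(cfg$grade_distribution), n, replace = TRUE,
                  prob = cfg$grade_distribution)
  tp <- cfg$therapy_prevalences
  tibble(
    patient_id = sprintf("P%05d", seq_len(n)),
    histology = histology, stage = stage, grade = grade,
    chemotherapy = runif(n) < tp[["chemotherapy"]],
    radiotherapy = runif(n) < tp[["radiotherapy"]],
    surgery = runif(n) < tp[["surgery"]]
  )
}

#' Generate a synthetic cohort
#'
#' Draws gold labels, then renders a document set per patient: one or
#' more clinical notes (the first note guarantees a sentence for each
#' gold-positive therapy), at least one pathology report carrying
#' histology, grade and stage, and a surgery report when the patient was
#' operated on. Per-element corpus omission, cross-document discordance
#' and distractor sentences follow the configured rates. The result is
#' deterministic given the configuration (including its seed).
#'
#' @param config An [synthetic_config()].
#' @param templates Template library.
#' @return An `lc_cohort` list: `patients`, `documents`, `reference`
#'   (gold labels in the evaluator's schema), `sentences` (the
#'   generator's own sentence boundaries) and `ledger` (per-sentence
#'   planted values).
#' @export
generate_cohort <- function(config, templates = load_templates()) {
  validate_synth_config(config)
  withr::with_seed(config$seed, generate_cohort_impl(config, templates))
}

generate_cohort_impl <- function(cfg, templates) {
  gold_tbl <- draw_gold_labels_impl(cfg)
  n <- cfg$n_patients
  diagnosis <- as.Date("2000-01-01") +
    sample.int(4748, n, replace = TRUE)   # diagnoses spread over 2000-2012
  patients <- tibble(patient_id = gold_tbl$patient_id,
                     diagnosis_date = diagnosis)

  omit <- sapply(lc_elements(), function(el) {
    runif(n) < cfg$missing_element_rates[[el]]
  })
  if (is.null(dim(omit))) omit <- matrix(omit, nrow = n)
  colnames(omit) <- lc_elements()

  docs <- list(); sents <- list(); ledg <- list()
  doc_counter <- 0L
  new_doc_id <- function() {
    doc_counter <<- doc_counter + 1L
    sprintf("D%06d", doc_counter)
  }
  offset_in <- function(source) {
    r <- cfg$offset_ranges[[source]]
    as.integer(round(runif(1, r[1], r[2])))
  }
  emit <- function(pid, source, subtype, date, gold, elements) {
    rd <- render_document(gold, source, templates, elements = elements,
                          discordance_rate = cfg$discordance_rate,
                          distractor_rate = cfg$distractor_rate,
                          surface_variants = cfg$surface_variants)
    id <- new_doc_id()
    docs[[length(docs) + 1L]] <<- tibble(
      doc_id = id, patient_id = pid, source = source,
      pathology_subtype = subtype, date = date, text = rd$text)
    s <- rd$sentences; s$doc_id <- id
    sents[[length(sents) + 1L]] <<- s[, c("doc_id", "sentence_id",
                                          "start", "end", "text")]
    l <- rd$ledger; l$doc_id <- id; l$patient_id <- pid
    ledg[[length(ledg) + 1L]] <<- l
  }

  for (i in seq_len(n)) {
    pid <- gold_tbl$patient_id[i]
    gold <- as.list(gold_tbl[i, setdiff(names(gold_tbl), "patient_id")])
    plantable <- function(el) !omit[i, el]
    cat_els <- Filter(plantable, c("stage", "histology", "grade"))
    ther_els <- Filter(function(el) plantable(el) && isTRUE(gold[[el]]),
                       c("chemotherapy", "radiotherapy", "surgery"))

    n_notes <- 1L + rpois(1, cfg$docs_per_patient$notes_lambda)
    for (k in seq_len(n_notes)) {
      els <- character(0)
      if (k == 1L) {
        els <- ther_els   # first note guarantees each gold therapy
      } else {
        for (el in ther_els) if (runif(1) < 0.4) els <- c(els, el)
      }
      for (el in cat_els) {
        p <- c(stage = 0.5, histology = 0.5, grade = 0.3)[[el]]
        if (runif(1) < p) els <- c(els, el)
      }
      emit(pid, "clinical_note", NA_character_,
           diagnosis[i] + offset_in("clinical_note"), gold, els)
    }

    n_path <- 1L + rbinom(1, 1, cfg$docs_per_patient$extra_pathology_prob)
    for (k in seq_len(n_path)) {
      subtype <- sample(lc_pathology_subtypes(), 1L)
      emit(pid, "pathology_report", subtype,
           diagnosis[i] + offset_in("pathology_report"), gold, cat_els)
    }

    if (isTRUE(gold$surgery) && plantable("surgery")) {
      els <- "surgery"
      for (el in intersect(cat_els, c("stage", "histology"))) {
        p <- c(stage = 0.3, histology = 0.5)[[el]]
        if (runif(1) < p) els <- c(els, el)
      }
      emit(pid, "surgery_report", NA_character_,
           diagnosis[i] + offset_in("surgery_report"), gold, els)
    }
  }

  reference <- gold_tbl[, c("patient_id", "stage", "histology", "grade",
                            "chemotherapy", "radiotherapy", "surgery")]
  structure(list(
    patients = patients,
    documents = clinical_documents(dplyr::bind_rows(docs)),
    reference = reference,
    sentences = dplyr::bind_rows(sents),
    ledger = dplyr::bind_rows(ledg),
    config = cfg
  ), class = "lc_cohort")
}

#' @export
print.lc_cohort <- function(x, ...) {
  cat(sprintf("<lc_cohort: %d patients, %d documents, seed %d>\n",
              nrow(x$patients), nrow(x$documents), x$config$seed))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Emits the corpus layout ([write_corpus()]) plus `reference.csv` in the
#' evaluator's schema.
#'
#' @param cohort An `lc_cohort`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  write_corpus(cohort$documents, cohort$patients, dir)
  write_reference(cohort$reference, file.path(dir, "reference.csv"))
  invisible(dir)
}
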