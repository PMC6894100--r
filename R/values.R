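# Canonical value sets for the six data elements.
#
# Histology follows the ten normalized types (small cell, the NSCLC
# subtypes, NSCLC-unspecified and an other/unknown bucket); stage covers
# the seven exact NSCLC stages, the two nonexact bands and the two SCLC
# stages; grade is the four differentiation levels.

#' Canonical value sets
#'
#' Vectors of the canonical (normalized) values used throughout the
#' package, plus the names of the six data elements and three document
#' sources.
#'
#' @return A character vector of canonical names.
#' @examples
#' lc_elements()
#' lc_stage_values()
#' @name lc_values
NULL

#' @rdname lc_values
#' @export
lc_elements <- function() {
  c("stage", "histology", "grade", "chemotherapy", "radiotherapy", "surgery")
}

#' @rdname lc_values
#' @export
lc_sources <- function() {
  c("clinical_note", "pathology_report", "surgery_report")
}

#' @rdname lc_values
#' @export
lc_pathology_subtypes <- function() {
  c("cytology", "general_pathology", "consultation")
}

#' @rdname lc_values
#' @export
lc_histology_values <- function() {
  c("SmallCell", "Adenocarcinoma", "Squamous", "LargeNeuroendocrine",
    "Adenosquamous", "CarcinoidTypicalAtypical", "Carcinoid",
    "NSCLCUnspecified", "OtherNSCLC", "OtherUnknown")
}

#' @rdname lc_values
#' @export
lc_stage_values <- function() {
  c("Ia", "Ib", "IIa", "IIb", "IIIa", "IIIb", "IV",
    "EarlyStage", "LateStage", "Extensive", "Limited")
}

#' @rdname lc_values
#' @export
lc_exact_stages <- function() {
  c("Ia", "Ib", "IIa", "IIb", "IIIa", "IIIb", "IV")
}

#' @rdname lc_values
#' @export
lc_grade_values <- function() {
  c("WellDifferentiated", "ModeratelyDifferentiated",
    "PoorlyDifferentiated", "Undifferentiated")
}

#' Canonical values for one element
#'
#' @param element One of `lc_elements()`.
#' @return Character vector of legal canonical values ("TRUE"/"FALSE" for
#'   the boolean therapy elements).
#' @export
lc_element_values <- function(element) {
  element <- match_element(element)
  switch(element,
    stage = lc_stage_values(),
    histology = lc_histology_values(),
    grade = lc_grade_values(),
    c("TRUE", "FALSE")
  )
}

match_element <- function(element) {
  if (length(element) != 1L || !element %in% lc_elements()) {
    abort(paste0("`element` must be one of: ",
                 paste(lc_elements(), collapse = ", ")),
          class = "lungnlp_config_error")
  }
  element
}

#' Histology supertype
#'
#' Maps each canonical histology value onto its general class:
#' `small_cell`, `non_small_cell`, or `other`.
#'
#' @param value Character vector of canonical histology values.
#' @return Character vector of supertypes.
#' @examples
#' histology_supertype(c("Adenocarcinoma", "SmallCell", "OtherUnknown"))
#' @export
histology_supertype <- function(value) {
  stopifnot(all(value %in% lc_histology_values()))
  dplyr::case_when(
    value == "SmallCell" ~ "small_cell",
    value == "OtherUnknown" ~ "other",
    TRUE ~ "non_small_cell"
  )
}

#' Stage exactness and disease class
#'
#' `stage_exactness()` labels a canonical stage as `exact` (Ia--IV) or
#' `nonexact` (bands and SCLC stages); `stage_disease_class()` labels it
#' as `SCLC` (Limited/Extensive) or `NSCLC`.
#'
#' @param value Character vector of canonical stage values.
#' @return Character vector.
#' @examples
#' stage_exactness(c("Ia", "EarlyStage", "Limited"))
#' stage_disease_class(c("IV", "Extensive"))
#' @export
stage_exactness <- function(value) {
  stopifnot(all(value %in% lc_stage_values()))
  ifelse(value %in% lc_exact_stages(), "exact", "nonexact")
}

#' @rdname stage_exactness
#' @export
stage_disease_class <- function(value) {
  stopifnot(all(value %in% lc_stage_values()))
  ifelse(value %in% c("Limited", "Extensive"), "SCLC", "NSCLC")
}

# Severity ranks: higher = more severe. Ranks are only compared within a
# comparable group (exact NSCLC stages; nonexact bands; SCLC stages), so
# the numeric scales may repeat across groups.
severity_ranks <- function(element) {
  switch(element,
    stage = c(
      Ia = 1, Ib = 2, IIa = 3, IIb = 4, IIIa = 5, IIIb = 6, IV = 7,
      EarlyStage = 1, LateStage = 2,
      Limited = 1, Extensive = 2
    ),
    grade = c(
      WellDifferentiated = 1, ModeratelyDifferentiated = 2,
      PoorlyDifferentiated = 3, Undifferentiated = 4
    ),
    histology = c(
      OtherUnknown = 1, Carcinoid = 2, CarcinoidTypicalAtypical = 3,
      Adenocarcinoma = 4, Adenosquamous = 5, LargeNeuroendocrine = 6,
      OtherNSCLC = 7, Squamous = 8, NSCLCUnspecified = 9, SmallCell = 10
    ),
    abort(paste0("No severity order for element '", element, "'."))
  )
}

#' Severity rank of canonical values
#'
#' The tie-breaking order used by the discordance resolver: a more severe
#' concept wins a frequency tie. For stage the rank is comparable within
#' a disease class (Ia < ... < IV; EarlyStage < LateStage;
#' Limited < Extensive); grades run well to undifferentiated; histology
#' uses other/unknown < carcinoid group < NSCLC subtypes <
#' NSCLC-unspecified < small cell.
#'
#' @param value Character vector of canonical values.
#' @param element The data element the values belong to.
#' @return Numeric rank vector (higher is more severe).
#' @examples
#' severity_rank(c("Ia", "IIIa"), "stage")
#' @export
severity_rank <- function(value, element) {
  element <- match_element(element)
  ranks <- severity_ranks(element)
  bad <- setdiff(value, names(ranks))
  if (length(bad)) {
    abort(paste0("Not canonical ", element, " values: ",
                 paste(bad, collapse = ", ")),
          class = "lungnlp_domain_error")
  }
  unname(ranks[value])
}
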