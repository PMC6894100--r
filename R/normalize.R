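# Normalization: raw matched strings -> canonical value sets.
#
# The site-specific mapping table is external configuration (a CSV of
# element, surface_form, canonical); the shipped default covers the
# canonical names plus common surface variants produced by the default
# ruleset. Lookups are keyed on a case-folded, hyphen/slash-collapsed,
# whitespace-squished form of the raw string, so "Non-Small Cell",
# "non small  cell" and "NON-SMALL CELL" all hit one row.

canon_key <- function(x) {
  stringr::str_squish(gsub("[-/]+", " ", tolower(x)))
}

#' Load a normalization table
#'
#' Reads a surface-form-to-canonical mapping from CSV (columns `element`,
#' `surface_form`, `canonical`). With no path, the table shipped with the
#' package is returned.
#'
#' @param path Path to a CSV mapping file, or `NULL` for the default.
#' @return A tibble with columns `element`, `surface_form` (lookup key)
#'   and `canonical`.
#' @export
load_normalization_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "normalization.csv", package = "lungnlp")
  }
  if (!file.exists(path)) {
    abort(paste0("Normalization table not found: ", path),
          class = "lungnlp_config_error")
  }
  tab <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("element", "surface_form", "canonical")
  if (!all(required %in% names(tab))) {
    abort("Normalization table needs columns element, surface_form, canonical.",
          class = "lungnlp_config_error")
  }
  tab$surface_form <- canon_key(tab$surface_form)
  bad <- !mapply(function(el, cn) cn %in% lc_element_values(el) ||
                   (el %in% c("chemotherapy", "radiotherapy", "surgery") &&
                      cn == el),
                 tab$element, tab$canonical)
  if (any(bad)) {
    abort(paste0("Non-canonical target values in normalization table: ",
                 paste(unique(tab$canonical[bad]), collapse = ", ")),
          class = "lungnlp_config_error")
  }
  as_tibble(tab)
}

the_default_norm_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_normalization_table()
    cache
  }
})

#' Normalize raw mention strings to canonical values
#'
#' Maps a raw matched string (or its captured value) onto the canonical
#' value set of its element. Unmapped histology strings degrade to
#' `"OtherUnknown"` (the explicit other/unknown bucket); unmapped stage or
#' grade strings raise a normalization error, since they signal a mismatch
#' between the ruleset and the mapping table. Therapy elements normalize
#' to the element name itself.
#'
#' @param raw Character vector of raw strings.
#' @param element The data element the strings were matched for.
#' @param table A normalization table (see [load_normalization_table()]).
#' @return Character vector of canonical values.
#' @examples
#' normalize_value(c("IA", "early stage"), "stage")
#' normalize_histology("adenosquamous carcinoma")
#' normalize_grade("grade 3")
#' @export
normalize_value <- function(raw, element,
                            table = the_default_norm_table()) {
  element <- match_element(element)
  sub <- table[table$element == element, ]
  key <- canon_key(raw)
  if (element == "stage") key <- sub("^stage ", "", key)
  idx <- match(key, sub$surface_form)
  out <- sub$canonical[idx]
  if (anyNA(out)) {
    if (element == "histology") {
      out[is.na(out)] <- "OtherUnknown"
    } else {
      abort(paste0("Cannot normalize ", element, " value(s): ",
                   paste(unique(raw[is.na(out)]), collapse = ", "),
                   " (rule/mapping-table mismatch)."),
            class = "lungnlp_normalization_error")
    }
  }
  out
}

#' @rdname normalize_value
#' @export
normalize_histology <- function(raw, table = the_default_norm_table()) {
  normalize_value(raw, "histology", table)
}

#' @rdname normalize_value
#' @export
normalize_stage <- function(raw, table = the_default_norm_table()) {
  normalize_value(raw, "stage", table)
}

#' @rdname normalize_value
#' @export
normalize_grade <- function(raw, table = the_default_norm_table()) {
  normalize_value(raw, "grade", table)
}

#' Derive the nonexact stage band of an exact stage
#'
#' Exact NSCLC stages map to the band used when a reference standard
#' records only a nonexact stage: Ia/Ib/IIa/IIb become `EarlyStage`,
#' IIIa/IIIb/IV become `LateStage`. Nonexact or SCLC input is a domain
#' error.
#'
#' @param exact Character vector of exact canonical stages.
#' @return Character vector of `"EarlyStage"`/`"LateStage"`.
#' @examples
#' derive_nonexact_stage(c("Ia", "IV"))
#' @export
derive_nonexact_stage <- function(exact) {
  stopifnot(all(exact %in% lc_stage_values()))
  if (any(stage_exactness(exact) != "exact")) {
    abort("derive_nonexact_stage() requires exact NSCLC stages.",
          class = "lungnlp_domain_error")
  }
  ifelse(exact %in% c("Ia", "Ib", "IIa", "IIb"), "EarlyStage", "LateStage")
}
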