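# Independent brute-force resolver used as the oracle: counts candidates,
# applies the quoted tie rules (exact stage over nonexact stage, then the
# more severe concept) with severity orders written out literally here.
oracle_severity <- list(
  stage = c(Ia = 1, Ib = 2, IIa = 3, IIb = 4, IIIa = 5, IIIb = 6, IV = 7,
            EarlyStage = 1, LateStage = 2),
  grade = c(WellDifferentiated = 1, ModeratelyDifferentiated = 2,
            PoorlyDifferentiated = 3, Undifferentiated = 4),
  histology = c(OtherUnknown = 1, Carcinoid = 2,
                CarcinoidTypicalAtypical = 3, Adenocarcinoma = 4,
                Adenosquamous = 5, LargeNeuroendocrine = 6, OtherNSCLC = 7,
                Squamous = 8, NSCLCUnspecified = 9, SmallCell = 10)
)

oracle_resolve <- function(values, element) {
  if (!length(values)) return(NA_character_)
  counts <- sapply(unique(values), function(v) sum(values == v))
  top <- names(counts)[counts == max(counts)]
  if (element == "stage") {
    exact <- top[top %in% c("Ia", "Ib", "IIa", "IIb", "IIIa", "IIIb", "IV")]
    if (length(exact)) top <- exact
  }
  sev <- oracle_severity[[element]][top]
  names(sev)[which.max(sev)]
}

test_that("within-source resolution matches the quoted rules on examples", {
  expect_equal(resolve_within_source(c("Ia", "Ia", "Ia", "Ib"), "stage"),
               "Ia")                                     # strict majority
  expect_equal(resolve_within_source(c("Ia", "EarlyStage"), "stage"),
               "Ia")                                     # exact over nonexact
  expect_equal(resolve_within_source(c("Ia", "Ia", "IIIa", "IIIa"), "stage"),
               "IIIa")                                   # severity on a tie
  expect_equal(resolve_within_source(character(0), "stage"),
               NA_character_)
  expect_error(resolve_within_source(c("Ia", "Adenocarcinoma"), "stage"),
               class = "lungnlp_domain_error")
})

test_that("within-source resolution equals the brute-force oracle exhaustively", {
  candidate_sets <- list(
    stage = c("Ia", "IIb", "IIIa", "EarlyStage", "LateStage"),
    histology = c("Adenocarcinoma", "Squamous", "SmallCell",
                  "NSCLCUnspecified", "OtherUnknown"),
    grade = lc_grade_values()
  )
  for (el in names(candidate_sets)) {
    multisets <- all_multisets(candidate_sets[[el]], 4)
    for (ms in multisets) {
      expect_equal(resolve_within_source(ms, el), oracle_resolve(ms, el),
                   label = paste(el, paste(ms, collapse = "+")))
    }
  }
})

test_that("a mixed SCLC/NSCLC stage tie falls back to the larger class", {
  # SCLC carries more mentions overall -> SCLC candidate wins the tie
  expect_equal(resolve_within_source(
    c("Limited", "Limited", "Extensive", "IIIa", "IIIa"), "stage"),
    "Limited")
  # class counts tied -> NSCLC preferred
  expect_equal(resolve_within_source(c("Limited", "IIIa"), "stage"), "IIIa")
  # frequency still decides before class
  expect_equal(resolve_within_source(
    c("Extensive", "Extensive", "IIIa"), "stage"), "Extensive")
})

test_that("adding a copy of the winner never changes the result", {
  set.seed(77)
  for (el in c("stage", "histology", "grade")) {
    vals <- setdiff(lc_element_values(el), c("Limited", "Extensive"))
    for (i in 1:40) {
      ms <- sample(vals, sample(1:4, 1), replace = TRUE)
      winner <- resolve_within_source(ms, el)
      expect_equal(resolve_within_source(c(ms, winner), el), winner)
    }
  }
})

test_that("cross-source combination follows pathology > notes > surgery", {
  expect_equal(combine_across_sources(
    c(pathology_report = "Adenocarcinoma",
      clinical_note = "NSCLCUnspecified")), "Adenocarcinoma")
  expect_equal(combine_across_sources(
    c(clinical_note = "Squamous", surgery_report = "Adenocarcinoma")),
    "Squamous")
  expect_equal(combine_across_sources(c(surgery_report = "Ib")), "Ib")
  expect_equal(combine_across_sources(
    c(clinical_note = "Ia", pathology_report = NA,
      surgery_report = "Ia")), "Ia")
  expect_equal(combine_across_sources(
    c(clinical_note = NA_character_)), NA_character_)
  expect_error(combine_across_sources(c(fax = "Ia")),
               class = "lungnlp_domain_error")
})

test_that("combination is idempotent and order-independent", {
  entries <- c(pathology_report = "Squamous", clinical_note = "SmallCell",
               surgery_report = "Adenocarcinoma")
  base <- combine_across_sources(entries)
  for (perm in list(c(1, 2, 3), c(3, 2, 1), c(2, 3, 1), c(2, 1, 3))) {
    expect_equal(combine_across_sources(entries[perm]), base)
  }
  expect_equal(combine_across_sources(
    c(pathology_report = base)), base)
})

test_that("therapy flags require at least one eligible mention", {
  m <- extract_document(make_doc("The patient has begun chemotherapy."))
  flags <- resolve_therapies(m)
  expect_true(flags$chemotherapy)
  expect_false(flags$radiotherapy)
  expect_false(flags$surgery)
  none <- resolve_therapies(extract_document(make_doc("Stable today.")))
  expect_false(any(unlist(none)))
})

test_that("the full pipeline resolves discordance toward the majority", {
  dx <- as.Date("2005-06-01")
  docs <- dplyr::bind_rows(
    make_doc("Biopsy results were consistent with stage Ia disease.",
             "clinical_note", "n1", date = dx),
    make_doc("Pathology review confirmed stage Ia.",
             "clinical_note", "n2", date = dx + 5),
    make_doc("Recent biopsy findings indicate stage IIb disease.",
             "clinical_note", "n3", date = dx + 10))
  ext <- extract_patients(docs, make_patient())
  expect_equal(ext$stage, "Ia")

  # pathology overrides a disagreeing clinical-note result
  docs2 <- dplyr::bind_rows(
    docs,
    make_doc("Pathologic staging is consistent with stage IIIb.",
             "pathology_report", "p1", date = dx + 7))
  ext2 <- extract_patients(docs2, make_patient())
  expect_equal(ext2$stage, "IIIb")
  expect_equal(ext2$stage_clinical_note, "Ia")
  expect_equal(ext2$stage_pathology_report, "IIIb")
})
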