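test_that("configuration validation rejects malformed settings", {
  expect_error(synthetic_config(n_patients = 0),
               class = "lungnlp_config_error")
  bad_hist <- setNames(rep(0.2, 5), lc_histology_values()[1:5])
  expect_error(synthetic_config(histology_distribution = bad_hist * 2),
               class = "lungnlp_config_error")
  expect_error(synthetic_config(discordance_rate = 1.5),
               class = "lungnlp_config_error")
})

test_that("generation is deterministic given seed and config", {
  cfg <- synthetic_config(n_patients = 15, seed = 123,
                          discordance_rate = 0.2, distractor_rate = 0.3)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$documents, b$documents)
  expect_identical(a$reference, b$reference)
  expect_identical(a$ledger, b$ledger)
  c <- generate_cohort(synthetic_config(n_patients = 15, seed = 124))
  expect_false(identical(a$documents$text, c$documents$text))
})

test_that("gold labels conserve the cohort and respect value domains", {
  co <- generate_cohort(synthetic_config(n_patients = 100, seed = 8))
  expect_equal(nrow(co$reference), 100)
  expect_true(all(co$reference$histology %in% lc_histology_values()))
  expect_true(all(co$reference$grade %in% lc_grade_values()))
  # SCLC patients get SCLC stages, others exact NSCLC stages
  sclc <- co$reference$histology == "SmallCell"
  expect_true(all(co$reference$stage[sclc] %in% c("Limited", "Extensive")))
  expect_true(all(co$reference$stage[!sclc] %in% lc_exact_stages()))
  # every patient has at least one clinical note and one pathology report
  per_src <- table(co$documents$patient_id, co$documents$source)
  expect_true(all(per_src[, "clinical_note"] >= 1))
  expect_true(all(per_src[, "pathology_report"] >= 1))
})

test_that("the generator's sentence boundaries are reproduced by segmentation", {
  co <- generate_cohort(synthetic_config(n_patients = 30, seed = 31,
                                         distractor_rate = 0.5))
  seg <- segment_sentences(co$documents)
  gen <- co$sentences[, c("doc_id", "sentence_id", "start", "end")]
  seg <- seg[, c("doc_id", "sentence_id", "start", "end")]
  ord <- function(d) d[order(d$doc_id, d$sentence_id), ]
  expect_equal(as.data.frame(ord(gen)), as.data.frame(ord(seg)),
               ignore_attr = TRUE)
})

test_that("ledger soundness: every template surface is extractable", {
  tpl <- load_templates()
  for (source in names(tpl$templates)) {
    for (el in intersect(names(tpl$templates[[source]]),
                         c("stage", "histology", "grade"))) {
      for (sent_tpl in tpl$templates[[source]][[el]]) {
        for (canonical in names(tpl$surfaces[[el]])) {
          for (surf in tpl$surfaces[[el]][[canonical]]) {
            sent <- gsub(paste0("{", el, "}"), surf, sent_tpl, fixed = TRUE)
            m <- extract_mentions(make_sentence(sent, source))
            hit <- m$normalized[m$element == el]
            expect_equal(hit, canonical,
                         label = paste(source, el, sent))
          }
        }
      }
    }
    for (el in intersect(names(tpl$templates[[source]]),
                         c("chemotherapy", "radiotherapy", "surgery"))) {
      for (sent_tpl in tpl$templates[[source]][[el]]) {
        sents <- if (grepl("{surgery_type}", sent_tpl, fixed = TRUE)) {
          vapply(tpl$surfaces$surgery_type, function(st) {
            gsub("{surgery_type}", st, sent_tpl, fixed = TRUE)
          }, character(1))
        } else sent_tpl
        for (sent in sents) {
          m <- extract_mentions(make_sentence(sent, source))
          expect_true(el %in% m$element, label = paste(source, sent))
        }
      }
    }
    # neutral sentences plant nothing
    for (sent in c(tpl$templates[[source]]$opening,
                   tpl$templates[[source]]$filler)) {
      expect_equal(nrow(extract_mentions(make_sentence(sent, source))), 0,
                   label = sent)
    }
  }
})

test_that("distractor sentences are planted but never extracted", {
  co <- generate_cohort(synthetic_config(n_patients = 30, seed = 17,
                                         distractor_rate = 1))
  planted_distractors <- co$ledger[!is.na(co$ledger$value) &
                                     co$ledger$value == "distractor", ]
  expect_gt(nrow(planted_distractors), 0)
  mentions <- extract_document(co$documents)
  hits <- dplyr::inner_join(
    planted_distractors[, c("doc_id", "sentence_id")],
    mentions[mentions$element == "histology",
             c("doc_id", "sentence_id")],
    by = c("doc_id", "sentence_id"))
  expect_equal(nrow(hits), 0)
})

test_that("discordance plants non-gold values at roughly the configured rate", {
  co <- generate_cohort(synthetic_config(n_patients = 150, seed = 29,
                                         discordance_rate = 0.3))
  planted <- co$ledger[co$ledger$element %in%
                         c("stage", "histology", "grade"), ]
  frac <- mean(!planted$is_gold)
  expect_gt(frac, 0.2)
  expect_lt(frac, 0.4)
})

test_that("corpus omission lowers recall but leaves the reference intact", {
  rates <- setNames(rep(0, 6), lc_elements())
  rates["grade"] <- 0.5
  co <- generate_cohort(synthetic_config(n_patients = 80, seed = 53,
                                         missing_element_rates = rates))
  expect_true(all(!is.na(co$reference$grade)))
  ext <- extract_patients(co$documents, co$patients)
  ev <- compute_metrics(ext, co$reference, "grade")
  expect_lt(ev$recall, 0.8)
  expect_equal(ev$precision2, 1)   # whatever is extracted is correct
})

test_that("a cohort round-trips to disk including the reference", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(synthetic_config(n_patients = 8, seed = 3))
  write_cohort(co, dir)
  back <- read_corpus(dir)
  expect_equal(as.data.frame(back$documents),
               as.data.frame(co$documents))
  ref <- read_reference(file.path(dir, "reference.csv"))
  expect_equal(as.data.frame(ref), as.data.frame(co$reference))
})
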