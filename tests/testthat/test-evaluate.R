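test_that("hierarchical value matching follows the evaluation rules", {
  expect_true(match_value("histology", "NSCLCUnspecified", "Adenocarcinoma"))
  expect_false(match_value("histology", "Adenocarcinoma", "SmallCell"))
  expect_false(match_value("histology", "Adenocarcinoma",
                           "NSCLCUnspecified"))  # not symmetric
  expect_true(match_value("stage", "EarlyStage", "Ib"))
  expect_true(match_value("stage", "LateStage", "IV"))
  expect_false(match_value("stage", "Ia", "EarlyStage"))  # no reverse map
  expect_false(match_value("grade", "PoorlyDifferentiated",
                           "ModeratelyDifferentiated"))
  expect_true(match_value("chemotherapy", TRUE, TRUE))
  expect_false(match_value("chemotherapy", TRUE, FALSE))
  expect_false(match_value("stage", NA, "Ia"))
})

test_that("metric arithmetic reproduces worked examples", {
  r <- metrics_from_counts(2127, 1330, 1883)
  expect_equal(round(r$precision1, 3), 0.625)
  expect_equal(round(r$precision2, 3), 0.706)
  expect_equal(round(r$recall, 3), 0.885)

  r2 <- metrics_from_counts(1635, 1170, 1300)
  expect_equal(round(r2$precision1, 3), 0.716)
  expect_equal(round(r2$precision2, 3), 0.900)
  expect_equal(round(r2$recall, 3), 0.795)

  r3 <- metrics_from_counts(50, 50, 50)
  expect_equal(c(r3$precision1, r3$precision2, r3$recall), c(1, 1, 1))

  expect_warning(metrics_from_counts(0, 0, 0))
  expect_error(metrics_from_counts(10, 5, 3))   # B > C impossible
})

test_that("patient-level counting anchors on the reference", {
  ref <- tibble::tibble(
    patient_id = c("p1", "p2", "p3", "p4"),
    stage = c("Ia", "EarlyStage", NA, "IV"),
    histology = c("Adenocarcinoma", NA, NA, "SmallCell"),
    grade = rep(NA_character_, 4),
    chemotherapy = c(TRUE, TRUE, FALSE, NA),
    radiotherapy = rep(FALSE, 4), surgery = rep(FALSE, 4))
  ext <- tibble::tibble(
    patient_id = c("p1", "p2", "p3", "p4", "p5"),
    stage = c("Ia", "IIb", "IIIa", NA, "Ia"),
    histology = c("Squamous", "Adenocarcinoma", NA, "SmallCell", NA),
    grade = rep(NA_character_, 5),
    chemotherapy = c(TRUE, FALSE, TRUE, TRUE, TRUE),
    radiotherapy = rep(FALSE, 5), surgery = rep(FALSE, 5))

  st <- compute_metrics(ext, ref, "stage")
  # A: p1,p2,p4 have reference stage; C: p1,p2 extracted; B: p1 exact +
  # p2 via the early-stage band; p3 and p5 contribute nothing
  expect_equal(c(st$A, st$B, st$C), c(3, 2, 2))

  hi <- compute_metrics(ext, ref, "histology")
  expect_equal(c(hi$A, hi$B, hi$C), c(2, 1, 2))

  ch <- compute_metrics(ext, ref, "chemotherapy")
  # reference-positive: p1, p2; flagged: p1 only
  expect_equal(c(ch$A, ch$B, ch$C), c(2, 1, 1))

  expect_error(compute_metrics(ext, ref[0, ], "stage"),
               class = "lungnlp_config_error")
})

test_that("precision1 equals precision2 times recall pre-rounding", {
  set.seed(42)
  for (i in 1:25) {
    A <- sample(50:3000, 1)
    C <- sample(1:A, 1)
    B <- sample(0:C, 1)
    r <- metrics_from_counts(A, B, C)
    expect_equal(r$precision1, r$precision2 * r$recall)
  }
})

test_that("coverage counts patients with eligible documents per source", {
  dx <- as.Date("2005-06-01")
  docs <- dplyr::bind_rows(
    make_doc("Note.", "clinical_note", "n1", "p1", dx),
    make_doc("Note.", "clinical_note", "n2", "p2", dx),
    make_doc("Path.", "pathology_report", "pr1", "p1", dx + 70),
    make_doc("Surg.", "surgery_report", "s1", "p2", dx + 10))
  pats <- dplyr::bind_rows(make_patient("p1", dx), make_patient("p2", dx),
                           make_patient("p3", dx))
  expect_equal(compute_coverage(docs, pats, "clinical_note"), 2)
  expect_equal(compute_coverage(docs, pats, "pathology_report",
                                time_window(14, 90)), 1)
  expect_equal(compute_coverage(docs, pats, "pathology_report",
                                time_window(14, 30)), 0)
  expect_equal(compute_coverage(docs, pats, "surgery_report",
                                time_window(14, 30)), 1)
  tab <- coverage_table(docs, pats)
  expect_equal(nrow(tab), 1 + 2 * 4)
  expect_true(all(tab$coverage <= nrow(pats)))
})

test_that("enlarging the window never decreases extraction coverage", {
  co <- generate_cohort(synthetic_config(
    n_patients = 40, seed = 99,
    offset_ranges = list(clinical_note = c(-30, 200),
                         pathology_report = c(-14, 85),
                         surgery_report = c(0, 85))))
  prev_c <- 0
  for (after in c(30, 60, 90)) {
    ext <- extract_patients(co$documents, co$patients,
                            window = time_window(14, after))
    ev <- compute_metrics(ext, co$reference, "grade")
    expect_gte(ev$C, prev_c)
    expect_lte(ev$B, ev$C)
    prev_c <- ev$C
  }
})

test_that("the windowed evaluation report has the expected layout", {
  co <- generate_cohort(synthetic_config(n_patients = 20, seed = 5))
  rep <- evaluate_windows(co$documents, co$patients, co$reference,
                          windows = c(30, 90))
  expect_equal(nrow(rep), 2 * 3 + 3)
  expect_setequal(unique(rep$element), lc_elements())
  expect_true(all(rep$B <= rep$C))
  expect_equal(rep$precision1, rep$precision2 * rep$recall)
  p <- ggplot2::autoplot(rep)
  expect_s3_class(p, "ggplot")
})

test_that("a reference standard round-trips through CSV", {
  dir <- withr::local_tempdir()
  ref <- tibble::tibble(
    patient_id = c("p1", "p2"),
    stage = c("Ia", NA), histology = c("Squamous", "SmallCell"),
    grade = c(NA, "Undifferentiated"),
    chemotherapy = c(TRUE, FALSE), radiotherapy = c(FALSE, NA),
    surgery = c(TRUE, TRUE))
  path <- file.path(dir, "reference.csv")
  write_reference(ref, path)
  expect_equal(as.data.frame(read_reference(path)), as.data.frame(ref))
  expect_error(write_reference(dplyr::mutate(ref, stage = "IA"), path),
               class = "lungnlp_config_error")
})
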