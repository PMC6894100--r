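# Template library for the synthetic EHR corpus generator.
#
# Every template is exactly one sentence (terminal period, uppercase
# start, no internal sentence punctuation or abbreviations), so the
# generator can record its own sentence boundaries. "{x}" placeholders
# are replaced with a surface realization of the planted canonical value;
# therapy templates are complete sentences already containing an
# extractable mention. Surfaces are listed most-canonical first: with
# surface variation disabled the generator always uses the first entry.
surfaces:
  stage:
    Ia: ["stage Ia", "stage IA", "stage 1a"]
    Ib: ["stage Ib", "stage IB", "stage 1b"]
    IIa: ["stage IIa", "stage IIA", "stage 2a"]
    IIb: ["stage IIb", "stage IIB", "stage 2b"]
    IIIa: ["stage IIIa", "stage IIIA", "stage 3a"]
    IIIb: ["stage IIIb", "stage IIIB", "stage 3b"]
    IV: ["stage IV", "stage 4"]
    EarlyStage: ["early stage", "early-stage"]
    LateStage: ["late stage", "late-stage"]
    Limited: ["limited stage", "limited-stage disease"]
    Extensive: ["extensive stage", "extensive disease"]
  histology:
    SmallCell: ["small cell carcinoma", "small cell lung cancer", "SCLC"]
    Adenocarcinoma: ["adenocarcinoma", "bronchioloalveolar adenocarcinoma"]
    Squamous: ["squamous cell carcinoma", "squamous carcinoma"]
    LargeNeuroendocrine: ["large cell neuroendocrine carcinoma", "larger neuroendocrine carcinoma"]
    Adenosquamous: ["adenosquamous carcinoma"]
    CarcinoidTypicalAtypical: ["atypical carcinoid", "typical carcinoid"]
    Carcinoid: ["carcinoid tumor"]
    NSCLCUnspecified: ["non-small cell lung cancer", "non-small cell carcinoma", "NSCLC"]
    OtherNSCLC: ["sarcomatoid carcinoma", "pleomorphic carcinoma"]
    OtherUnknown: ["unknown cell type"]
  grade:
    WellDifferentiated: ["well differentiated", "grade 1", "grade I"]
    ModeratelyDifferentiated: ["moderately differentiated", "grade 2", "grade II"]
    PoorlyDifferentiated: ["poorly differentiated", "grade 3", "grade III"]
    Undifferentiated: ["undifferentiated", "grade 4", "grade IV"]
  surgery_type: ["lobectomy", "wedge resection", "pneumonectomy", "segmentectomy"]
templates:
  clinical_note:
    opening:
      - "Patient seen in thoracic oncology clinic for follow-up."
      - "Follow-up visit regarding lung cancer management."
      - "Interval history was reviewed with the patient today."
    filler:
      - "Vital signs were stable today."
      - "Medication list was reviewed and reconciled."
      - "Return to clinic in six weeks was arranged."
    stage:
      - "Biopsy results were consistent with {stage} disease."
      - "Pathology review confirmed {stage}."
      - "Recent biopsy findings indicate {stage} disease."
    histology:
      - "Imaging and pathology are consistent with {histology}."
      - "Tumor board reviewed the diagnosis of {histology}."
      - "Outside pathology confirmed {histology}."
    grade:
      - "The lesion was reported as {grade}."
      - "Pathology described the tumor as {grade}."
    chemotherapy:
      - "The patient has begun chemotherapy."
      - "Cycle two of carboplatin chemotherapy was administered."
      - "Adjuvant chemo was recommended and accepted."
    radiotherapy:
      - "Radiation therapy to the chest is underway."
      - "Planned combined modality treatment."
      - "He has completed XRT to the mediastinum."
    surgery:
      - "He is status post lung cancer surgery."
      - "She underwent wedge resection last month."
      - "Status post lung cancer surgery with good recovery."
    distractor:
      - "Family history is notable for prostate adenocarcinoma in his father."
      - "Family history includes thyroid carcinoma in a sibling."
      - "Family history of breast adenocarcinoma was reported."
  pathology_report:
    opening:
      - "Specimen received from lung, right upper lobe, biopsy."
      - "Specimen received from lung, left lower lobe, needle core."
    filler:
      - "Gross description is on file with the specimen."
    stage:
      - "Pathologic staging is consistent with {stage}."
      - "Findings correspond to {stage} disease."
    histology:
      - "Diagnosis: {histology}."
      - "Sections show {histology}."
      - "Immunostains support a diagnosis of {histology}."
    grade:
      - "The tumor is {grade}."
      - "Histologic grade: {grade}."
  surgery_report:
    opening:
      - "Operative report for elective thoracic procedure."
      - "Operative report dictated following the procedure."
    filler:
      - "Estimated blood loss was minimal."
    stage:
      - "Intraoperative findings were consistent with {stage} disease."
    histology:
      - "Frozen section revealed {histology}."
    surgery:
      - "A {surgery_type} was performed without complication."
      - "Procedure performed: {surgery_type}."
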