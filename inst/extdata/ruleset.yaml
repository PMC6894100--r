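# Default extraction ruleset.
#
# Each rule: element, id, a case-insensitive Perl regular expression,
# the capture group holding the value to normalize (0 = whole match),
# the document sources the rule applies to, and exclusion contexts --
# regular expressions that suppress the rule's matches anywhere in the
# same sentence. Non-lung primary sites and a family-history cue guard
# the histology rules; the family-history cue also guards the therapy
# rules. Site-specific vocabularies can be swapped by pointing
# load_ruleset() at an edited copy of this file.
version: "1.0"
negation_cues:
  - '\bno\s+evidence\s+of\b'
  - '\bdenies\b'
rules:
  - element: stage
    id: stage_exact
    pattern: '\bstage\s+(IIIa|IIIb|IIa|IIb|Ia|Ib|IV|3a|3b|2a|2b|1a|1b|4)\b'
    capture: 1
    sources: [clinical_note, pathology_report, surgery_report]
    exclusions: []
  - element: stage
    id: stage_band
    pattern: '\b(early|late)[\s-]+stage\b'
    capture: 0
    sources: [clinical_note, pathology_report, surgery_report]
    exclusions: []
  - element: stage
    id: stage_sclc
    pattern: '\b(limited|extensive)[\s-]+(stage|disease)\b'
    capture: 0
    sources: [clinical_note, pathology_report, surgery_report]
    exclusions: []
  - element: stage
    id: stage_sclc_after
    pattern: '\bstage\s+(limited|extensive)\b'
    capture: 1
    sources: [clinical_note, pathology_report, surgery_report]
    exclusions: []
  - element: histology
    id: hist_nonsmall
    pattern: '\bnon[\s-]+small[\s-]+cell(\s+(lung\s+)?(carcinoma|cancer))?\b'
    capture: 0
    sources: [clinical_note, pathology_report, surgery_report]
    exclusions: ['\b(prostate|thyroid|breast|colon|skin)\b', '\bfamily\s+history\b']
  - element: histology
    id: hist_small
    pattern: '\bsmall[\s-]+cell(\s+(lung\s+)?(carcinoma|cancer))?\b'
    capture: 0
    sources: [clinical_note, pathology_report, surgery_report]
    exclusions: ['\b(prostate|thyroid|breast|colon|skin)\b', '\bfamily\s+history\b']
  - element: histology
    id: hist_abbrev
    pattern: '\b(sclc|nsclc)\b'
    capture: 0
    sources: [clinical_note, pathology_report, surgery_report]
    exclusions: ['\b(prostate|thyroid|breast|colon|skin)\b', '\bfamily\s+history\b']
  - element: histology
    id: hist_oat
    pattern: '\boat\s+cell\s+carcinoma\b'
    capture: 0
    sources: [clinical_note, pathology_report, surgery_report]
    exclusions: ['\b(prostate|thyroid|breast|colon|skin)\b', '\bfamily\s+history\b']
  - element: histology
    id: hist_adeno
    pattern: '\badenocarcinoma\b'
    capture: 0
    sources: [clinical_note, pathology_report, surgery_report]
    exclusions: ['\b(prostate|thyroid|breast|colon|skin)\b', '\bfamily\s+history\b']
  - element: histology
    id: hist_bac
    pattern: '\bbronchioloalveolar(\s+(adenocarcinoma|carcinoma))?\b'
    capture: 0
    sources: [clinical_note, pathology_report, surgery_report]
    exclusions: ['\b(prostate|thyroid|breast|colon|skin)\b', '\bfamily\s+history\b']
  - element: histology
    id: hist_squamous
    pattern: '\bsquamous(\s+cell)?(\s+carcinoma)?\b'
    capture: 0
    sources: [clinical_note, pathology_report, surgery_report]
    exclusions: ['\b(prostate|thyroid|breast|colon|skin)\b', '\bfamily\s+history\b']
  - element: histology
    id: hist_adenosquamous
    pattern: '\badenosquamous(\s+carcinoma)?\b'
    capture: 0
    sources: [clinical_note, pathology_report, surgery_report]
    exclusions: ['\b(prostate|thyroid|breast|colon|skin)\b', '\bfamily\s+history\b']
  - element: histology
    id: hist_lcne
    pattern: '\blarge(r)?(\s+cell)?\s+neuroendocrine(\s+carcinoma)?\b'
    capture: 0
    sources: [clinical_note, pathology_report, surgery_report]
    exclusions: ['\b(prostate|thyroid|breast|colon|skin)\b', '\bfamily\s+history\b']
  - element: histology
    id: hist_carcinoid_subtyped
    pattern: '\b(typical|atypical)\s+carcinoid(\s+tumor)?\b'
    capture: 0
    sources: [clinical_note, pathology_report, surgery_report]
    exclusions: ['\b(prostate|thyroid|breast|colon|skin)\b', '\bfamily\s+history\b']
  - element: histology
    id: hist_carcinoid
    pattern: '\bcarcinoid(\s+tumor)?\b'
    capture: 0
    sources: [clinical_note, pathology_report, surgery_report]
    exclusions: ['\b(prostate|thyroid|breast|colon|skin)\b', '\bfamily\s+history\b']
  - element: histology
    id: hist_other_nsclc
    pattern: '\b(sarcomatoid|pleomorphic|giant\s+cell)\s+carcinoma\b'
    capture: 0
    sources: [clinical_note, pathology_report, surgery_report]
    exclusions: ['\b(prostate|thyroid|breast|colon|skin)\b', '\bfamily\s+history\b']
  - element: histology
    id: hist_unknown
    pattern: '\b(unknown\s+cell\s+type|cell\s+type\s+unknown|other\s+cell\s+type)\b'
    capture: 0
    sources: [clinical_note, pathology_report, surgery_report]
    exclusions: ['\b(prostate|thyroid|breast|colon|skin)\b', '\bfamily\s+history\b']
  - element: grade
    id: grade_numeric
    pattern: '\bgrade\s+(4|3|2|1|IV|III|II|I)\b'
    capture: 1
    sources: [clinical_note, pathology_report, surgery_report]
    exclusions: []
  - element: grade
    id: grade_verbal
    pattern: '\b(well|moderately|poorly)[\s-]+differentiated\b'
    capture: 0
    sources: [clinical_note, pathology_report, surgery_report]
    exclusions: []
  - element: grade
    id: grade_undifferentiated
    pattern: '\bundifferentiated\b'
    capture: 0
    sources: [clinical_note, pathology_report, surgery_report]
    exclusions: []
  - element: chemotherapy
    id: chemo_keyword
    pattern: '\bchemo(therapy)?\b'
    capture: 0
    sources: [clinical_note, surgery_report]
    exclusions: ['\bfamily\s+history\b']
  - element: chemotherapy
    id: chemo_regimen
    pattern: '\b(carboplatin|cisplatin|paclitaxel|etoposide|pemetrexed|gemcitabine)\b'
    capture: 0
    sources: [clinical_note, surgery_report]
    exclusions: ['\bfamily\s+history\b']
  - element: radiotherapy
    id: radio_keyword
    pattern: '\bradiation\s+(therapy|treatment)\b|\bradiotherapy\b|\bxrt\b'
    capture: 0
    sources: [clinical_note, surgery_report]
    exclusions: ['\bfamily\s+history\b']
  - element: radiotherapy
    id: radio_combined_modality
    pattern: '\bcombined\s+modality\b'
    capture: 0
    sources: [clinical_note, surgery_report]
    exclusions: ['\bfamily\s+history\b']
  - element: surgery
    id: surgery_procedure
    pattern: '\b(segmentectomy|lobectomy|pneumonectomy|wedge\s+resection|thoracotomy)\b'
    capture: 0
    sources: [clinical_note, surgery_report]
    exclusions: ['\bfamily\s+history\b']
  - element: surgery
    id: surgery_status_post
    pattern: '\b(status\s+post\s+)?lung\s+cancer\s+surgery\b'
    capture: 0
    sources: [clinical_note, surgery_report]
    exclusions: ['\bfamily\s+history\b']
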