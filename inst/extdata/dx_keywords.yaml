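# Default keyword table for classifying free-text pathologic diagnoses of
# gastrointestinal endoscopic biopsies into M / D / N / U, and for routing
# specimens to the organ-specific model from the specimen heading.
#
# Matching rules (see classifyDx):
#   * text is lowercased (except case_sensitive keywords) and tokenized on
#     non-alphanumeric characters; multi-word phrases must match contiguous
#     tokens
#   * keyword tokens with at least substring_min_chars characters also match
#     inside a longer token (so "carcinoma" fires in "adenocarcinoma" and
#     "carcinomatous"); shorter tokens ("high", "low", "NET") match whole
#     tokens only
#   * evaluation order: M, then U, then the sessile-serrated overrides
#     (which force N), then D; anything else is N
substring_min_chars: 6
classes:
  M:
    - Carcinoma
    - High
    - Grade undetermined
    - Grade uncertain
    - Favor neoplastic
    - Sarcoma
    - Lymphoma
    - Malignant
    - Malignancy
    - Cancer
  U:
    - Neuroendocrine
    - Carcinoid
    - NET
  D:
    - Dysplasia
    - Adenoma
    - Low
    - Indefinite for dysplasia
    - Undetermined significance
n_overrides:
  - Sessile serrated adenoma/polyp
  - Sessile serrated adenoma
  - Sessile serrated lesion
case_sensitive:
  - NET
organ_routes:
  gastric:
    - Stomach
    - Esophagogastric junction
    - Gastroesophageal junction
  colorectal:
    - Terminal ileum
    - Ileocecal valve
    - Cecum
    - Colon
    - Large intestine
    - Rectosigmoid junction
    - Colon and Rectum
    - Rectum
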