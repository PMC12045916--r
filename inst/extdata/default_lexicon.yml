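# Default term lexicon, version 1.
#
# Term syntax: terms are matched case-insensitively on normalized text
# (lowercased, hyphens/slashes mapped to spaces, whitespace collapsed).
# A single word matches as a whole token; a trailing "-" marks a
# token-prefix pattern ("scr-" matches screen, screening, scr, ...);
# a multi-word term matches as a token sequence.
lexicon_version: 1
screening_terms:
  - low dose
  - ldct
  - lcs
  - scr-
scr_exception_phrases:
  - "Is this procedure to screen for malignancy?"
  - "This study is not intended for lung cancer screening."
  - "HCC screening."
  - "Not for initial screening."
diagnostic_terms:
  - cough
  - hemoptysis
  - chest pain
  - weight loss
  - dyspnea
  - shortness of breath
  - wheezing
  - hoarseness
  - fatigue
  - pneumonia
  - fever
  - night sweats
fleischner_terms:
  - fleischner
  - fleishner
  - fleichner
  - fleischer
imported_markers:
  - Exam imported from outside
  - Imported study
in_scope_cpt:
  - "71250"
  - G0297
  - S8023
  - "71271"
lcs_specific_cpt:
  - G0297
  - S8023
  - "71271"
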