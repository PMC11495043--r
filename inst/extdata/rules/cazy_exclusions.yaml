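# CAZyme biosynthetic exclusion list, version 1. Calls whose family
# class is GT (glycosyltransferase) or whose family description matches
# one of these labels are excluded as probable biosynthetic/cell-wall-
# recycling functions.
excluded_class_labels:
  - Glycoside transferases
  - Soluble_lytic_murein_transglycosylase
  - Peptidoglycan-N-acetylmuramic_acid_deacetylase_PdaC
  - Peptidoglycan_hydrolase_FlgJ
  - Membrane-bound_lytic_murein_transglycosylase_A
  - Membrane-bound_lytic_murein_transglycosylase_D
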