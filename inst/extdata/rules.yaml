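# Default categorization rule set.
#
# The shipped keyword rules cover the documented per-source conventions for
# low-annotation wording (e.g. "predicted", "hypothetical" in descriptions)
# and high-trust functional evidence (assay-backed evidence codes,
# experimentally supported transcription-factor annotations). The engine is
# data-driven: extend these lists freely for a specific knowledge-base
# release; rules are matched case-insensitively, `match_mode: substring`
# matches anywhere in the feature value, `word` on whole-word boundaries.
keyword_rules:
  - {kb: ecocyc, feature_type: description, pattern: possibly, target: yome, match_mode: substring}
  - {kb: ecocyc, feature_type: description, pattern: predicted, target: yome, match_mode: substring}
  - {kb: ecocyc, feature_type: description, pattern: hypothetical, target: yome, match_mode: substring}
  - {kb: ecocyc, feature_type: evidence, pattern: assay, target: well_annotated, match_mode: substring}
  - {kb: ecocyc, feature_type: evidence, pattern: traceable author statement to experimental support, target: well_annotated, match_mode: substring}
  - {kb: ecocyc, feature_type: evidence, pattern: reaction blocked in mutant, target: well_annotated, match_mode: substring}
  - {kb: uniprot, feature_type: description, pattern: putative uncharacterized, target: yome, match_mode: substring}
  - {kb: regulondb, feature_type: tf_evidence, pattern: strong, target: well_annotated, match_mode: word}

# Structured (non-keyword) rules; each can be switched off.
structured_rules:
  ecocyc_reaction_equation: true    # reaction equation present -> well_annotated
  ecocyc_complex: true              # complex membership -> well_annotated
  ecocyc_insertion: true            # insertion element flag -> well_annotated
  ecocyc_ins_name: true             # primary name beginning "ins" -> well_annotated
  uniprot_annotation_score: true    # <=2 yome, 3 insufficient, >=4 well_annotated
  pseudogene_flag: true             # -> excluded (any source)
  phantom_flag: true                # -> excluded (any source)
  ecogene_apostrophe: true          # primary name ending in apostrophe -> excluded

# Phrases that mark a feature value as carrying no functional information
# (prefix match, case-insensitive); domain_only features always count as
# uninformative. Scanned feature types are listed below.
no_info_phrases:
  - no information about this
  - putative uncharacterized
no_info_feature_types: [description, summary]
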