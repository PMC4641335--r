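# Default SeMaS instrument definition.
#
# Items are identified by construct + ordinal; wording is an optional `label`
# and is not part of scoring. The anxiety and depression category bands below
# are placeholders (authoritative: false): the source subscales keep their own
# published cut-offs, which must be supplied here by the user for clinical use.
schema_version: 1
name: SeMaS
scales:
  agree4:
    # completely false .. completely true
    levels:
      - {code: 1, label: "completely false", score: 0}
      - {code: 2, label: "somewhat false",   score: 1}
      - {code: 3, label: "somewhat true",    score: 2}
      - {code: 4, label: "completely true",  score: 3}
  freq5:
    # symptom frequency scale: never .. very often/continuously
    levels:
      - {code: 1, label: "never",                     score: 0}
      - {code: 2, label: "sometimes",                 score: 1}
      - {code: 3, label: "regularly",                 score: 2}
      - {code: 4, label: "often",                     score: 3}
      - {code: 5, label: "very often/continuously",   score: 4}
  freq5_coping:
    # coping reuses the 5-point frequency scale, but the added option
    # "often" scores the same as "very often/continuously" (declared collapse)
    collapse: true
    levels:
      - {code: 1, label: "never",                     score: 0}
      - {code: 2, label: "sometimes",                 score: 1}
      - {code: 3, label: "regularly",                 score: 2}
      - {code: 4, label: "often",                     score: 3}
      - {code: 5, label: "very often/continuously",   score: 3}
  support5:
    # "no", "completely false" and "somewhat false" all score 0 (declared collapse)
    collapse: true
    levels:
      - {code: 1, label: "no",               score: 0}
      - {code: 2, label: "completely false", score: 0}
      - {code: 3, label: "somewhat false",   score: 0}
      - {code: 4, label: "somewhat true",    score: 1}
      - {code: 5, label: "completely true",  score: 2}
constructs:
  self_efficacy:
    role: barrier_construct
    missing_policy: exclude_case
    items:
      - {item_id: se_1, scale: agree4}
      - {item_id: se_2, scale: agree4}
    category_rule:
      kind: banded
      bands:
        - {lo: 0, hi: 1, category: major}
        - {lo: 2, hi: 3, category: minor}
        - {lo: 4, hi: 6, category: none}
  coping_P:
    role: barrier_construct
    group: coping
    missing_policy: exclude_case
    items:
      - {item_id: cop_p1, scale: freq5_coping}
      - {item_id: cop_p2, scale: freq5_coping}
    category_rule: {kind: style_dominance}
  coping_E:
    role: barrier_construct
    group: coping
    missing_policy: exclude_case
    items:
      - {item_id: cop_e1, scale: freq5_coping}
      - {item_id: cop_e2, scale: freq5_coping}
    category_rule: {kind: style_dominance}
  coping_D:
    role: barrier_construct
    group: coping
    missing_policy: exclude_case
    items:
      - {item_id: cop_d1, scale: freq5_coping}
      - {item_id: cop_d2, scale: freq5_coping}
    category_rule: {kind: style_dominance}
  depression:
    role: barrier_construct
    missing_policy: exclude_case
    items:
      - {item_id: dep_1, scale: freq5}
      - {item_id: dep_2, scale: freq5}
      - {item_id: dep_3, scale: freq5}
    category_rule:
      kind: external_table
      authoritative: false   # placeholder bands, supply published cut-offs
      bands:
        - {lo: 0, hi: 2,  category: none}
        - {lo: 3, hi: 5,  category: minor}
        - {lo: 6, hi: 12, category: major}
  anxiety:
    role: barrier_construct
    missing_policy: exclude_case
    items:
      - {item_id: anx_1, scale: freq5}
      - {item_id: anx_2, scale: freq5}
      - {item_id: anx_3, scale: freq5}
      - {item_id: anx_4, scale: freq5}
    category_rule:
      kind: external_table
      authoritative: false   # placeholder bands, supply published cut-offs
      bands:
        - {lo: 0, hi: 3,  category: none}
        - {lo: 4, hi: 7,  category: minor}
        - {lo: 8, hi: 16, category: major}
  locus_internal:
    role: barrier_construct
    group: locus
    missing_policy: exclude_case
    items:
      - {item_id: loc_int, scale: agree4}
    category_rule: {kind: dichotomy}
  locus_external:
    role: barrier_construct
    group: locus
    missing_policy: exclude_case
    items:
      - {item_id: loc_ext, scale: agree4}
    category_rule: {kind: dichotomy}
  social_support:
    role: barrier_construct
    missing_policy: treat_missing_as_zero
    items:
      - {item_id: ss_1, scale: support5}
      - {item_id: ss_2, scale: support5}
      - {item_id: ss_3, scale: support5}
      - {item_id: ss_4, scale: support5}
      - {item_id: ss_5, scale: support5}
      - {item_id: ss_6, scale: support5, label: "support from neighbours"}
    category_rule:
      kind: banded
      bands:
        - {lo: 0, hi: 1,  category: major}
        - {lo: 2, hi: 2,  category: minor}
        - {lo: 3, hi: 12, category: none}
  burden:
    role: barrier_construct
    missing_policy: exclude_case
    items:
      - {item_id: burden, vas: true, label: "perceived burden of disease (VAS 0-10)"}
    category_rule:
      kind: u_shaped
      bands:
        - {lo: 0, hi: 2,  category: minor}
        - {lo: 3, hi: 7,  category: none}
        - {lo: 8, hi: 10, category: minor}
  computer_skills:
    role: guidance_item
    missing_policy: exclude_case
    items:
      - {item_id: guide_pc, scale: agree4}
  group_functioning:
    role: guidance_item
    missing_policy: exclude_case
    items:
      - {item_id: guide_group, scale: agree4}
  self_monitoring_willingness:
    role: guidance_item
    missing_policy: exclude_case
    items:
      - {item_id: guide_selfmon, scale: agree4}
settings:
  # which dominant coping style counts as a barrier; ties (multiple styles) -> minor
  coping_style_category: {P: none, E: minor, D: minor, multiple: minor}
  locus_tie: internal
  locus_category: {internal: none, external: minor}
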