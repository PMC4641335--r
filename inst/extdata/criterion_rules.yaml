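# Example criterion rule set for validation runs on synthetic cohorts.
#
# ILLUSTRATIVE ONLY: these rules mirror SeMaS-style banding on the criterion
# channel. The published cut-offs and norms of the original full-length
# instruments (perceived competence scale, UCL-k, 4DSQ, MHLCS, SSSS) are not
# redistributed with this package; supply them here for a real validation.
rules:
  self_efficacy:
    type: category
  coping:
    type: dominance
    non_barrier_styles: [P]
  depression:
    type: category
  anxiety:
    type: category
  locus:
    type: orientation
    barrier_orientation: external
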