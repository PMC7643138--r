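# Example simulation config for the operant CLI (inst/cli/operant.R).
# Flat key-value mapping; unknown keys are rejected.
seed: 1
n_per_group: 16
tasks:
  - pr4
  - pr4_prefed
  - pr8
  - pr12
  - fr1_uncapped
  - ext
  - reinstate
  - vd_rev
ext_sessions_max: 20
acq_sessions_max: 20
rev_sessions_max: 30
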