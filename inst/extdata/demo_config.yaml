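# Demo pipeline configuration: 20,000-person community, 3 bundled trials.
sim:
  n_community: 20000
  n_trial: 1000
  seed: 2026
policy: strict
select_structure: false
n_mc: 2000
n_boot: 99
outcome: sae
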