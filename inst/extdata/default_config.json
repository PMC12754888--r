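{
  "seed": 1,
  "n_respondents": 10000,
  "n_sets": 40,
  "n_blocks": 8,
  "n_candidates": 100000,
  "p_inattentive": 0.10,
  "include_optout_asc": true,
  "hesitancy_threshold": 3,
  "rai_exclude": "cost"
}
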