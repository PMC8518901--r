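# Canonical degree-distribution scenarios: shifted negative binomials of
# increasing variance at (nominal) mean degree 10, per-link transmission
# rate tau = 0.016 per day, recovery rate 1/14 per day.
- name: delta-like
  "n": 1.0
  p: 0.99
  shift: 9
  tau: 0.016
- name: normal-like
  "n": 3.86
  p: 0.31
  shift: 1
  tau: 0.016
- name: scale-free-like
  "n": 1.07
  p: 0.107
  shift: 1
  tau: 0.016
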