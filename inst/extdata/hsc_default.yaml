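# Default brown-trout habitat suitability curves.
# depth curves take x in cm; velocity curves take x in cm/s.
adult:
  depth:
    family: gaussian_offset
    c: 0.1357
    A: 0.8643
    mu: 51.78
    sigma: 35.87
  velocity:
    family: gamma_offset
    c: 0.1
    A: 0.9
    lam: 1.421
    u0: 12.08
    theta: 25.71
juvenile:
  depth:
    family: gaussian_offset
    c: 0.074
    A: 0.926
    mu: 45.85
    sigma: 45.62
  velocity:
    family: gamma_offset
    c: 0.06047
    A: 0.93953
    lam: 1.113
    u0: 15.1
    theta: 32.95
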