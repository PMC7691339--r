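# Shipped conserved-cysteine scaffold profiles in the format accepted
# by read_pattern_config(). Copy and edit to supply custom profiles.
obp_classic:
  residues: CCCCCC
  gap_min: [0, 23, 3, 36, 8, 8]
  gap_max: [0, 44, 3, 43, 12, 8]
obp_minusc:
  residues: CCCC
  gap_min: [0, 27, 36, 17]
  gap_max: [0, 48, 43, 21]
csp:
  residues: CCCC
  gap_min: [0, 6, 18, 2]
  gap_max: [0, 6, 18, 2]
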