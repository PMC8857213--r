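# PUL classification rule table.  Rules are applied in order; the first
# match wins.  Conditions per rule:
#   inward_pair:  TRUE requires two contiguous inward-pointing (+,-) GH29
#                 genes in the window
#   all_of:       every listed tag must occur in the window
#   any_of:       list of groups; each group must contribute >= 1 tag
#   no_sulfatase: TRUE requires the window to carry no S1_<n> tag
#   supporting:   tags recorded in matched_features when present, never
#                 required
#   disabled:     rule slot kept for completeness, never matched
rules:
  - type: PUL-7
    inward_pair: true
    all_of: [S1_15]
    supporting: [PF03629]
  - type: PUL-3
    all_of: [S1_17, S1_25]
  - type: PUL-4
    any_of:
      - [S1_7, S1_8, S1_19]
      - [GH139, GH141]
  - type: PUL-5
    any_of:
      - [S1_22]
      - [GH2, GH31, GH36]
    supporting: [S1_17]
  - type: PUL-6
    any_of:
      - [S1_16]
      - [GH2, GH31, GH36]
  - type: PUL-1
    no_sulfatase: true
    any_of:
      - [PF07859]
  - type: PUL-2
    disabled: true
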