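# SOFA subscore bands (canonical 1996 definition, vasopressor tiers omitted
# because vasopressor dosing channels are optional and off by default).
# Band convention: value < breaks[1] -> points[1], breaks[1] <= value <
# breaks[2] -> points[2], ..., value >= breaks[last] -> points[last+1].
version: 1
coagulation:        # platelets, 10^3/uL
  breaks: [20, 50, 100, 150]
  points: [4, 3, 2, 1, 0]
liver:              # bilirubin, mg/dL
  breaks: [1.2, 2.0, 6.0, 12.0]
  points: [0, 1, 2, 3, 4]
renal:              # creatinine, mg/dL
  breaks: [1.2, 2.0, 3.5, 5.0]
  points: [0, 1, 2, 3, 4]
cns:                # Glasgow Coma Score
  breaks: [6, 10, 13, 15]
  points: [4, 3, 2, 1, 0]
cardiovascular:     # mean arterial pressure, mm Hg
  map_lo: 70        # MAP below this scores 1; higher tiers need vasopressors
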