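# Modified Early Warning Score component bands (Subbe et al., 2001).
# Band convention as in sofa.yaml. AVPU is derived from GCS upstream.
version: 1
sbp:                # systolic blood pressure, mm Hg
  breaks: [71, 81, 101, 200]
  points: [3, 2, 1, 0, 2]
hr:                 # heart rate, /min
  breaks: [41, 51, 101, 111, 130]
  points: [2, 1, 0, 1, 2, 3]
rr:                 # respiration rate, /min
  breaks: [9, 15, 21, 30]
  points: [2, 0, 1, 2, 3]
temp:               # temperature, degrees C
  breaks: [35.0, 38.5]
  points: [2, 0, 2]
avpu:               # consciousness level
  alert: 0
  voice: 1
  pain: 2
  unresponsive: 3
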