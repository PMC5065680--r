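# SAPS II component point bands (Le Gall et al., 1993), restricted to the
# variables carried by the channel registry. Each physiology component is
# scored on the worst hourly value inside the admission window (worst =
# highest point total); missing variables score 0. Chronic-disease and
# admission-type points default to 0 unless supplied by the caller.
# Band convention as in sofa.yaml.
version: 1
age:                # years
  breaks: [40, 60, 70, 75, 80]
  points: [0, 7, 12, 15, 16, 18]
hr:                 # heart rate, /min
  breaks: [40, 70, 120, 160]
  points: [11, 2, 0, 4, 7]
sbp:                # systolic blood pressure, mm Hg
  breaks: [70, 100, 200]
  points: [13, 5, 0, 2]
temp:               # temperature, degrees C
  breaks: [39]
  points: [0, 3]
gcs:                # Glasgow Coma Score
  breaks: [6, 9, 11, 14]
  points: [26, 13, 7, 5, 0]
bilirubin:          # mg/dL
  breaks: [4.0, 6.0]
  points: [0, 4, 9]
wbc:                # 10^3/uL
  breaks: [1.0, 20.0]
  points: [12, 0, 3]
chronic:
  none: 0
  metastatic_cancer: 9
  hematologic_malignancy: 10
  aids: 17
admission:
  scheduled_surgical: 0
  medical: 6
  unscheduled_surgical: 8
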