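# Systemic Inflammatory Response Syndrome criterion thresholds (1992
# consensus definition). One point per criterion met; missing inputs do not
# score. The >10 percent immature-band criterion is not represented (no
# differential-count channel).
version: 1
temp_hi: 38.0       # degrees C
temp_lo: 36.0
hr_hi: 90           # /min
rr_hi: 20           # /min
paco2_lo: 32        # mm Hg
wbc_hi: 12          # 10^3/uL
wbc_lo: 4
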