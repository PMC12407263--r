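# Clinical interpretation bands for the three-biomarker panel.
# Bands are advisory flags against published normal ranges, never a
# diagnosis.
CEA:
  units: ng/mL
  normal_below: 5        # healthy individuals
  elevated_above: 20     # values above suggest follow-up
CA125:
  units: U/mL
  normal_upper: 35       # conventional upper limit of normal in serum
  strongly_elevated_above: 100
CRP:
  units: ug/mL
  low_high_boundary: 10  # sandwich/competitive branch boundary
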