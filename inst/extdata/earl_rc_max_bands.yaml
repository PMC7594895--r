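# Maximum-voxel recovery-coefficient acceptance windows per sphere
# diameter, in the style of the EARL accreditation specification
# (standard-1 RC_max ranges; nominal = interval midpoint).  Editable:
# replace with your accreditation programme's current values, or point
# earl_band_table() at a different file.
source: EARL
bands:
  - {diameter_mm: 10, nominal: 0.455, lower: 0.34, upper: 0.57}
  - {diameter_mm: 13, nominal: 0.72,  lower: 0.59, upper: 0.85}
  - {diameter_mm: 17, nominal: 0.87,  lower: 0.73, upper: 1.01}
  - {diameter_mm: 22, nominal: 0.96,  lower: 0.83, upper: 1.09}
  - {diameter_mm: 28, nominal: 1.02,  lower: 0.91, upper: 1.13}
  - {diameter_mm: 37, nominal: 1.055, lower: 0.95, upper: 1.16}
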