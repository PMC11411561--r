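endmember:
  label: Irinovskoe
  concentrations:
    H2:  {value: 7.5, unit: mM}
    H2S: {value: 3.2, unit: mM}
    CH4: {value: 0.78, unit: mM}
    CO:  {value: 1.9, unit: uM}
seawater:
  oxygen:  {value: 250, unit: uM}
  sulfate: {value: 28, unit: mM}
  pH: 8.0
  temperature_K: 275.9
  pressure_bar: 265
  activity_coefficients:
    SO4: 0.12
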