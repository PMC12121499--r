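# Five-state charge-separation cascade, far-red system (Chl d at Chl_D1).
# Forward rates are the calibrated default table; back rates are added by
# detailed balance at temperature_K.
temperature_K: 298.15
reversible: true
states:
  - {label: "S1", energy_eV: 1.72}
  - {label: "ChlD1+ PheoD1-", energy_eV: 1.57}
  - {label: "PD1PD2+ QA-", energy_eV: 1.45}
  - {label: "Mn_ox QA-", energy_eV: 1.35}
  - {label: "Mn_ox QB-", energy_eV: 1.25}
edges:
  - {from: "S1", to: "ChlD1+ PheoD1-", k_forward_s1: 3.0e11}
  - {from: "ChlD1+ PheoD1-", to: "PD1PD2+ QA-", k_forward_s1: 3.47e9}
  - {from: "PD1PD2+ QA-", to: "Mn_ox QA-", k_forward_s1: 1.0e7}
  - {from: "Mn_ox QA-", to: "Mn_ox QB-", k_forward_s1: 2.31e3}
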