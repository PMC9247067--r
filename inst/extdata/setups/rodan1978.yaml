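setup:
  id: rodan1978
  radius_mm: 15.0
  layers:
    - name: Copper Electrode
      role: electrode
      thickness_mm: 1.0
      sigma_S_per_m: 5.998e+7
      eps_r: 1.0
    - name: Polypropylene
      role: insulator
      thickness_mm: 1.0
      sigma_S_per_m: 1.0e-16
      eps_r: 2.1
    - name: Culture Medium
      role: medium
      thickness_mm: 13.0
      sigma_S_per_m: 1.5
      eps_r: 80.1
    - name: Polypropylene
      role: insulator
      thickness_mm: 1.0
      sigma_S_per_m: 1.0e-16
      eps_r: 2.1
    - name: Copper Electrode
      role: electrode
      thickness_mm: 1.0
      sigma_S_per_m: 5.998e+7
      eps_r: 1.0
  waveform:
    type: trapezoid
    amplitude_V: 1750.0
    rise_s: 1.85e-3
    width_s: 0.1
    fall_s: 1.85e-3
    polarity: 1
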