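setup:
  id: hartig2000
  radius_mm: 65.0
  layers:
    - name: High Grade Stainless Steel Electrode
      role: electrode
      thickness_mm: 2.0
      sigma_S_per_m: 1.4e+6
      eps_r: 1.0
    - name: Air
      role: insulator
      thickness_mm: 2.0
      sigma_S_per_m: 1.0e-14
      eps_r: 1.005
    - name: Culture Medium
      role: medium
      thickness_mm: 2.5
      sigma_S_per_m: 1.5
      eps_r: 80.1
    - name: Polystyrene
      role: insulator
      thickness_mm: 1.0
      sigma_S_per_m: 6.7e-14
      eps_r: 2.5
    - name: High Grade Stainless Steel Electrode
      role: electrode
      thickness_mm: 2.0
      sigma_S_per_m: 1.4e+6
      eps_r: 1.0
  waveform:
    type: sawtooth
    peak_to_peak_V: 100.0
    rise_s: 45.0e-9
    fall_s: 62.5e-3
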