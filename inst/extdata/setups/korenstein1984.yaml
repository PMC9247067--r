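setup:
  id: korenstein1984
  radius_mm: 27.0
  layers:
    - name: Copper Electrode
      role: electrode
      thickness_mm: 1.0
      sigma_S_per_m: 5.99e+7
      eps_r: 1.0
    - name: Air
      role: insulator
      thickness_mm: 1.25
      sigma_S_per_m: 1.0e-14
      eps_r: 1.005
    - name: Culture Medium
      role: medium
      thickness_mm: 2.25
      sigma_S_per_m: 1.5
      eps_r: 74.0
    - name: Polystyrene
      role: insulator
      thickness_mm: 1.0
      sigma_S_per_m: 6.7e-14
      eps_r: 2.5
    - name: Copper Electrode
      role: electrode
      thickness_mm: 1.0
      sigma_S_per_m: 5.99e+7
      eps_r: 1.0
  waveform:
    type: trapezoid
    amplitude_V: 300.0
    rise_s: 7.0e-9
    width_s: 25.0e-6
    fall_s: 7.0e-9
    polarity: -1
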