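setup:
  id: brighton1992
  radius_mm: 16.5
  layers:
    - name: Stainless Steel Electrode
      role: electrode
      thickness_mm: 1.0
      sigma_S_per_m: 4.032e+6
      eps_r: 1.0
    - name: No.1 Glass Coverslip
      role: insulator
      thickness_mm: 0.16
      sigma_S_per_m: 1.0e-13
      eps_r: 6.85
    - name: Culture Medium
      role: medium
      thickness_mm: 9.8
      sigma_S_per_m: 1.5
      eps_r: 80.1
    - name: No.1 Glass Coverslip
      role: insulator
      thickness_mm: 0.16
      sigma_S_per_m: 1.0e-13
      eps_r: 6.85
    - name: Stainless Steel Electrode
      role: electrode
      thickness_mm: 1.0
      sigma_S_per_m: 4.032e+6
      eps_r: 1.0
  waveform:
    type: sinusoid
    amplitude_V: 44.81
    frequency_Hz: 60.0e+3
    phase_rad: 0.0
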