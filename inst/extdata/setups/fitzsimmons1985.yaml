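setup:
  id: fitzsimmons1985
  radius_mm: 26.0
  layers:
    - name: Metal Plate
      role: electrode
      thickness_mm: 1.0
      sigma_S_per_m: 5.99e+7
      eps_r: 1.0
    - name: Air
      role: insulator
      thickness_mm: 10.0
      sigma_S_per_m: 1.0e-14
      eps_r: 1.005
    - name: Culture Medium
      role: medium
      thickness_mm: 7.0
      sigma_S_per_m: 1.5
      eps_r: 80.1
    - name: Polystyrene
      role: insulator
      thickness_mm: 3.0
      sigma_S_per_m: 6.7e-14
      eps_r: 2.5
    - name: Metal Plate
      role: electrode
      thickness_mm: 1.0
      sigma_S_per_m: 5.99e+7
      eps_r: 1.0
  waveform:
    type: sinusoid
    amplitude_V: 10.0
    frequency_Hz: 10.0
    phase_rad: 0.0
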