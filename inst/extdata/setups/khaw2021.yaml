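# Cylindrical equivalent; the surrounding 120 mm air sphere of the original
# 3D model is not part of the coaxial stack.
setup:
  id: khaw2021
  radius_mm: 15.0
  layers:
    - name: Electrode
      role: electrode
      thickness_mm: 1.75
      sigma_S_per_m: 5.99e+7
      eps_r: 1.0
    - name: Plastic
      role: insulator
      thickness_mm: 0.75
      sigma_S_per_m: 6.7e-14
      eps_r: 2.0
    - name: Culture Medium
      role: medium
      thickness_mm: 19.5
      sigma_S_per_m: 1.7
      eps_r: 80.0
    - name: Plastic
      role: insulator
      thickness_mm: 0.75
      sigma_S_per_m: 6.7e-14
      eps_r: 2.0
    - name: Electrode
      role: electrode
      thickness_mm: 1.75
      sigma_S_per_m: 5.99e+7
      eps_r: 1.0
  waveform:
    type: dc
    level_V: 14.2
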