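# Cylindrical equivalent of a single-well petri-dish rig; the petri wall
# thickness (1 mm) is a typical value, not reported by the original study.
setup:
  id: stephan2020
  radius_mm: 16.0
  layers:
    - name: Ti6Al4V Electrode
      role: electrode
      thickness_mm: 0.5
      sigma_S_per_m: 5.85e+5
      eps_r: 1.0
    - name: Polystyrene
      role: insulator
      thickness_mm: 1.0
      sigma_S_per_m: 6.7e-14
      eps_r: 2.5
    - name: Culture Medium
      role: medium
      thickness_mm: 32.0
      sigma_S_per_m: 1.6
      eps_r: 80.1
    - name: Polystyrene
      role: insulator
      thickness_mm: 1.0
      sigma_S_per_m: 6.7e-14
      eps_r: 2.5
    - name: Ti6Al4V Electrode
      role: electrode
      thickness_mm: 0.5
      sigma_S_per_m: 5.85e+5
      eps_r: 1.0
  waveform:
    type: sinusoid
    amplitude_V: 0.141
    frequency_Hz: 60.0e+3
    phase_rad: 0.0
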