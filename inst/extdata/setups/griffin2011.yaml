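# The original drive is a damped "degenerate wave" (160 mV pk-pk, 16 Hz)
# whose printed shape is not parameterised here; the waveform below is the
# slew-rate-equivalent stand-in sinusoid (22 Hz, 100 mV, the amplitude of the
# first positive deflection).  Users with a digitised capture can replace it
# with a pwl waveform.
setup:
  id: griffin2011
  radius_mm: 40.0
  layers:
    - name: High Grade Steel Electrode
      role: electrode
      thickness_mm: 1.0
      sigma_S_per_m: 5.99e+7
      eps_r: 1.0
    - name: Air
      role: insulator
      thickness_mm: 2.0
      sigma_S_per_m: 1.0e-14
      eps_r: 1.005
    - name: Culture Medium
      role: medium
      thickness_mm: 4.7
      sigma_S_per_m: 1.5
      eps_r: 80.1
    - name: Polystyrene
      role: insulator
      thickness_mm: 1.0
      sigma_S_per_m: 6.7e-14
      eps_r: 2.5
    - name: High Grade Steel Electrode
      role: electrode
      thickness_mm: 1.0
      sigma_S_per_m: 5.99e+7
      eps_r: 1.0
  waveform:
    type: sinusoid
    amplitude_V: 0.1
    frequency_Hz: 22.0
    phase_rad: 0.0
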