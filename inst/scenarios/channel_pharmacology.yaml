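# Curve-fitting stages reproducing the concentration-response and
# voltage-activation analyses on seeded synthetic data.
name: channel_pharmacology
seed: 1
stages:
  stim_dose_response:
    type: dose_response
    concentrations: [0.1, 1, 3, 10, 30, 100, 300]
    e_max: 100
    ec50: 9.8
    n_h: 1
    n_cells: 200
  activation_control:
    type: boltzmann
    v_half: -26.8
    q: 1.86
  activation_drug:
    type: boltzmann
    v_half: -44.3
    q: 2.01
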