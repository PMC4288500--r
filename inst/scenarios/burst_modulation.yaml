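# Three burst-model runs mimicking pharmacological activation of the
# M-type and Ca2+-activated K+ conductances: baseline, g_M doubled, and
# both g_M and g_KCa doubled.
name: burst_modulation
seed: 1
stages:
  baseline:
    type: simulate
    g_m_scale: 1
    g_kca_scale: 1
    duration: 3000
    dt: 0.001
  gm_doubled:
    type: simulate
    g_m_scale: 2
    g_kca_scale: 1
    duration: 3000
    dt: 0.001
  both_doubled:
    type: simulate
    g_m_scale: 2
    g_kca_scale: 2
    duration: 3000
    dt: 0.001
  m_current_fold:
    type: fold_change
    a: baseline
    b: both_doubled
    current: I_M
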