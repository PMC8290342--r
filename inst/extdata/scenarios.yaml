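# Synthetic-truth scenario presets, one per reported experimental cell.
# kf_true (mL/(U day)) seeds the generator; these are demonstration scenarios,
# not reconstructions of the study's raw measurements.
scenarios:
  - name: discrete_pk_12h_pooled
    method: discrete
    enzyme: ProteinaseK
    wa_hours: 12
    enzyme_conc: [0.01, 0.1]
    kf_true: 15
  - name: discrete_pk_12h_0.1
    method: discrete
    enzyme: ProteinaseK
    wa_hours: 12
    enzyme_conc: [0.1]
    kf_true: 13
  - name: discrete_pk_12h_0.01
    method: discrete
    enzyme: ProteinaseK
    wa_hours: 12
    enzyme_conc: [0.01]
    kf_true: 15
  - name: continuous_pk_12h_pooled
    method: continuous
    enzyme: ProteinaseK
    wa_hours: 12
    enzyme_conc: [0.1, 1]
    kf_true: 1.0
  - name: continuous_pk_12h_0.1
    method: continuous
    enzyme: ProteinaseK
    wa_hours: 12
    enzyme_conc: [0.1]
    kf_true: 2.2
  - name: continuous_pk_12h_1
    method: continuous
    enzyme: ProteinaseK
    wa_hours: 12
    enzyme_conc: [1]
    kf_true: 1.0
  - name: continuous_px_12h_1
    method: continuous
    enzyme: ProteaseXIV
    wa_hours: 12
    enzyme_conc: [1]
    kf_true: 0.2
  - name: continuous_pk_6h_0.1
    method: continuous
    enzyme: ProteinaseK
    wa_hours: 6
    enzyme_conc: [0.1]
    kf_true: 2.1
  - name: continuous_px_6h_1
    method: continuous
    enzyme: ProteaseXIV
    wa_hours: 6
    enzyme_conc: [1]
    kf_true: 0.2
  - name: continuous_pk_2h_0.1
    method: continuous
    enzyme: ProteinaseK
    wa_hours: 2
    enzyme_conc: [0.1]
    kf_true: 11
  - name: continuous_px_2h_1
    method: continuous
    enzyme: ProteaseXIV
    wa_hours: 2
    enzyme_conc: [1]
    kf_true: 1.4
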