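# Three-antibiotic parallel-design study configuration: meropenem,
# ceftazidime and ceftriaxone at clinically relevant unbound exposures.
drugs:
  - name: meropenem
    cmax_mg_L: 120
    half_life_h: 1.0
    dosing_interval_h: 8
  - name: ceftazidime
    cmax_mg_L: 120
    half_life_h: 2.5
    dosing_interval_h: 8
  - name: ceftriaxone
    cmax_mg_L: 30
    half_life_h: 8.0
    dosing_interval_h: 24
    doses_per_24h: 1
hardware:
  v_central_mL: 180
  flow_mL_min: 0.7
  infusion_min: 30
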