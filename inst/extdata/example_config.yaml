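# Reference lysimeter setup: 1.5 m silty column, nine-season rotation,
# one-time surface application of PFOA and PFOS on 2007-03-31, scenario II
# (NER formation) at the behavioural posterior medians.
# Units: mm (water), l (volumes), ug/l (concentrations), g (masses), d (time).
site:
  albedo: 0.11
  latitude: 51.3
  column_area: 1
  elevation_m: 200
soil:
  n_layers: 15
  thickness: 0.1
rotation:
  start_year: 2007
  rsmin_crops: 57
  rsmin_canola: 44
substances:
  - name: PFOA
    k_foc: 72          # ml/g
    freundlich_n: 0.88
    f_star: 1.1e-05
    scenario: II
    r_ner: 0.0047      # 1/d
    dispersivity_cm: 12
    applied_mass_g: 360
    application_date: 2007-03-31
    purity: 0.96
  - name: PFOS
    k_foc: 510
    freundlich_n: 0.75
    f_star: 9.6e-05
    scenario: II
    r_ner: 0.0013
    dispersivity_cm: 12
    applied_mass_g: 367.5
    application_date: 2007-03-31
    purity: 0.98
weather:
  synthetic:
    start: 2006-01-01  # one pre-application year of model warm-up
    years: 10
    seed: 42
seed: 1
output_dir: pfleach-output
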