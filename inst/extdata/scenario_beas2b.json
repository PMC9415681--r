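{
  "label": "beas2b-like",
  "mode": "simulate",
  "seed": 20,
  "tracer": "13C6",
  "f_unlabeled": 0.35,
  "f_direct": 0.60,
  "f_scrambled": 0.05,
  "p": 0.5,
  "glycogen_ug": 24.2,
  "pre_glucose_nmol": 29.1,
  "protein_mg": 0.61,
  "temperature_C": 110,
  "time_min": 10,
  "spike_nmol": 50,
  "nmr_visible_fraction": 0.85,
  "dss_mM": 0.5,
  "volume_uL": 50
}
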