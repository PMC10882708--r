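# Reference configuration for a T7 runoff IVT batch and its segmented-flow
# screening campaign. Transcript composition is a synthetic approximation of
# a codon-optimized GC-rich construct (the length is the real one; the
# per-base fractions are not published and are package defaults).
transcript:
  name: bnt-like
  n_mrna: 4284
  f: {A: 0.26, C: 0.28, G: 0.29, U: 0.17}
params:
  vmax: 0.358            # uM/min
  km: {A: 140.4, C: 71.5, G: 165.5, U: 101.5}   # apparent Km, uM
  se:
    vmax: 0.001
    km: {A: 2.9, C: 1.9, G: 6.4, U: 3.8}
ppiase:
  k_ppiase: 2.0e6        # uM/min per U/uL
  c_ppase: 0.002         # U/uL
  km_ppi: 50             # uM
reactor:
  tau: 135               # min
  dt: 6.6                # min
  horizon: 270           # min
  flow_ml_min: 0.2
factors:
  - {name: temp_C, low: 37, high: 40, unit: degC}
  - {name: urea_M, low: 0.4, high: 1.2, unit: M}
  - {name: additive_mg_ml, low: 0.1, high: 1, unit: mg/mL}
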