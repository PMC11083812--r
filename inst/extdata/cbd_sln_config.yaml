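# End-to-end configuration for the packaged CBD-SLN study.
factors:
  - {name: A, low: 1.5, high: 2.5, units: g}   # glyceryl monostearate
  - {name: B, low: 0.6, high: 1.0, units: g}   # polysorbate 80
  - {name: C, low: 10, high: 20, units: mg}    # methanolic CBD
responses:
  Y1: {goal: minimize, terms: auto, hard_max: 200}  # particle size, nm
  Y2: {goal: minimize, terms: auto}                 # polydispersity index
  Y3: {goal: maximize, terms: auto}                 # encapsulation efficiency, %
  Y4: {goal: maximize, terms: auto}                 # drug loading, %
alpha: 0.05
release: {Ve: 1, Vo: 200, m: 1}   # aliquot mL, vessel mL, drug in bag mg
thresholds: {pdi_max: 0.3, pdi_aggregation: 0.7, zeta_min: 30}
assay: {stimulated: stimulated}
seed: 1
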