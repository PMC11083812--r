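factors:
  - name: A        # glyceryl monostearate (lipid)
    low: 1.5
    high: 2.5
    units: g
  - name: B        # polysorbate 80 (surfactant)
    low: 0.6
    high: 1.0
    units: g
  - name: C        # methanolic CBD (drug)
    low: 10
    high: 20
    units: mg
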