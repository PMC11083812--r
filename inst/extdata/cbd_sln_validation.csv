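response,predicted,observed
Y1,119.36,123.40
Y2,0.1910,0.2099
Y3,95.33,95.16
Y4,2.35,2.36
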