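# Global null: all true effects zero, perfect commensurability (w = 0).
mu_E: [0, 0, 0, 0, 0, 0, 0]
mu_C: 0
sigma2: 0.3
R: 0.5
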