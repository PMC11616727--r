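# Consistently-effective borderline case: every true effect equals delta,
# identical outcome distributions across subtrials (perfect
# commensurability, all w = 0). Sizes filled from the solved design.
mu_E: [-0.4, -0.4, -0.4, -0.4, -0.4, -0.4, -0.4]
mu_C: 0
sigma2: 0.3
R: 0.5
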