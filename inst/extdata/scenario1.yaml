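# Divergent-effects scenario derived from the seven-subtype design: truth
# equals the assumed experimental-arm distributions. Sizes `n` are omitted
# on purpose; run_simulate() fills them from the solved borrowing design.
mu_E: [-0.489, 0.226, -0.181, 0.293, 0.329, -0.275, -0.136]
mu_C: 0
sigma2: [0.344569, 0.119025, 0.1444, 0.120409, 0.118336, 0.153664, 0.153664]
R: 0.5
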