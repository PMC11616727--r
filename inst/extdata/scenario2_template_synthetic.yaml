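# SYNTHETIC TEMPLATE - UNVERIFIED. A "consistently enhanced benefit"
# scenario of this shape is part of the published simulation study, but its
# exact configuration is not reproducible from the main text. Edit the
# means/variances to your case before use.
mu_E: [-0.50, -0.45, -0.48, -0.46, -0.47, -0.49, -0.45]
mu_C: 0
sigma2: [0.344569, 0.119025, 0.1444, 0.120409, 0.118336, 0.153664, 0.153664]
R: 0.5
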