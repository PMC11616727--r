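# Seven-subtype oncology basket design (relative change in tumor volume,
# lower = better, so delta < 0). Incommensurability derived from the
# Hellinger distance between the assumed experimental-arm outcome
# distributions.
sigma2: [0.344569, 0.119025, 0.1444, 0.120409, 0.118336, 0.153664, 0.153664]
delta: -0.40
eta: 0.95
zeta: 0.80
R: 0.5
s02: 100
m0: 0
c0: 0.05
distributions:
  mu: [-0.489, 0.226, -0.181, 0.293, 0.329, -0.275, -0.136]
  sigma: [0.587, 0.345, 0.380, 0.347, 0.344, 0.392, 0.392]
gamma_mixture: {a1: 1.1, b1: 1.1, a2: 54, b2: 3}
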