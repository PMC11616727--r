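# Three-subtrial chronic-disease basket design (CANTAB cognitive score,
# higher = better): delta = +2.3, 90% futility threshold for subtrial 1.
sigma2: [6.177, 5.134, 5.134]
delta: 2.3
eta: 0.95
zeta: [0.90, 0.80, 0.80]
R: [0.5, 0.6, 0.6]
s02: 100
m0: 0
c0: 0.05
w_matrix:
  - [0.0, 0.239, 0.417]
  - [0.239, 0.0, 0.145]
  - [0.417, 0.145, 0.0]
gamma_mixture: {a1: 1.1, b1: 1.1, a2: 54, b2: 3}
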