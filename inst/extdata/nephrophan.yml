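membrane:
  Lp: 4.9e-12
  sigma1: 0.068
  sigma2: 0.025
  omega11: 8.0e-10
  omega12: 8.1e-14
  omega21: 1.63e-12
  omega22: 1.43e-09
environment:
  temperature: 298.15
  R_gas: 8.314
  g: 9.81
  nu: 1.063e-06
  rho_ref: 998.3
  drho_dC1: 0.06
  drho_dC2: -0.0095
  D11: 6.9e-10
  D12: .na.real
  D21: .na.real
  D22: .na.real
baths:
  C1h: 33.44
  C1l: 1.0
  C2h: 201.0
  C2l: 1.0
  dP: 0.0
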