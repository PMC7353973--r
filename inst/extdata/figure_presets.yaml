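# Shipped parameter presets for the package's standard scenarios.
# All rates in 1/time, densities in resource/consumer units per patch.
fig1:
  scenario: vary_lambda_p0
  C_T: 15.0
  model: {r_H: 2.0, r_L: 1.0, K_H: 100.0, K_L: 50.0, alpha: 0.05, c: 0.05,
          mu: 0.1, beta: 1.0, lam: 0.0, p: 0}
  levels: [1.0]          # mobility; the p = 0 fixed point does not depend on it
fig2_solid:
  scenario: vary_lambda_p0
  C_T: 15.0
  model: {r_H: 2.0, r_L: 1.0, K_H: 100.0, K_L: 50.0, alpha: 0.05, c: 0.05,
          mu: 0.1, beta: 1.0, lam: 0.0, p: 0, gamma: 1.0}
  levels: [1.0]
fig2_dashed:
  scenario: vary_lambda_p0
  C_T: 15.0
  model: {r_H: 2.0, r_L: 1.0, K_H: 50.0, K_L: 50.0, alpha: 0.05, c: 0.05,
          mu: 0.1, beta: 1.0, lam: 0.0, p: 0, gamma: 1.0}
  levels: [1.0]
fig2_dotted:
  scenario: vary_lambda_p0
  C_T: 15.0
  model: {r_H: 1.0, r_L: 1.0, K_H: 100.0, K_L: 50.0, alpha: 0.05, c: 0.05,
          mu: 0.1, beta: 1.0, lam: 0.0, p: 0, gamma: 1.0}
  levels: [1.0]
fig3:
  scenario: vary_beta_fixed_lambda_p1
  model: {r_H: 2.0, r_L: 1.0, K_H: 100.0, K_L: 50.0, alpha: 0.05, c: 0.05,
          mu: 0.1, beta: 0.0, lam: 0.1, p: 1}
  levels: [0.1, 10.0, 1000.0]   # fitness sensitivity
fig4:
  scenario: vary_lambda_fixed_beta_p1
  model: {r_H: 2.0, r_L: 1.0, K_H: 100.0, K_L: 50.0, alpha: 0.05, c: 0.05,
          mu: 0.1, beta: 0.01, lam: 0.0, p: 1}
  levels: [0.01, 0.1, 1.0]      # mobility
fig5:
  scenario: covary_p1
  model: {r_H: 2.0, r_L: 1.0, K_H: 100.0, K_L: 50.0, alpha: 0.05, c: 0.05,
          mu: 0.1, beta: 0.0, lam: 0.0, p: 1}
  levels: [0.1, 1.0, 10.0]      # gamma = lam / beta
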