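# Shared fixtures: the captioned parameter sets, built in code.

base_patches <- function(r_H = 2, r_L = 1, K_H = 100, K_L = 50) {
  list(high = patch_params(r_H, K_H), low = patch_params(r_L, K_L))
}

fig1_params <- function(beta = 1, lam = 0) {
  p <- base_patches()
  model_params(p$high, p$low, alpha = 0.05, c = 0.05, mu = 0.1,
               beta = beta, lam = lam, p = 0)
}

fig3_params <- function(beta = 0, lam = 0.1) {
  p <- base_patches()
  model_params(p$high, p$low, alpha = 0.05, c = 0.05, mu = 0.1,
               beta = beta, lam = lam, p = 1)
}

# No-movement closed forms for the demography-on parameter set, evaluated by
# hand from the printed parameters: R* = mu/(c*alpha) = 40,
# C_H* = (2/0.05)(1 - 40/100) = 24, C_L* = (1/0.05)(1 - 40/50) = 4.
fig3_closed_form <- c(R_H = 40, R_L = 40, C_H = 24, C_L = 4)

small_lambda_grid <- c(0, 0.1, 0.5, 1, 2, 5, 10, 20)
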