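test_that("no-movement closed forms match hand-evaluated values", {
  eq <- equilibrium_no_movement(fig3_params(beta = 0))
  expect_equal(unname(eq$state), unname(fig3_closed_form), tolerance = 1e-12)
  expect_equal(unname(eq$fitness), c(0, 0), tolerance = 1e-14)
  expect_lt(eq$residual, 1e-12)
  expect_true(eq$stable)
  expect_identical(eq$method, "closed_form_no_movement")
})

test_that("no-movement equilibrium is symmetric for identical patches", {
  pr <- model_params(patch_params(2, 100), patch_params(2, 100),
                     alpha = 0.05, c = 0.05, mu = 0.1, beta = 0, p = 1)
  eq <- equilibrium_no_movement(pr)
  expect_equal(eq$state[["C_H"]], eq$state[["C_L"]])
})

test_that("no-movement closed form enforces its preconditions", {
  expect_error(equilibrium_no_movement(fig3_params(beta = 1)), "beta")
  expect_error(equilibrium_no_movement(fig1_params()), "p = 1")
  # mu/(c*alpha) = 40 >= K_L = 30: consumer cannot persist in the low patch
  pr <- suppressWarnings(
    model_params(patch_params(2, 100), patch_params(1, 30),
                 alpha = 0.05, c = 0.05, mu = 0.1, beta = 0, p = 1))
  expect_error(equilibrium_no_movement(pr), "persist")
})

test_that("zero fitness sensitivity splits the consumers equally", {
  eq <- equilibrium_no_demography(fig1_params(lam = 0), conserved_total(15))
  expect_equal(eq$state[["C_H"]], 15, tolerance = 1e-12)
  expect_equal(eq$state[["C_L"]], 15, tolerance = 1e-12)
  # resources on their nullclines at C = 15: 100(1 - 0.75/2), 50(1 - 0.75)
  expect_equal(eq$state[["R_H"]], 62.5, tolerance = 1e-10)
  expect_equal(eq$state[["R_L"]], 12.5, tolerance = 1e-10)
  expect_true(eq$stable)
  expect_lt(eq$residual, 1e-8)
})

test_that("high fitness sensitivity drives the system to an IFD", {
  eq4 <- equilibrium_no_demography(fig1_params(lam = 1e4), conserved_total(15))
  expect_lt(abs(eq4$fitness[["w_H"]] - eq4$fitness[["w_L"]]), 1e-4)
  # the implicit relation ties the resource gap to ln(C_H/C_L)/(2 lam c alpha),
  # so the gap shrinks like 1/lam; at lam = 1e6 it is below 1e-3
  eq6 <- equilibrium_no_demography(fig1_params(lam = 1e6), conserved_total(15))
  expect_lt(abs(eq6$state[["R_H"]] - eq6$state[["R_L"]]), 1e-3)
  expect_lt(abs(eq6$state[["R_H"]] - eq6$state[["R_L"]]),
            abs(eq4$state[["R_H"]] - eq4$state[["R_L"]]))
})

test_that("mobility does not move the no-demography fixed point", {
  states <- lapply(c(0.1, 1, 10), function(b)
    equilibrium_no_demography(fig1_params(beta = b, lam = 2),
                              conserved_total(15))$state)
  expect_equal(states[[1]], states[[2]], tolerance = 1e-8)
  expect_equal(states[[2]], states[[3]], tolerance = 1e-8)
})

test_that("the flux-balance identity holds along a sensitivity grid", {
  pr <- fig1_params()
  for (lam in small_lambda_grid) {
    pr$lam <- lam
    eq <- equilibrium_no_demography(pr, conserved_total(15))
    st <- eq$state
    lhs <- log(st[["C_L"]] / st[["C_H"]]) +
      2 * lam * pr$c * pr$alpha * (st[["R_H"]] - st[["R_L"]])
    expect_lt(abs(lhs), 1e-8)
    expect_lt(eq$residual, 1e-8)
    expect_true(eq$stable)
  }
})

test_that("numeric root-finding agrees with both specialised solvers", {
  # demography on, no movement: independent Newton route hits the closed form
  eq_num <- equilibrium_numeric(fig3_params(beta = 0))
  expect_identical(eq_num$method, "numeric_root")
  expect_equal(unname(eq_num$state), unname(fig3_closed_form),
               tolerance = 1e-8)
  # demography off: matches the implicit flux-balance solve (uniqueness)
  pr0 <- fig1_params(beta = 1, lam = 2)
  eq_imp <- equilibrium_no_demography(pr0, conserved_total(15))
  eq_num0 <- equilibrium_numeric(pr0, system_state(50, 25, 15, 15))
  expect_equal(unname(eq_num0$state), unname(eq_imp$state), tolerance = 1e-8)
})

test_that("numeric root matches the long-integration endpoint (p = 1)", {
  pr <- fig3_params(beta = 1, lam = 10)
  eq_num <- equilibrium_numeric(pr)
  eq_int <- equilibrium_integrate(pr)
  expect_equal(unname(eq_num$state), unname(eq_int$state), tolerance = 1e-6)
  expect_lt(eq_num$residual, 1e-10)
  expect_true(eq_num$stable)
})

test_that("numeric root avoids the unstable boundary equilibrium", {
  # strong mixing with weak sensitivity: the naive Newton basin contains a
  # resource-extinct saddle; the solver must land on the interior attractor
  pr <- fig3_params(beta = 1, lam = 0.01)
  eq <- equilibrium_numeric(pr)
  expect_gt(min(eq$state), 1)
  expect_true(eq$stable)
  expect_error(equilibrium_numeric(pr, guess = c(-1, 10, 5, 5)), "positive")
})

test_that("finite-difference Jacobian matches logistic linearizations", {
  pr <- fig3_params(beta = 0.4, lam = 2)
  # at extinction the resource rows are diagonal with the intrinsic rates
  J0 <- jacobian(c(0, 0, 0, 0), pr)
  expect_equal(J0[1, 1], 2, tolerance = 1e-6)
  expect_equal(J0[2, 2], 1, tolerance = 1e-6)
  expect_true(max(Re(eigen(J0, only.values = TRUE)$values)) > 0)
  # consumer-free carrying-capacity state: resource diagonal is -r_i
  JK <- jacobian(c(100, 50, 0, 0), pr)
  expect_equal(JK[1, 1], -2, tolerance = 1e-5)
  expect_equal(JK[2, 2], -1, tolerance = 1e-5)
  # general state: resource self-derivative r(1 - 2R/K) - alpha C
  st <- c(40, 20, 9, 3)
  J <- jacobian(st, pr)
  expect_equal(J[1, 1], 2 * (1 - 2 * 40 / 100) - 0.05 * 9, tolerance = 1e-5)
  expect_equal(J[2, 2], 1 * (1 - 2 * 20 / 50) - 0.05 * 3, tolerance = 1e-5)
})

test_that("flux balance holds at equilibrium and flags perturbed states", {
  pr <- fig1_params(beta = 1, lam = 0)
  eq <- equilibrium_no_demography(pr, conserved_total(15))
  res <- flux_balance_check(eq, pr)
  expect_lt(res, 1e-8 * pr$beta * 15)
  expect_true(attr(res, "ok"))
  pr2 <- fig1_params(beta = 1, lam = 3)
  eq2 <- equilibrium_no_demography(pr2, conserved_total(15))
  expect_true(attr(flux_balance_check(eq2, pr2), "ok"))
  # inflate C_H by 10%: migration out of the high patch must exceed inflow
  bad <- eq2
  bad$state[["C_H"]] <- bad$state[["C_H"]] * 1.1
  res_bad <- flux_balance_check(bad, pr2)
  expect_gt(res_bad, 0)
  expect_false(attr(res_bad, "ok"))
})

test_that("auto dispatch picks the cheapest applicable method", {
  eq1 <- equilibrium_auto(fig3_params(beta = 0))
  expect_identical(eq1$method, "closed_form_no_movement")
  eq2 <- equilibrium_auto(fig1_params(lam = 1), total = conserved_total(15))
  expect_identical(eq2$method, "implicit_no_demography")
  eq3 <- equilibrium_auto(fig3_params(beta = 0.5, lam = 5))
  expect_identical(eq3$method, "numeric_root")
  expect_error(equilibrium_auto(fig1_params()), "conserved_total")
})

test_that("equilibrium records flatten to the canonical row", {
  eq <- equilibrium_no_movement(fig3_params(beta = 0))
  row <- as.data.frame(eq)
  expect_named(row, c("R_H", "R_L", "C_H", "C_L", "w_H", "w_L",
                      "residual", "stable", "method"))
  expect_identical(row$stable, TRUE)
})
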