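test_that("shipped presets carry the captioned parameters", {
  ps <- figure_presets()
  expect_setequal(names(ps), c("fig1", "fig2_solid", "fig2_dashed",
                               "fig2_dotted", "fig3", "fig4", "fig5"))
  expect_equal(ps$fig1$total$C_T, 15)
  expect_identical(ps$fig1$base_params$p, 0L)
  m <- params_to_list(ps$fig1$base_params)
  expect_equal(m[c("r_H", "r_L", "K_H", "K_L", "c", "alpha", "mu")],
               list(r_H = 2, r_L = 1, K_H = 100, K_L = 50, c = 0.05,
                    alpha = 0.05, mu = 0.1))
  expect_equal(ps$fig3$fixed_levels, c(0.1, 10, 1000))
  expect_equal(ps$fig4$fixed_levels, c(0.01, 0.1, 1))
  expect_equal(ps$fig5$fixed_levels, c(0.1, 1, 10))
  expect_identical(ps$fig3$base_params$p, 1L)
  # the dashed regional-trend variant lowers only K_H
  expect_equal(params_to_list(ps$fig2_dashed$base_params)$K_H, 50)
  expect_equal(params_to_list(ps$fig2_dotted$base_params)$r_H, 1)
  expect_error(figure_presets("fig9"), "unknown preset")
})

test_that("sweep configs police scenario/parameter consistency", {
  ps <- figure_presets()
  expect_error(sweep_config("vary_lambda_p0", ps$fig3$base_params,
                            c(0, 1), 1, conserved_total(15)), "p = 0")
  expect_error(sweep_config("covary_p1", ps$fig1$base_params, c(0.1, 1), 1),
               "p = 1")
  expect_error(sweep_config("vary_lambda_p0", ps$fig1$base_params,
                            c(0, 1), 1), "C_T")
  expect_error(sweep_config("covary_p1", ps$fig3$base_params,
                            c(1, 0.5), 1), "increasing")
})

test_that("no-demography sweep starts at the equal split and conserves C_T", {
  cfg <- figure_presets("fig1")
  cfg$grid <- small_lambda_grid
  tab <- run_sweep(cfg)
  expect_equal(nrow(tab), length(small_lambda_grid))
  expect_equal(tab$C_H[1], 15, tolerance = 1e-10)
  expect_equal(tab$C_L[1], 15, tolerance = 1e-10)
  expect_equal(tab$mean_C, rep(15, nrow(tab)), tolerance = 1e-10)
  expect_true(all(tab$stable))
  # consumers concentrate and the resource gap closes as lam grows
  expect_true(all(diff(tab$C_H) >= -1e-10))
  expect_true(all(diff(abs(tab$R_H - tab$R_L)) <= 1e-10))
})

test_that("mobility sweep rows at beta = 0 equal the closed forms", {
  cfg <- figure_presets("fig3")
  cfg$grid <- c(0, 0.5, 2)
  tab <- run_sweep(cfg)
  expect_equal(nrow(tab), 9L)
  # ordered by (level, grid value)
  expect_equal(tab$level_value, rep(c(0.1, 10, 1000), each = 3))
  first <- tab[tab$swept_value == 0, ]
  for (i in seq_len(nrow(first)))
    expect_equal(unname(unlist(first[i, c("R_H", "R_L", "C_H", "C_L")])),
                 unname(fig3_closed_form), tolerance = 1e-10)
})

test_that("sweep errors identify the offending coordinate", {
  cfg <- figure_presets("fig1")
  cfg$grid <- c(0, 1)
  cfg$total <- conserved_total(45)  # drives R_L* negative: outside regime
  expect_error(run_sweep(cfg), "beta = 1, lam = ")
})

test_that("regional resource trend follows the r/K comparison", {
  ps <- figure_presets()
  expect_identical(regional_resource_trend(ps$fig2_solid$base_params),
                   "constant")
  expect_identical(regional_resource_trend(ps$fig2_dashed$base_params),
                   "increasing")
  expect_identical(regional_resource_trend(ps$fig2_dotted$base_params),
                   "decreasing")
  expect_error(regional_resource_trend(ps$fig3$base_params), "p = 0")
  # and the prediction matches the mean_R column of an actual sweep
  for (nm in c("fig2_solid", "fig2_dashed", "fig2_dotted")) {
    cfg <- ps[[nm]]
    cfg$grid <- small_lambda_grid
    mean_R <- run_sweep(cfg, cross_check_seed = NULL)$mean_R
    trend <- regional_resource_trend(cfg$base_params)
    if (trend == "constant") expect_lt(diff(range(mean_R)), 1e-6)
    if (trend == "increasing") expect_true(all(diff(mean_R) > 0))
    if (trend == "decreasing") expect_true(all(diff(mean_R) < 0))
  }
})

test_that("time to equilibrium is zero at the equilibrium itself", {
  pr <- fig1_params(beta = 1, lam = 1)
  eq <- equilibrium_no_demography(pr, conserved_total(15))
  expect_equal(time_to_equilibrium(pr, init = eq$state), 0)
})

test_that("greater mobility shortens the approach to equilibrium", {
  times <- vapply(c(0.1, 1, 10), function(b)
    time_to_equilibrium(fig1_params(beta = b, lam = 1)), numeric(1))
  expect_true(all(is.finite(times)))
  expect_true(all(diff(times) < 0))
})

test_that("with lam = 0 the consumer gap decays at exactly rate 2 beta", {
  # the consumer subsystem decouples: d(C_H - C_L)/dt = -2 beta (C_H - C_L)
  for (b in c(0.25, 0.5)) {
    pr <- fig1_params(beta = b, lam = 0)
    traj <- simulate_model(pr, system_state(50, 25, 27, 3), horizon = 8,
                           sample_interval = 1)
    gap <- traj$C_H - traj$C_L
    expect_equal(gap, 24 * exp(-2 * b * traj$t), tolerance = 1e-7)
  }
})

test_that("disparity profiles locate the covarying-movement turning point", {
  cfg <- figure_presets("fig5")
  cfg$fixed_levels <- 10
  cfg$grid <- c(0.2, 0.5, 1, 2, 4, 7, 10)
  tab <- run_sweep(cfg, cross_check_seed = NULL)
  prof <- disparity_profile(tab, cfg)[["10"]]
  # unimodal: falls from the immobile value, then recovers
  no_move <- fig3_closed_form[["C_H"]] - fig3_closed_form[["C_L"]]
  expect_lt(min(prof$dC), no_move)
  expect_gt(prof$dC[length(prof$dC)], min(prof$dC))
  # refined interior minimum sits at low mobility, below the grid spacing
  expect_lt(prof$dC_min_at, 2)
  expect_gt(prof$dC_min_at, 0)
  expect_lte(prof$dC_min, min(prof$dC) + 1e-8)
  # consumers and resources turn in opposite directions
  expect_gt(prof$dR_max, prof$dR[length(prof$dR)])
})

test_that("consumer disparity shrinks with mobility and grows with sensitivity", {
  cfg3 <- figure_presets("fig3")
  cfg3$grid <- c(0, 0.25, 1, 4, 10)
  tab3 <- run_sweep(cfg3, cross_check_seed = NULL)
  for (p in disparity_profile(tab3))
    expect_true(all(diff(p$dC) <= 1e-9))
  cfg4 <- figure_presets("fig4")
  cfg4$grid <- c(0, 0.1, 1, 5, 20)
  tab4 <- run_sweep(cfg4, cross_check_seed = NULL)
  for (p in disparity_profile(tab4))
    expect_true(all(diff(p$dC) >= -1e-9))
})
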