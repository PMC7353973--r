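.scenarios <- c("vary_lambda_p0", "vary_beta_fixed_lambda_p1",
                "vary_lambda_fixed_beta_p1", "covary_p1")

# level_name / swept_name per scenario
.scenario_roles <- list(
  vary_lambda_p0            = c(level = "beta",  swept = "lam"),
  vary_beta_fixed_lambda_p1 = c(level = "lam",   swept = "beta"),
  vary_lambda_fixed_beta_p1 = c(level = "beta",  swept = "lam"),
  covary_p1                 = c(level = "gamma", swept = "beta"))

#' Configuration of a parameter sweep
#'
#' A sweep varies one movement parameter over \code{grid} while holding the
#' other at each value in \code{fixed_levels}, under one of four scenarios:
#' \describe{
#'   \item{vary_lambda_p0}{demography off; sweep fitness sensitivity
#'     \code{lam} at fixed mobility level(s). Requires \code{total}.}
#'   \item{vary_beta_fixed_lambda_p1}{demography on; sweep mobility
#'     \code{beta} at fixed \code{lam} level(s).}
#'   \item{vary_lambda_fixed_beta_p1}{demography on; sweep \code{lam} at
#'     fixed \code{beta} level(s).}
#'   \item{covary_p1}{demography on; sweep \code{beta} with
#'     \code{lam = gamma * beta} at fixed \code{gamma} level(s).}
#' }
#'
#' @param scenario One of the four scenario names.
#' @param base_params A \code{\link{model_params}} object (its \code{p} must
#'   match the scenario).
#' @param grid Strictly increasing numeric vector of swept values, all >= 0.
#' @param fixed_levels Nonempty numeric vector of levels for the non-swept
#'   movement parameter.
#' @param total A \code{\link{conserved_total}}; required for
#'   \code{vary_lambda_p0}, ignored otherwise.
#' @return An object of class \code{sweep_config}.
#' @export
sweep_config <- function(scenario, base_params, grid, fixed_levels,
                         total = NULL) {
  scenario <- match.arg(scenario, .scenarios)
  stopifnot(inherits(base_params, "model_params"), is.numeric(grid),
            is.numeric(fixed_levels), length(fixed_levels) >= 1L)
  if (length(grid) < 1L || any(grid < 0) || any(diff(grid) <= 0))
    stop("`grid` must be strictly increasing with all values >= 0")
  need_p <- if (scenario == "vary_lambda_p0") 0L else 1L
  if (base_params$p != need_p)
    stop("scenario '", scenario, "' requires p = ", need_p,
         "; base_params has p = ", base_params$p)
  if (scenario == "vary_lambda_p0") {
    if (is.null(total)) stop("scenario 'vary_lambda_p0' requires `total` (C_T)")
    stopifnot(inherits(total, "conserved_total"))
    if (any(fixed_levels <= 0))
      stop("mobility levels must be > 0 for the p = 0 scenario")
  }
  structure(list(scenario = scenario, base_params = base_params,
                 grid = as.numeric(grid),
                 fixed_levels = as.numeric(fixed_levels), total = total),
            class = "sweep_config")
}

# Build model parameters for one (level, swept value) coordinate.
.sweep_params <- function(config, level, value) {
  pr <- config$base_params
  role <- .scenario_roles[[config$scenario]]
  if (config$scenario == "covary_p1")
    return(apply_covary(pr, covary_rule(level), value))
  pr[[role[["level"]]]] <- level
  pr[[role[["swept"]]]] <- value
  pr
}

# Equilibrium at one sweep coordinate by the cheapest valid method.
.sweep_point <- function(config, level, value, guess = NULL) {
  pr <- .sweep_params(config, level, value)
  if (pr$p == 0) return(equilibrium_no_demography(pr, config$total))
  if (pr$beta == 0) return(equilibrium_no_movement(pr))
  equilibrium_numeric(pr, guess)
}

#' Run a parameter sweep of equilibria
#'
#' For each fixed level and each grid value, computes the equilibrium by the
#' cheapest valid method (implicit flux-balance solve for p = 0; closed form
#' at beta = 0; otherwise numeric root-finding, warm-started by continuation
#' from the previous grid point) and emits one tidy row. A random 10\% of
#' rows (at least one per level; fixed seed, default 20200247, restored on
#' exit) is cross-checked against the independent long-integration endpoint;
#' disagreement beyond 1e-6 aborts the sweep.
#'
#' @param config A \code{\link{sweep_config}}.
#' @param cross_check_seed Seed for the cross-check subsample; set to
#'   \code{NULL} to skip cross-checking.
#' @return A data frame (one row per (level, grid value), ordered by level
#'   then grid) with columns \code{scenario, level_name, level_value,
#'   swept_name, swept_value, R_H, R_L, C_H, C_L, w_H, w_L, mean_C, mean_R,
#'   stable, residual}.
#' @examples
#' \donttest{
#' cfg <- figure_presets("fig1")
#' cfg$grid <- c(0, 0.5, 2, 8)
#' run_sweep(cfg)
#' }
#' @export
run_sweep <- function(config, cross_check_seed = 20200247) {
  stopifnot(inherits(config, "sweep_config"))
  role <- .scenario_roles[[config$scenario]]
  rows <- vector("list", length(config$fixed_levels) * length(config$grid))
  k <- 0L
  for (lev in config$fixed_levels) {
    guess <- NULL
    for (val in config$grid) {
      eq <- tryCatch(.sweep_point(config, lev, val, guess),
                     error = function(e)
                       stop("sweep failed at ", role[["level"]], " = ", lev,
                            ", ", role[["swept"]], " = ", val, ": ",
                            conditionMessage(e)))
      guess <- pmax(eq$state, 1e-8)  # continuation for the next grid point
      k <- k + 1L
      rows[[k]] <- data.frame(
        scenario = config$scenario,
        level_name = role[["level"]], level_value = lev,
        swept_name = role[["swept"]], swept_value = val,
        R_H = eq$state[["R_H"]], R_L = eq$state[["R_L"]],
        C_H = eq$state[["C_H"]], C_L = eq$state[["C_L"]],
        w_H = eq$fitness[["w_H"]], w_L = eq$fitness[["w_L"]],
        mean_C = (eq$state[["C_H"]] + eq$state[["C_L"]]) / 2,
        mean_R = (eq$state[["R_H"]] + eq$state[["R_L"]]) / 2,
        stable = eq$stable, residual = eq$residual,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(cross_check_seed)) .cross_check_sweep(config, tab, cross_check_seed)
  tab
}

# Cross-check a random subsample of sweep rows against integration endpoints.
.cross_check_sweep <- function(config, tab, seed, frac = 0.1, tol = 1e-6) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  n_pick <- max(1L, ceiling(frac * nrow(tab)))
  idx <- sort(sample.int(nrow(tab), n_pick))
  for (i in idx) {
    pr <- .sweep_params(config, tab$level_value[i], tab$swept_value[i])
    init <- if (pr$p == 0) default_guess(pr, config$total) else default_guess(pr)
    ref <- equilibrium_integrate(pr, init)
    got <- c(tab$R_H[i], tab$R_L[i], tab$C_H[i], tab$C_L[i])
    err <- max(abs(got - ref$state) / pmax(1, abs(ref$state)))
    if (err > tol)
      stop("sweep cross-check failed at row ", i, " (",
           tab$level_name[i], " = ", tab$level_value[i], ", ",
           tab$swept_name[i], " = ", tab$swept_value[i],
           "): relative discrepancy ", signif(err, 3),
           " vs integration endpoint")
  }
  invisible(TRUE)
}

#' Direction of the regional resource response to fitness sensitivity
#'
#' Without consumer demography, sweeping fitness sensitivity moves consumers
#' from the low- into the high-quality patch. Whether the regional (mean)
#' resource density rises, falls or stays put is decided entirely by the
#' between-patch comparison of the density-dependent mortality coefficient
#' r/K of the resources: equal ratios leave the mean invariant; a larger
#' ratio in the high-quality patch means consumers relocating there relieve
#' proportionally more intraspecific competition, so the mean rises; a
#' smaller ratio means it falls.
#'
#' @param base_params A \code{\link{model_params}} with \code{p = 0}.
#' @param rel_tol Relative tolerance for calling the two ratios equal.
#' @return One of \code{"constant"}, \code{"increasing"},
#'   \code{"decreasing"}.
#' @export
regional_resource_trend <- function(base_params, rel_tol = 1e-12) {
  stopifnot(inherits(base_params, "model_params"))
  if (base_params$p != 0)
    stop("regional resource trend is a p = 0 result; got p = ",
         base_params$p)
  hi <- base_params$high$r / base_params$high$K
  lo <- base_params$low$r / base_params$low$K
  if (abs(hi - lo) <= rel_tol * max(hi, lo)) "constant"
  else if (hi > lo) "increasing"
  else "decreasing"
}

#' Time for a trajectory to reach the equilibrium
#'
#' Integrates from \code{init} (demography off) and returns the first time
#' at which the relative max-norm distance to the known equilibrium drops
#' below \code{epsilon} and stays below it through the horizon; \code{Inf}
#' if the horizon is reached first. Mobility does not move the p = 0 fixed
#' point, but it does set the pace: greater mobility means faster
#' convergence.
#'
#' @param params A \code{\link{model_params}} with \code{p = 0},
#'   \code{beta > 0}.
#' @param init Initial state; default puts resources at K/2 and splits the
#'   consumers 90/10 (a strongly unequal split, so convergence is
#'   nondegenerate): \code{C_H = 1.8 C_T, C_L = 0.2 C_T}.
#' @param epsilon Relative distance threshold in (0, 1); default 1e-3.
#' @param total A \code{\link{conserved_total}}; default C_T = 15, or
#'   inferred from \code{init} when that is given.
#' @param horizon Integration horizon (default 5000).
#' @return Time (model time units); 0 if \code{init} already lies within
#'   \code{epsilon} of the equilibrium.
#' @export
time_to_equilibrium <- function(params, init = NULL, epsilon = 1e-3,
                                total = NULL, horizon = 5000) {
  stopifnot(inherits(params, "model_params"))
  if (params$p != 0)
    stop("time_to_equilibrium is defined for the p = 0 setting")
  stopifnot(epsilon > 0, epsilon < 1)
  if (is.null(init)) {
    C_T <- if (is.null(total)) 15 else total$C_T
    init <- system_state(params$high$K / 2, params$low$K / 2,
                         1.8 * C_T, 0.2 * C_T)
  } else {
    init <- as_state(as.numeric(init))
    C_T <- (init[["C_H"]] + init[["C_L"]]) / 2
  }
  eq <- equilibrium_no_demography(params, conserved_total(C_T))
  scale <- max(abs(eq$state))
  # dense early sampling so fast (high-mobility) convergence is resolved
  times <- sort(unique(c(seq(0, min(100, horizon), by = 0.01),
                         seq(0, horizon, by = min(0.5, horizon / 10)))))
  traj <- simulate_model(params, init, times = times)
  dist <- apply(abs(t(as.matrix(traj[, .state_names])) - eq$state),
                2L, max) / scale
  if (dist[length(dist)] >= epsilon) return(Inf)
  above <- which(dist >= epsilon)
  if (length(above) == 0L) return(0)
  traj$t[above[length(above)] + 1L]
}

#' Between-patch disparity profiles of a sweep table
#'
#' For each fixed level in a \code{\link{run_sweep}} table, extracts the
#' consumer disparity \code{C_H - C_L} and resource disparity
#' \code{R_H - R_L} along the swept grid, and locates each series' extremum
#' (the minimum of the consumer disparity and the maximum of the resource
#' disparity — the turning points of the unimodal covarying-movement
#' pattern). When \code{config} is supplied and the extremum is interior to
#' the swept domain, its location is refined by golden-section search on the
#' continuous equilibrium map rather than left on the grid.
#'
#' @param table A data frame from \code{\link{run_sweep}}.
#' @param config The \code{\link{sweep_config}} that produced it (optional;
#'   enables continuous refinement).
#' @param refine_tol Tolerance of the golden-section refinement.
#' @return A named list with one entry per level: a list with the grid
#'   (\code{swept}), the two series (\code{dC}, \code{dR}), and the refined
#'   extremum locations and values (\code{dC_min_at}, \code{dC_min},
#'   \code{dR_max_at}, \code{dR_max}).
#' @export
disparity_profile <- function(table, config = NULL, refine_tol = 1e-4) {
  stopifnot(is.data.frame(table),
            all(c("level_value", "swept_value", "C_H", "C_L") %in% names(table)))
  out <- list()
  for (lev in unique(table$level_value)) {
    sub <- table[table$level_value == lev, ]
    sub <- sub[order(sub$swept_value), ]
    dC <- sub$C_H - sub$C_L
    dR <- sub$R_H - sub$R_L
    grid <- sub$swept_value
    ext_dC <- .locate_extremum(grid, dC, minimum = TRUE, config, lev, refine_tol)
    ext_dR <- .locate_extremum(grid, dR, minimum = FALSE, config, lev, refine_tol)
    out[[as.character(lev)]] <- list(
      level = lev, swept = grid, dC = dC, dR = dR,
      dC_min_at = ext_dC$at, dC_min = ext_dC$value,
      dR_max_at = ext_dR$at, dR_max = ext_dR$value)
  }
  out
}

# Discrete extremum with optional golden-section refinement on the
# continuous equilibrium map. The swept domain is treated as open below the
# first grid point whenever that point is positive (a (0, b] grid), so an
# extremum sitting on the first grid point still gets an interior bracket.
.locate_extremum <- function(grid, series, minimum, config, level, tol) {
  n <- length(grid)
  i <- if (minimum) which.min(series) else which.max(series)
  at <- grid[i]; val <- series[i]
  interior <- (i < n) && (i > 1L || grid[1L] > 0)
  if (is.null(config) || !interior || n < 3L)
    return(list(at = at, value = val, interior = interior))
  lo <- if (i > 1L) grid[i - 1L] else max(grid[1L] / 100, 1e-6)
  hi <- grid[i + 1L]
  f <- function(v) {
    st <- .sweep_point(config, level, v)$state
    d <- if (minimum) st[["C_H"]] - st[["C_L"]] else st[["R_H"]] - st[["R_L"]]
    if (minimum) d else -d
  }
  opt <- stats::optimize(f, lower = lo, upper = hi, tol = tol)
  list(at = opt$minimum,
       value = if (minimum) opt$objective else -opt$objective,
       interior = TRUE)
}
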