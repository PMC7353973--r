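#' System state: the four densities
#'
#' @param R_H,R_L Resource densities in the high- and low-quality patch.
#' @param C_H,C_L Consumer densities in the high- and low-quality patch.
#' @return A named numeric vector \code{c(R_H, R_L, C_H, C_L)}.
#' @examples
#' system_state(50, 25, 10, 5)
#' @export
system_state <- function(R_H, R_L, C_H, C_L) {
  x <- c(R_H = as.numeric(R_H), R_L = as.numeric(R_L),
         C_H = as.numeric(C_H), C_L = as.numeric(C_L))
  if (any(!is.finite(x))) stop("state components must be finite")
  if (any(x < 0)) stop("state components must be >= 0; got (",
                       paste(signif(x, 6), collapse = ", "), ")")
  x
}

.state_names <- c("R_H", "R_L", "C_H", "C_L")

as_state <- function(x) {
  # internal: accept a bare length-4 numeric in canonical order
  stopifnot(is.numeric(x), length(x) == 4L)
  names(x) <- .state_names
  x
}

#' Consumer fitness in each patch
#'
#' Fitness is the consumer's per-capita growth rate,
#' \eqn{w_i = c \alpha R_i - \mu}. It can be negative (mortality exceeding
#' intake); zero fitness marks the resource density \eqn{\mu / (c \alpha)} at
#' which intake exactly offsets mortality.
#'
#' @param state A \code{\link{system_state}} vector.
#' @param params A \code{\link{model_params}} object.
#' @return Named numeric vector \code{c(w_H, w_L)} (1/time).
#' @export
fitness <- function(state, params) {
  state <- as_state(state)
  c(w_H = params$c * params$alpha * state[["R_H"]] - params$mu,
    w_L = params$c * params$alpha * state[["R_L"]] - params$mu)
}

# Largest exponent argument passed to exp(); beyond this exp() overflows
# double precision. Clamping keeps the kernel finite, positive and
# monotone in the fitness difference even at extreme lam.
.exp_clamp <- 700

#' Per-capita movement rate between patches
#'
#' The movement kernel is \eqn{Q_{ij} = \beta e^{\lambda (w_i - w_j)}}: the
#' rate from patch j into patch i is the baseline mobility \code{beta}
#' weighted exponentially by the fitness gained by moving. With
#' \code{lam = 0} (or equal fitnesses) movement is unbiased at rate
#' \code{beta}. The exponent argument is clamped to +/-700 so that extreme
#' \code{lam} values (e.g. 1000) cannot overflow; the clamp preserves sign
#' and monotonicity, and at equilibrium the fitness difference — and hence
#' the exponent — is small.
#'
#' @param w_to Fitness in the destination patch (1/time).
#' @param w_from Fitness in the source patch (1/time).
#' @param beta Mobility; >= 0.
#' @param lam Fitness sensitivity; >= 0.
#' @return Per-capita migration rate (1/time), >= 0. Vectorized over the
#'   fitness arguments.
#' @export
movement_rate <- function(w_to, w_from, beta, lam) {
  stopifnot(beta >= 0, lam >= 0)
  z <- lam * (w_to - w_from)
  beta * exp(pmin(pmax(z, -.exp_clamp), .exp_clamp))
}

#' Time derivatives of the two-patch system
#'
#' The exact right-hand side of the model: resources grow logistically in
#' each patch and are consumed through a Type I (linear) functional response;
#' consumers gain the demographic term \eqn{p (c \alpha R_i - \mu) C_i} and
#' exchange individuals at per-capita rates given by
#' \code{\link{movement_rate}}:
#' \deqn{dR_i/dt = r_i R_i (1 - R_i/K_i) - \alpha R_i C_i}
#' \deqn{dC_H/dt = p (c \alpha R_H - \mu) C_H + C_L Q_{HL} - C_H Q_{LH}}
#' and symmetrically for \eqn{C_L}. With \code{p = 0} the two consumer
#' derivatives sum to zero identically, so total consumer density is
#' conserved; with \code{beta = 0} the patches are demographically decoupled.
#'
#' This is a total function of the state: it does not clip or guard, so it
#' can be differentiated numerically across the axes (see
#' \code{\link{jacobian}}).
#'
#' @param state Numeric length-4 state (order R_H, R_L, C_H, C_L).
#' @param params A \code{\link{model_params}} object.
#' @return Named numeric vector of the four time derivatives.
#' @export
derivatives <- function(state, params) {
  R_H <- state[[1L]]; R_L <- state[[2L]]
  C_H <- state[[3L]]; C_L <- state[[4L]]
  w_H <- params$c * params$alpha * R_H - params$mu
  w_L <- params$c * params$alpha * R_L - params$mu
  Q_HL <- movement_rate(w_H, w_L, params$beta, params$lam)  # into H, from L
  Q_LH <- movement_rate(w_L, w_H, params$beta, params$lam)  # into L, from H
  c(R_H = params$high$r * R_H * (1 - R_H / params$high$K) - params$alpha * R_H * C_H,
    R_L = params$low$r * R_L * (1 - R_L / params$low$K) - params$alpha * R_L * C_L,
    C_H = params$p * w_H * C_H + C_L * Q_HL - C_H * Q_LH,
    C_L = params$p * w_L * C_L + C_H * Q_LH - C_L * Q_HL)
}

# deSolve-style RHS wrapper
.rhs_desolve <- function(t, y, parms) list(derivatives(y, parms))

#' Integrate the model forward in time
#'
#' Adaptive continuous-time integration of the model equations with a
#' stiff-capable solver (\code{deSolve::ode}, method \code{lsoda}), at tight
#' tolerances (relative 1e-10, absolute 1e-12 by default). The default
#' horizon of 5000 time units is ample for every parameter set shipped with
#' the package to settle at equilibrium.
#'
#' Integration does not clip densities; instead the trajectory is monitored
#' and an error is raised if any component falls below -1e-6, which signals
#' genuine misuse (e.g. wildly loose tolerances) rather than floating-point
#' jitter around zero.
#'
#' @param params A \code{\link{model_params}} object.
#' @param init Initial \code{\link{system_state}}.
#' @param horizon Final time (default 5000).
#' @param times Optional explicit output times (overrides \code{horizon} /
#'   \code{sample_interval}).
#' @param sample_interval Spacing of output times (default \code{horizon/500},
#'   or 1 if horizon is 0).
#' @param rtol,atol Integrator tolerances.
#' @return A data frame with columns \code{t, R_H, R_L, C_H, C_L, w_H, w_L}.
#' @examples
#' pr <- model_params(patch_params(2, 100), patch_params(1, 50),
#'                    alpha = 0.05, c = 0.05, mu = 0.1, beta = 1, lam = 0,
#'                    p = 0)
#' traj <- simulate_model(pr, system_state(50, 25, 25, 5), horizon = 100)
#' tail(traj, 1)  # consumers mix toward an equal split
#' @export
simulate_model <- function(params, init, horizon = 5000, times = NULL,
                           sample_interval = NULL, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(params, "model_params"))
  init <- system_state(init[[1L]], init[[2L]], init[[3L]], init[[4L]])
  if (is.null(times)) {
    stopifnot(is.numeric(horizon), length(horizon) == 1L, horizon >= 0)
    if (horizon == 0) {
      w <- fitness(init, params)
      return(data.frame(t = 0, R_H = init[["R_H"]], R_L = init[["R_L"]],
                        C_H = init[["C_H"]], C_L = init[["C_L"]],
                        w_H = w[["w_H"]], w_L = w[["w_L"]]))
    }
    if (is.null(sample_interval)) sample_interval <- horizon / 500
    times <- unique(c(seq(0, horizon, by = sample_interval), horizon))
  }
  sol <- deSolve::ode(y = init, times = times, func = .rhs_desolve,
                      parms = params, method = "lsoda",
                      rtol = rtol, atol = atol)
  m <- unclass(sol)
  if (min(m[, .state_names]) < -1e-6)
    stop("integration produced a density below -1e-6; ",
         "check parameters and tolerances")
  w_H <- params$c * params$alpha * m[, "R_H"] - params$mu
  w_L <- params$c * params$alpha * m[, "R_L"] - params$mu
  data.frame(t = m[, "time"], R_H = m[, "R_H"], R_L = m[, "R_L"],
             C_H = m[, "C_H"], C_L = m[, "C_L"], w_H = w_H, w_L = w_L)
}
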