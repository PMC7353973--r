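#' @name equilibrium_result
#' @title Equilibrium results
#'
#' @description An equilibrium computation returns an object of class
#' \code{equilibrium_result}: a list with the equilibrium \code{state}
#' (named length-4 vector), the per-patch \code{fitness} at that state, the
#' \code{residual} (max-norm of the time derivatives at the state), a
#' \code{stable} flag, the vector \code{eigen_real_parts} of Jacobian
#' eigenvalue real parts used for the classification, and the \code{method}
#' string (\code{closed_form_no_movement}, \code{implicit_no_demography},
#' \code{numeric_root} or \code{integration_endpoint}).
#'
#' @details Stability is linear stability of the computed state. Without
#' consumer demography (\code{p = 0}) the consumer total is conserved, which
#' makes one direction of the full 4-D linearization structurally neutral;
#' stability is therefore assessed on the 3-D reduced system in which
#' \code{C_L} is eliminated through the conserved total, and
#' \code{eigen_real_parts} then has length 3. With demography (\code{p = 1})
#' it has length 4.
NULL

new_equilibrium_result <- function(state, params, method,
                                   eigen_real_parts, residual) {
  structure(list(state = as_state(state),
                 fitness = fitness(state, params),
                 residual = residual,
                 stable = max(eigen_real_parts) < 0,
                 eigen_real_parts = eigen_real_parts,
                 method = method),
            class = "equilibrium_result")
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat("Equilibrium (", x$method, ")\n", sep = "")
  cat(sprintf("  R_H* = %.8g  R_L* = %.8g\n",
              x$state[["R_H"]], x$state[["R_L"]]))
  cat(sprintf("  C_H* = %.8g  C_L* = %.8g\n",
              x$state[["C_H"]], x$state[["C_L"]]))
  cat(sprintf("  w_H = %.8g  w_L = %.8g\n",
              x$fitness[["w_H"]], x$fitness[["w_L"]]))
  cat(sprintf("  residual = %.3g, %s (max Re(eig) = %.3g)\n", x$residual,
              if (x$stable) "stable" else "unstable",
              max(x$eigen_real_parts)))
  invisible(x)
}

#' Flatten an equilibrium result to a one-row data frame
#'
#' @param x An \code{equilibrium_result}.
#' @param ... Unused.
#' @return One-row data frame with columns \code{R_H, R_L, C_H, C_L, w_H,
#'   w_L, residual, stable, method}.
#' @export
as.data.frame.equilibrium_result <- function(x, ...) {
  data.frame(R_H = x$state[["R_H"]], R_L = x$state[["R_L"]],
             C_H = x$state[["C_H"]], C_L = x$state[["C_L"]],
             w_H = x$fitness[["w_H"]], w_L = x$fitness[["w_L"]],
             residual = x$residual, stable = x$stable, method = x$method,
             stringsAsFactors = FALSE)
}

#' Conserved consumer total (no-demography case)
#'
#' Without consumer demography the consumers' regional abundance is fixed by
#' the initial condition. \code{C_T} is the mean consumer density per patch,
#' so the total across the two (equally sized) patches is \code{2 * C_T}.
#'
#' @param C_T Mean consumer density per patch; > 0.
#' @return An object of class \code{conserved_total}.
#' @export
conserved_total <- function(C_T) {
  stopifnot(is.numeric(C_T), length(C_T) == 1L, is.finite(C_T))
  if (C_T <= 0) stop("`C_T` must be > 0")
  structure(list(C_T = as.numeric(C_T)), class = "conserved_total")
}

#' Finite-difference Jacobian of the derivative field
#'
#' Central finite differences of \code{\link{derivatives}} with per-column
#' step \code{h = 1e-6 * max(1, |x_j|)}. Differentiating the implemented
#' right-hand side (rather than hand-coded analytic entries) keeps the
#' stability classification honest against the equations actually integrated.
#'
#' @param state Numeric length-4 state.
#' @param params A \code{\link{model_params}} object.
#' @return A 4x4 matrix, rows and columns ordered (R_H, R_L, C_H, C_L).
#' @export
jacobian <- function(state, params) {
  state <- as.numeric(state)
  J <- matrix(0, 4L, 4L, dimnames = list(.state_names, .state_names))
  for (j in 1:4) {
    h <- 1e-6 * max(1, abs(state[j]))
    up <- state; up[j] <- state[j] + h
    dn <- state; dn[j] <- state[j] - h
    J[, j] <- (derivatives(up, params) - derivatives(dn, params)) / (2 * h)
  }
  J
}

# Reduced 3-D RHS for p=0: (R_H, R_L, C_H) with C_L = 2*C_T - C_H.
.derivatives_reduced <- function(x, params, C_T) {
  d <- derivatives(c(x[1L], x[2L], x[3L], 2 * C_T - x[3L]), params)
  d[1:3]
}

# Eigenvalue real parts used for stability classification: reduced 3-D
# system for p=0 (the conserved consumer total is a neutral direction of the
# full linearization), full 4-D Jacobian for p=1.
.stability_eigs <- function(state, params, C_T = NULL) {
  if (params$p == 0) {
    if (is.null(C_T)) C_T <- (state[[3L]] + state[[4L]]) / 2
    x <- as.numeric(state)[1:3]
    J <- matrix(0, 3L, 3L)
    for (j in 1:3) {
      h <- 1e-6 * max(1, abs(x[j]))
      up <- x; up[j] <- x[j] + h
      dn <- x; dn[j] <- x[j] - h
      J[, j] <- (.derivatives_reduced(up, params, C_T) -
                 .derivatives_reduced(dn, params, C_T)) / (2 * h)
    }
  } else {
    J <- jacobian(state, params)
  }
  sort(Re(eigen(J, only.values = TRUE)$values), decreasing = TRUE)
}

#' Closed-form equilibrium without movement
#'
#' With consumer demography on and no movement (\code{p = 1, beta = 0}) the
#' patches decouple and each settles at the classic Lotka-Volterra
#' equilibrium with logistic prey: the resource is pinned at the density
#' where consumer fitness vanishes,
#' \deqn{R_H^* = R_L^* = \mu / (c \alpha),}
#' and the consumers absorb the surplus production,
#' \deqn{C_i^* = (r_i / \alpha) (1 - \mu / (c \alpha K_i)).}
#' Fitness is exactly zero in both patches. Requires
#' \eqn{\mu/(c\alpha) < K_i} in both patches, otherwise the consumer cannot
#' persist there and the model's positive-density regime is left.
#'
#' @param params A \code{\link{model_params}} with \code{p = 1},
#'   \code{beta = 0}.
#' @return An \code{\link{equilibrium_result}} with method
#'   \code{"closed_form_no_movement"}.
#' @export
equilibrium_no_movement <- function(params) {
  stopifnot(inherits(params, "model_params"))
  if (params$p != 1)
    stop("closed-form no-movement equilibrium requires consumer demography ",
         "(p = 1); got p = ", params$p)
  if (params$beta != 0)
    stop("closed-form no-movement equilibrium requires beta = 0; got beta = ",
         params$beta)
  Rstar <- params$mu / (params$c * params$alpha)
  if (Rstar >= params$high$K || Rstar >= params$low$K)
    stop("consumer cannot persist: mu/(c*alpha) = ", signif(Rstar, 6),
         " must be below both carrying capacities")
  C_H <- (params$high$r / params$alpha) * (1 - Rstar / params$high$K)
  C_L <- (params$low$r / params$alpha) * (1 - Rstar / params$low$K)
  st <- c(Rstar, Rstar, C_H, C_L)
  res <- max(abs(derivatives(st, params)))
  new_equilibrium_result(st, params, "closed_form_no_movement",
                         .stability_eigs(st, params), res)
}

# g(C_H) for the implicit p=0 equilibrium, in log-ratio form:
#   g = ln((2 C_T - C_H)/C_H) + 2 lam c alpha [R_H(C_H) - R_L(2 C_T - C_H)]
# with R_i the linear resource nullclines. g is strictly decreasing in C_H,
# so the root on (0, 2 C_T) is unique when it exists.
.g_no_demography <- function(C_H, params, C_T) {
  C_L <- 2 * C_T - C_H
  R_H <- params$high$K * (1 - params$alpha * C_H / params$high$r)
  R_L <- params$low$K * (1 - params$alpha * C_L / params$low$r)
  log(C_L / C_H) + 2 * params$lam * params$c * params$alpha * (R_H - R_L)
}

.g_no_demography_deriv <- function(C_H, params, C_T) {
  C_L <- 2 * C_T - C_H
  -(1 / C_H + 1 / C_L) - 2 * params$lam * params$c * params$alpha^2 *
    (params$high$K / params$high$r + params$low$K / params$low$r)
}

#' Implicit equilibrium without consumer demography
#'
#' With demography off (\code{p = 0}) the unique positive equilibrium
#' balances migration fluxes: \eqn{C_L Q_{HL} = C_H Q_{LH}}, i.e.
#' \deqn{C_L^*/C_H^* = e^{-2 \lambda c \alpha (R_H^* - R_L^*)},}
#' with each resource on its nullcline
#' \eqn{R_i^* = K_i (1 - \alpha C_i^* / r_i)}. Mobility \code{beta} drops out
#' of these conditions entirely — it sets only the speed of convergence, not
#' the fixed point. The solver works in log-ratio form,
#' \code{g(C_H) = log((2 C_T - C_H)/C_H) + 2 lam c alpha (R_H - R_L)}, which
#' is strictly decreasing in \code{C_H}; a bracketed \code{uniroot} on
#' \code{(eps, 2 C_T - eps)} followed by Newton polishing with the analytic
#' derivative gives the root essentially to machine precision.
#'
#' At \code{lam = 0} the root is the equal split \code{C_H = C_L = C_T}; as
#' \code{lam} grows the consumers pile into the high-quality patch until the
#' resource densities — and so the fitnesses — equalize: the ideal free
#' distribution limit.
#'
#' @param params A \code{\link{model_params}} with \code{p = 0} and
#'   \code{beta > 0}.
#' @param total A \code{\link{conserved_total}} (mean consumer density per
#'   patch).
#' @return An \code{\link{equilibrium_result}} with method
#'   \code{"implicit_no_demography"}.
#' @export
equilibrium_no_demography <- function(params, total) {
  stopifnot(inherits(params, "model_params"),
            inherits(total, "conserved_total"))
  if (params$p != 0)
    stop("implicit equilibrium requires p = 0; got p = ", params$p)
  if (params$beta <= 0)
    stop("implicit equilibrium requires beta > 0 (movement couples the ",
         "patches); got beta = ", params$beta)
  C_T <- total$C_T
  eps <- 1e-12 * C_T
  lo <- eps; hi <- 2 * C_T - eps
  g_lo <- .g_no_demography(lo, params, C_T)
  g_hi <- .g_no_demography(hi, params, C_T)
  if (!is.finite(g_lo) || !is.finite(g_hi) || g_lo * g_hi > 0)
    stop("no sign change on the consumer bracket: parameters are outside ",
         "the positive-density regime")
  C_H <- stats::uniroot(.g_no_demography, c(lo, hi), params = params,
                        C_T = C_T, tol = 1e-14 * C_T)$root
  # Newton polish (g is monotone with analytic derivative)
  for (k in 1:6) {
    step <- .g_no_demography(C_H, params, C_T) /
      .g_no_demography_deriv(C_H, params, C_T)
    C_H_new <- min(max(C_H - step, lo), hi)
    if (abs(C_H_new - C_H) <= 1e-15 * C_T) { C_H <- C_H_new; break }
    C_H <- C_H_new
  }
  C_L <- 2 * C_T - C_H
  R_H <- params$high$K * (1 - params$alpha * C_H / params$high$r)
  R_L <- params$low$K * (1 - params$alpha * C_L / params$low$r)
  if (R_H <= 0 || R_L <= 0)
    stop("equilibrium resource density is not positive: parameters are ",
         "outside the positive-density regime")
  st <- c(R_H, R_L, C_H, C_L)
  res <- max(abs(derivatives(st, params)))
  new_equilibrium_result(st, params, "implicit_no_demography",
                         .stability_eigs(st, params, C_T), res)
}

# Damped Newton on F(x) = 0 with finite-difference Jacobian.
.newton_root <- function(F, x0, tol = 1e-12, maxit = 60L) {
  x <- x0
  f <- F(x)
  n <- length(x)
  for (it in seq_len(maxit)) {
    if (max(abs(f)) < tol) return(list(x = x, f = f, converged = TRUE))
    J <- matrix(0, n, n)
    for (j in seq_len(n)) {
      h <- 1e-7 * max(1, abs(x[j]))
      up <- x; up[j] <- x[j] + h
      dn <- x; dn[j] <- x[j] - h
      J[, j] <- (F(up) - F(dn)) / (2 * h)
    }
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step)) return(list(x = x, f = f, converged = FALSE))
    lam <- 1
    repeat {  # backtracking line search on ||F||_inf
      x_new <- x - lam * step
      f_new <- F(x_new)
      if (all(is.finite(f_new)) &&
          (max(abs(f_new)) < max(abs(f)) || lam < 1e-4)) break
      lam <- lam / 2
    }
    x <- x_new; f <- f_new
  }
  list(x = x, f = f, converged = max(abs(f)) < tol)
}

#' General numerical equilibrium by multidimensional root-finding
#'
#' Solves \code{derivatives(state) = 0} by damped Newton iteration with a
#' finite-difference Jacobian, starting from \code{guess}. For \code{p = 0}
#' the consumer total is conserved, so the fourth equation is replaced by
#' the constraint \code{C_H + C_L = C_H(guess) + C_L(guess)}; this pins the
#' root to the conservation class of the guess, where it is unique. If
#' Newton stalls, the guess is first relaxed by integrating to the default
#' horizon and Newton is retried from the endpoint.
#'
#' @param params A \code{\link{model_params}} object.
#' @param guess Strictly positive initial \code{\link{system_state}}; if
#'   omitted, a default interior guess is built from the parameters
#'   (resources at K/2; consumers split equally for \code{p = 0}, at the
#'   no-movement closed forms for \code{p = 1}).
#' @param tol Residual tolerance on the derivative field (default 1e-11,
#'   near the finite-difference Newton floor at the model's density scale;
#'   the result is guaranteed below 1e-10 or an error is raised).
#' @return An \code{\link{equilibrium_result}} with method
#'   \code{"numeric_root"}.
#' @export
equilibrium_numeric <- function(params, guess = NULL, tol = 1e-11) {
  stopifnot(inherits(params, "model_params"))
  if (is.null(guess)) guess <- default_guess(params)
  guess <- as.numeric(guess)
  if (any(guess <= 0)) stop("`guess` must be strictly positive")
  if (params$p == 0 && params$beta == 0)
    stop("p = 0 with beta = 0 leaves the consumer distribution arbitrary; ",
         "no isolated equilibrium to solve for")
  if (params$p == 0) {
    tot <- guess[3L] + guess[4L]
    F <- function(x) {
      d <- derivatives(x, params)
      c(d[1L], d[2L], d[3L], x[3L] + x[4L] - tot)
    }
  } else {
    F <- function(x) derivatives(x, params)
  }
  sol <- .newton_root(F, guess, tol = tol)
  # A root with a (near-)zero component is a boundary equilibrium outside
  # the positive-density regime; treat it like non-convergence and relax the
  # guess along the flow, which leads to the interior attractor.
  if (!sol$converged || any(sol$x < 1e-6)) {
    relaxed <- simulate_model(params, pmax(guess, 1e-8), horizon = 5000,
                              sample_interval = 5000)
    x1 <- as.numeric(relaxed[nrow(relaxed), c("R_H", "R_L", "C_H", "C_L")])
    sol2 <- .newton_root(F, x1, tol = tol)
    if (sol2$converged) sol <- sol2
  }
  if (!sol$converged)
    stop("numeric equilibrium search did not converge (residual ",
         signif(max(abs(sol$f)), 3), ")")
  st <- sol$x
  if (any(st < -1e-10))
    stop("converged root has a negative component: parameters are outside ",
         "the positive-equilibrium regime")
  st <- pmax(st, 0)
  res <- max(abs(derivatives(st, params)))
  if (res >= 1e-10)
    stop("numeric equilibrium residual ", signif(res, 3), " exceeds 1e-10")
  new_equilibrium_result(st, params, "numeric_root",
                         .stability_eigs(st, params), res)
}

#' Equilibrium as the endpoint of a long integration
#'
#' Integrates from \code{init} to \code{horizon} and returns the endpoint as
#' an equilibrium estimate. This is the package's independent cross-check on
#' the root-finding methods: it follows the flow rather than solving the
#' algebraic conditions.
#'
#' @param params A \code{\link{model_params}} object.
#' @param init Initial state; defaults to \code{default_guess(params)}.
#' @param horizon Integration horizon (default 5000).
#' @return An \code{\link{equilibrium_result}} with method
#'   \code{"integration_endpoint"}.
#' @export
equilibrium_integrate <- function(params, init = NULL, horizon = 5000) {
  stopifnot(inherits(params, "model_params"))
  if (is.null(init)) init <- default_guess(params)
  traj <- simulate_model(params, init, horizon = horizon,
                         sample_interval = horizon)
  st <- pmax(as.numeric(traj[nrow(traj), c("R_H", "R_L", "C_H", "C_L")]), 0)
  res <- max(abs(derivatives(st, params)))
  new_equilibrium_result(st, params, "integration_endpoint",
                         .stability_eigs(st, params), res)
}

#' Default interior initial guess for equilibrium searches
#'
#' Resources start at half their carrying capacities. Consumers split
#' equally at \code{C_T} each when demography is off, and sit at the
#' no-movement closed-form values when it is on — both lie inside the
#' positive-density region for all shipped parameter presets.
#'
#' @param params A \code{\link{model_params}} object.
#' @param total Optional \code{\link{conserved_total}} (p = 0 only; default
#'   C_T = 15).
#' @return A \code{\link{system_state}} vector.
#' @export
default_guess <- function(params, total = NULL) {
  R <- c(params$high$K / 2, params$low$K / 2)
  if (params$p == 0) {
    C_T <- if (is.null(total)) 15 else total$C_T
    system_state(R[1], R[2], C_T, C_T)
  } else {
    Rstar <- params$mu / (params$c * params$alpha)
    C_H <- (params$high$r / params$alpha) * (1 - Rstar / params$high$K)
    C_L <- (params$low$r / params$alpha) * (1 - Rstar / params$low$K)
    system_state(R[1], R[2], max(C_H, 1e-3), max(C_L, 1e-3))
  }
}

#' Migration flux-balance residual at a no-demography equilibrium
#'
#' At the p = 0 equilibrium, total migration into and out of each patch must
#' balance: \eqn{C_L Q_{HL} = C_H Q_{LH}}. Returns the absolute residual
#' \eqn{|C_L Q_{HL} - C_H Q_{LH}|}; at a converged equilibrium it must be
#' below \code{1e-8 * beta * max(C_H, C_L)}.
#'
#' @param result An \code{\link{equilibrium_result}} from a p = 0
#'   computation.
#' @param params The \code{\link{model_params}} used to produce it.
#' @return The residual (density/time), with attribute \code{"ok"} giving
#'   the tolerance comparison.
#' @export
flux_balance_check <- function(result, params) {
  stopifnot(inherits(result, "equilibrium_result"),
            inherits(params, "model_params"))
  st <- result$state
  w <- fitness(st, params)
  Q_HL <- movement_rate(w[["w_H"]], w[["w_L"]], params$beta, params$lam)
  Q_LH <- movement_rate(w[["w_L"]], w[["w_H"]], params$beta, params$lam)
  res <- abs(st[["C_L"]] * Q_HL - st[["C_H"]] * Q_LH)
  tol <- 1e-8 * params$beta * max(st[["C_H"]], st[["C_L"]])
  structure(unname(res), ok = res < tol)
}

#' Dispatch to the cheapest applicable equilibrium method
#'
#' \code{p = 1, beta = 0} takes the closed form; \code{p = 0} takes the
#' implicit flux-balance solve; everything else goes to numeric
#' root-finding with an integration fallback.
#'
#' @param params A \code{\link{model_params}} object.
#' @param total A \code{\link{conserved_total}}; required when \code{p = 0}.
#' @param guess Optional initial state for the numeric route.
#' @return An \code{\link{equilibrium_result}}.
#' @export
equilibrium_auto <- function(params, total = NULL, guess = NULL) {
  stopifnot(inherits(params, "model_params"))
  if (params$p == 0) {
    if (is.null(total))
      stop("p = 0 requires a conserved_total (C_T)")
    if (params$beta > 0) return(equilibrium_no_demography(params, total))
    stop("p = 0 with beta = 0 has no coupled equilibrium: consumers never ",
         "redistribute")
  }
  if (params$beta == 0) return(equilibrium_no_movement(params))
  tryCatch(equilibrium_numeric(params, guess),
           error = function(e) equilibrium_integrate(params, guess))
}
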