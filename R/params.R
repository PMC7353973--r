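#' Per-patch resource demography
#'
#' Bundles the logistic parameters of the resource in one patch: the intrinsic
#' growth rate \code{r} and the carrying capacity \code{K}.
#'
#' @param r Resource intrinsic growth rate (1/time). Must be positive.
#' @param K Resource carrying capacity (density). Must be positive.
#'
#' @return An object of class \code{patch_params}: a list with elements
#'   \code{r} and \code{K}.
#' @examples
#' patch_params(r = 2, K = 100)
#' @export
patch_params <- function(r, K) {
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r),
            is.numeric(K), length(K) == 1L, is.finite(K))
  if (r <= 0) stop("patch growth rate `r` must be > 0, got ", r)
  if (K <= 0) stop("patch carrying capacity `K` must be > 0, got ", K)
  structure(list(r = as.numeric(r), K = as.numeric(K)),
            class = "patch_params")
}

#' Full model parameterization
#'
#' Collects everything the dynamical equations need: the two patches'
#' resource demography, the consumer's functional-response and demographic
#' rates, the movement parameters, and the demography switch.
#'
#' The consumer's per-capita growth rate (fitness) in patch i is
#' \eqn{w_i = c \alpha R_i - \mu}; the per-capita movement rate from patch j
#' into patch i is \eqn{Q_{ij} = \beta e^{\lambda (w_i - w_j)}}, so
#' \code{beta} is the baseline mobility and \code{lam} scales how strongly
#' movement responds to the fitness difference. \code{p = 0} switches consumer
#' births and deaths off (consumers then change only by migration and their
#' total is conserved); \code{p = 1} switches them on.
#'
#' By convention the first patch is the high-quality one: \code{high$r >=
#' low$r} and \code{high$K >= low$K}. A violation is a warning, not an error,
#' because the equations themselves are symmetric under relabelling.
#'
#' @param high,low \code{\link{patch_params}} for the high- and low-quality
#'   patch.
#' @param alpha Attack rate (1/(consumer x time)); > 0.
#' @param c Conversion efficiency (dimensionless); > 0.
#' @param mu Consumer mortality rate (1/time); >= 0.
#' @param beta Mobility: baseline per-capita movement rate (1/time); >= 0.
#' @param lam Fitness sensitivity of movement (time); >= 0.
#' @param p Demography switch, 0 or 1.
#'
#' @return An object of class \code{model_params}.
#' @examples
#' model_params(patch_params(2, 100), patch_params(1, 50),
#'              alpha = 0.05, c = 0.05, mu = 0.1, beta = 1, lam = 0, p = 0)
#' @export
model_params <- function(high, low, alpha, c, mu, beta = 0, lam = 0, p = 1) {
  if (!inherits(high, "patch_params") || !inherits(low, "patch_params"))
    stop("`high` and `low` must be patch_params objects")
  for (nm in c("alpha", "c", "mu", "beta", "lam", "p")) {
    v <- get(nm)
    stopifnot(is.numeric(v), length(v) == 1L, is.finite(v))
  }
  if (alpha <= 0) stop("`alpha` must be > 0")
  if (c <= 0) stop("`c` must be > 0")
  if (mu < 0) stop("`mu` must be >= 0")
  if (beta < 0) stop("`beta` must be >= 0")
  if (lam < 0) stop("`lam` must be >= 0")
  if (!p %in% c(0, 1)) stop("`p` must be 0 or 1")
  if (high$r < low$r || high$K < low$K)
    warning("patch labelling convention violated: expected high$r >= low$r ",
            "and high$K >= low$K")
  structure(list(high = high, low = low,
                 alpha = as.numeric(alpha), c = as.numeric(c),
                 mu = as.numeric(mu), beta = as.numeric(beta),
                 lam = as.numeric(lam), p = as.integer(p)),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Two-patch consumer-resource model parameters\n")
  cat(sprintf("  high patch: r = %g, K = %g\n", x$high$r, x$high$K))
  cat(sprintf("  low  patch: r = %g, K = %g\n", x$low$r, x$low$K))
  cat(sprintf("  alpha = %g, c = %g, mu = %g\n", x$alpha, x$c, x$mu))
  cat(sprintf("  movement: beta = %g, lam = %g\n", x$beta, x$lam))
  cat(sprintf("  consumer demography: %s (p = %d)\n",
              if (x$p == 1) "on" else "off", x$p))
  invisible(x)
}

#' Proportionality rule linking fitness sensitivity to mobility
#'
#' Under covarying movement the two movement parameters are tied linearly,
#' \eqn{\lambda = \gamma \beta} with \eqn{\gamma > 0}, so a single mobility
#' axis sweeps both at once.
#'
#' @param gamma Ratio lambda/beta; > 0.
#' @return An object of class \code{covary_rule}.
#' @export
covary_rule <- function(gamma) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L, is.finite(gamma))
  if (gamma <= 0) stop("`gamma` must be > 0")
  structure(list(gamma = as.numeric(gamma)), class = "covary_rule")
}

#' Apply the covariation rule at a given mobility
#'
#' Returns a copy of \code{params} with \code{beta} set to the given mobility
#' and \code{lam = gamma * beta}; all other fields are unchanged.
#'
#' @param params A \code{\link{model_params}} object.
#' @param rule A \code{\link{covary_rule}}.
#' @param beta Mobility at which to evaluate the rule; >= 0.
#' @return A \code{model_params} object.
#' @export
apply_covary <- function(params, rule, beta) {
  stopifnot(inherits(params, "model_params"), inherits(rule, "covary_rule"),
            is.numeric(beta), length(beta) == 1L, beta >= 0)
  params$beta <- as.numeric(beta)
  params$lam <- rule$gamma * as.numeric(beta)
  params
}

# Flat serialization keys, in canonical order. `gamma` is optional on input.
.param_keys <- c("r_H", "r_L", "K_H", "K_L", "alpha", "c", "mu",
                 "beta", "lam", "p")

#' Serialize model parameters to a flat named list
#'
#' The mapping uses the keys \code{r_H, r_L, K_H, K_L, alpha, c, mu, beta,
#' lam, p}, suitable for YAML/JSON round-tripping.
#'
#' @param params A \code{\link{model_params}} object.
#' @return A named list of scalars.
#' @seealso [params_from_list()]
#' @export
params_to_list <- function(params) {
  stopifnot(inherits(params, "model_params"))
  list(r_H = params$high$r, r_L = params$low$r,
       K_H = params$high$K, K_L = params$low$K,
       alpha = params$alpha, c = params$c, mu = params$mu,
       beta = params$beta, lam = params$lam, p = params$p)
}

#' Deserialize model parameters from a flat named list
#'
#' Accepts exactly the keys produced by \code{\link{params_to_list}} plus an
#' optional \code{gamma}; any other key is an error (silent typos in a config
#' must not become silent defaults).
#'
#' @param x Named list with keys \code{r_H, r_L, K_H, K_L, alpha, c, mu,
#'   beta, lam, p} and optionally \code{gamma}.
#' @return A \code{\link{model_params}} object; if \code{gamma} was present it
#'   is attached as the attribute \code{"gamma"}.
#' @export
params_from_list <- function(x) {
  stopifnot(is.list(x))
  unknown <- setdiff(names(x), c(.param_keys, "gamma"))
  if (length(unknown) > 0L)
    stop("unknown model parameter key(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(.param_keys, names(x))
  if (length(missing) > 0L)
    stop("missing model parameter key(s): ", paste(missing, collapse = ", "))
  pr <- model_params(high = patch_params(x$r_H, x$K_H),
                     low = patch_params(x$r_L, x$K_L),
                     alpha = x$alpha, c = x$c, mu = x$mu,
                     beta = x$beta, lam = x$lam, p = x$p)
  if (!is.null(x$gamma)) attr(pr, "gamma") <- as.numeric(x$gamma)
  pr
}
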