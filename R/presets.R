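#' Shipped scenario presets
#'
#' The package ships the parameter sets behind its standard scenarios as a
#' plain YAML fixture (\code{inst/extdata/figure_presets.yaml}), transcribed
#' verbatim into \code{\link{sweep_config}} objects:
#' \describe{
#'   \item{fig1}{No-demography baseline (p = 0, C_T = 15): fitness
#'     sensitivity swept, showing the transition from the equal split at
#'     \code{lam = 0} to the ideal free distribution at large \code{lam}.}
#'   \item{fig2_solid, fig2_dashed, fig2_dotted}{The regional-resource
#'     trichotomy: identical (solid), larger (dashed) and smaller (dotted)
#'     density-dependent resource mortality r/K in the high-quality patch.}
#'   \item{fig3}{Demography on, fitness sensitivity fixed at
#'     \code{lam = 0.1, 10, 1000}, mobility swept.}
#'   \item{fig4}{Demography on, mobility fixed at \code{beta = 0.01, 0.1, 1},
#'     fitness sensitivity swept.}
#'   \item{fig5}{Demography on, covarying movement \code{lam = gamma * beta}
#'     at \code{gamma = 0.1, 1, 10}, mobility swept.}
#' }
#'
#' Default grids: fitness-sensitivity sweeps use 50 log-spaced points on
#' [0.01, 20] with 0 prepended; mobility sweeps use 50 evenly spaced points
#' on [0, 10] (covarying sweeps start just above 0, since the p = 1 closed
#' form covers beta = 0 exactly and the interesting turning point is
#' interior). Grids are configurable through \code{\link{sweep_config}}.
#'
#' @param name Optional preset name; if omitted, all presets are returned.
#' @return A named list of \code{\link{sweep_config}} objects (or a single
#'   one if \code{name} is given).
#' @examples
#' names(figure_presets())
#' figure_presets("fig1")$total$C_T
#' @export
figure_presets <- function(name = NULL) {
  path <- system.file("extdata", "figure_presets.yaml", package = "crmove",
                      mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    entry <- raw[[nm]]
    params <- params_from_list(entry$model)
    total <- if (!is.null(entry$C_T)) conserved_total(entry$C_T) else NULL
    sweep_config(scenario = entry$scenario, base_params = params,
                 grid = default_grid(entry$scenario),
                 fixed_levels = as.numeric(entry$levels), total = total)
  })
  names(out) <- names(raw)
  if (!is.null(name)) {
    if (!name %in% names(out))
      stop("unknown preset '", name, "'; available: ",
           paste(names(out), collapse = ", "))
    return(out[[name]])
  }
  out
}

#' Default sweep grid for a scenario
#'
#' @param scenario One of the scenario names accepted by
#'   \code{\link{sweep_config}}.
#' @return A strictly increasing numeric grid.
#' @export
default_grid <- function(scenario) {
  switch(scenario,
    vary_lambda_p0 = ,
    vary_lambda_fixed_beta_p1 =
      c(0, 10^seq(log10(0.01), log10(20), length.out = 50)),
    vary_beta_fixed_lambda_p1 = seq(0, 10, length.out = 50),
    covary_p1 = seq(0.2, 10, length.out = 50),
    stop("unknown scenario '", scenario, "'"))
}
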