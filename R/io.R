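# File I/O: run configs (YAML/JSON) and deterministic CSV output.

# Allowed top-level config keys, per command.
.config_keys_common <- c("model", "preset", "out", "horizon", "rtol", "atol",
                         "seed", "C_T")
.config_keys <- list(
  simulate    = c(.config_keys_common, "init", "sample_interval"),
  equilibrium = c(.config_keys_common, "method"),
  sweep       = c(.config_keys_common, "scenario", "grid", "levels"))

#' Read and validate a run configuration
#'
#' Configurations are YAML (JSON accepted; both parse through
#' \code{yaml::read_yaml}, JSON being a YAML subset). The model block uses
#' the flat parameter keys \code{r_H, r_L, K_H, K_L, alpha, c, mu, beta,
#' lam, p} (optional \code{gamma}); \code{C_T} sits at the top level.
#' Validation is strict: unknown keys are an error, as is a p = 0 model
#' without \code{C_T} for commands that need the conserved total.
#'
#' @param path Path to a YAML or JSON config file.
#' @param command One of \code{"simulate"}, \code{"equilibrium"},
#'   \code{"sweep"}.
#' @return The validated config list, with \code{$params} (a
#'   \code{\link{model_params}}) attached when a model block is present.
#' @export
read_run_config <- function(path, command) {
  stopifnot(file.exists(path))
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg, command)
}

#' @rdname read_run_config
#' @param cfg A config list (as parsed from file).
#' @export
validate_run_config <- function(cfg, command) {
  command <- match.arg(command, names(.config_keys))
  stopifnot(is.list(cfg))
  unknown <- setdiff(names(cfg), .config_keys[[command]])
  if (length(unknown) > 0L)
    stop("unknown config key(s) for command '", command, "': ",
         paste(unknown, collapse = ", "))
  if (is.null(cfg$model) && is.null(cfg$preset))
    stop("config must provide either `model` or `preset`")
  if (!is.null(cfg$model)) {
    cfg$params <- params_from_list(cfg$model)
    needs_total <- cfg$params$p == 0 && command %in% c("equilibrium", "sweep")
    if (needs_total && is.null(cfg$C_T))
      stop("missing config key `C_T`: a p = 0 model needs the conserved ",
           "mean consumer density")
  }
  if (!is.null(cfg$init)) {
    unknown_init <- setdiff(names(cfg$init), .state_names)
    if (length(unknown_init) > 0L)
      stop("unknown init key(s): ", paste(unknown_init, collapse = ", "))
    missing_init <- setdiff(.state_names, names(cfg$init))
    if (length(missing_init) > 0L)
      stop("missing init key(s): ", paste(missing_init, collapse = ", "))
  }
  if (!is.null(cfg$grid)) {
    unknown_grid <- setdiff(names(cfg$grid),
                            c("start", "stop", "count", "spacing"))
    if (length(unknown_grid) > 0L)
      stop("unknown grid key(s): ", paste(unknown_grid, collapse = ", "))
  }
  cfg
}

# Expand a grid spec {start, stop, count, spacing: linear|log} to a vector.
.expand_grid_spec <- function(g) {
  stopifnot(!is.null(g$start), !is.null(g$stop), !is.null(g$count))
  spacing <- if (is.null(g$spacing)) "linear" else g$spacing
  switch(match.arg(spacing, c("linear", "log")),
         linear = seq(g$start, g$stop, length.out = g$count),
         log = 10^seq(log10(g$start), log10(g$stop), length.out = g$count))
}

# %.12g rendering: deterministic, diff-stable, no precision loss at
# tolerance level.
.fmt_num <- function(x) {
  if (is.numeric(x)) sprintf("%.12g", x) else as.character(x)
}

#' Write a data frame as a deterministic CSV
#'
#' Numeric columns are rendered with \code{\%.12g}; identical tables produce
#' byte-identical files.
#'
#' @param df A data frame.
#' @param path Output path, or \code{""} for stdout.
#' @return \code{path}, invisibly.
#' @export
write_csv_12g <- function(df, path) {
  cols <- lapply(df, .fmt_num)
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, if (nzchar(path)) path else stdout())
  invisible(path)
}

#' Read back a CSV written by [write_csv_12g()]
#'
#' @param path CSV path.
#' @return A data frame with numeric/logical columns restored.
#' @export
read_csv_12g <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Serialize an equilibrium record to JSON
#'
#' Flat record with the fields \code{R_H, R_L, C_H, C_L, w_H, w_L,
#' residual, stable, method}, plus \code{flux_balance_residual} when
#' supplied.
#'
#' @param result An \code{\link{equilibrium_result}}.
#' @param path Output path, or \code{""} for stdout.
#' @param flux Optional flux-balance residual to include.
#' @return \code{path}, invisibly.
#' @export
write_equilibrium_json <- function(result, path, flux = NULL) {
  rec <- as.list(as.data.frame(result))
  rec$eigen_real_parts <- result$eigen_real_parts
  if (!is.null(flux)) rec$flux_balance_residual <- as.numeric(flux)
  txt <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(txt, if (nzchar(path)) path else stdout())
  invisible(path)
}
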