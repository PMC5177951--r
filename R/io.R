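# Configuration files and trajectory output: YAML configs in, TSV
# trajectories out, with a JSON sidecar for growth rates and pole tables.
# The TSV schema (t_days, N_*, V_*, V_tot, mean_n) is shared by every
# engine so downstream comparisons are engine-agnostic.

#' Read a model configuration
#'
#' YAML (or JSON, which is valid YAML) with keys \code{mode},
#' \code{v1}|\code{b}, \code{M}, \code{mu}, \code{lambda},
#' \code{schedule: \{type, s_hat | values\}},
#' \code{r_model: \{type, eta | c, p_mu | order\}}, \code{n_max},
#' \code{volumetric_exponent}.  Numeric fields accept scientific notation.
#'
#' @param path file path.
#' @return a \code{\link{model_params}} object.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  config_to_params(cfg)
}

config_to_params <- function(cfg) {
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  model_params(
    growth_mode = cfg$mode,
    v1 = num(cfg$v1), b = num(cfg$b),
    M = as.numeric(cfg$M),
    mu = if (is.null(cfg$mu)) 0 else as.numeric(cfg$mu),
    lam = num(cfg$lambda),
    schedule = if (is.null(cfg$schedule)) list(type = "linear")
               else lapply(cfg$schedule, function(x)
                 if (is.character(x)) x else as.numeric(x)),
    r_model = if (is.null(cfg$r_model)) list(type = "exponential")
              else lapply(cfg$r_model, function(x)
                if (is.character(x)) x else as.numeric(x)),
    n_max = if (is.null(cfg$n_max)) 32L else as.integer(cfg$n_max),
    volumetric_exponent = if (is.null(cfg$volumetric_exponent)) "b_minus_M"
                          else cfg$volumetric_exponent)
}

#' Write a model configuration
#'
#' @param params a \code{\link{model_params}} object.
#' @param path destination file.
#' @return \code{path}, invisibly.
#' @export
write_model_config <- function(params, path) {
  cfg <- list(mode = params$growth_mode)
  if (!is.null(params$v1)) cfg$v1 <- params$v1
  if (!is.null(params$b)) {
    cfg$b <- params$b
    cfg$volumetric_exponent <- params$volumetric_exponent
  }
  cfg$M <- params$M
  cfg$mu <- params$mu
  if (params$growth_mode == "surface_slowdown") cfg$lambda <- params$lam
  cfg$schedule <- params$schedule
  cfg$r_model <- params$r_model
  cfg$n_max <- params$n_max
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write a trajectory in the standard TSV schema
#'
#' Tab-separated, '.' decimal, header row: \code{t_days}, then the
#' per-type and derived columns of the series.
#'
#' @param series a time series data.frame (from \code{\link{solve_exact}},
#'   \code{\link{integrate_pde}}, \code{\link{simulate_tumour}}, ...).
#' @param path destination file.
#' @return \code{path}, invisibly.
#' @export
write_trajectory_tsv <- function(series, path) {
  out <- as.data.frame(series)
  names(out)[names(out) == "t"] <- "t_days"
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, dec = ".")
  invisible(path)
}

#' Read a trajectory written by \code{\link{write_trajectory_tsv}}
#'
#' @param path file path.
#' @return a data.frame with column \code{t} restored.
#' @export
read_trajectory_tsv <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE)
  names(out)[names(out) == "t_days"] <- "t"
  class(out) <- c("lesion_timeseries", "data.frame")
  out
}

#' Named parameter sets of the reference figures
#'
#' Returns the fixture configurations used throughout the validation
#' suite: single-type speed and migration sweeps (\code{fig2a},
#' \code{fig2b}), slow-down sweep (\code{fig2c}), the three multi-driver
#' scenarios (\code{fig3_surface}, \code{fig3_slowdown},
#' \code{fig3_volumetric}), the three-strong-drivers stochastic comparison
#' (\code{fig4}) and the Eden lattice comparisons (\code{fig5},
#' \code{fig6}).
#'
#' @param name fixture name; with no argument, the list of all fixtures.
#' @return a \code{\link{model_params}} object, an
#'   \code{\link{eden_params}} object, a list of either (for the sweeps),
#'   or the named list of everything.
#' @export
fig_params <- function(name = NULL) {
  all <- list(
    fig2a = lapply(c(0.01, 0.02, 0.05, 0.1), function(v)
      model_params("surface", v1 = v, M = 1e-6, mu = 0, n_max = 1L)),
    fig2b = lapply(c(1e-8, 1e-7, 1e-6, 1e-5), function(m)
      model_params("surface", v1 = 0.1, M = m, mu = 0, n_max = 1L)),
    fig2c = lapply(c(0.1, 0.01, 1e-3, 1e-4), function(l)
      model_params("surface_slowdown", v1 = 0.1, M = 1e-6, mu = 0,
                   lam = l, n_max = 1L)),
    fig3_surface = model_params("surface", v1 = 0.0475, M = 1e-6,
                                mu = 2e-5),
    fig3_slowdown = model_params("surface_slowdown", v1 = 0.053, M = 1e-6,
                                 mu = 2e-5, lam = 1e-3),
    fig3_volumetric = model_params("volumetric", b = 0.0026, M = 1e-5,
                                   mu = 2e-5),
    fig4 = model_params("surface", v1 = 0.015, M = 1e-4, mu = 2e-5,
                        schedule = list(type = "three_strong", s_hat = 0.01),
                        n_max = 10L),
    fig5 = eden_params(b1 = 0.0182, p_mu = 1e-4, M = 0, n_max = 3L),
    fig6 = eden_params(b1 = 0.0182, p_mu = 1e-4, M = 1e-4, n_max = 3L)
  )
  if (is.null(name)) return(all)
  if (!name %in% names(all)) stop("unknown fixture: ", name)
  all[[name]]
}

#' Write all fixture configs to a directory
#'
#' Model-parameter fixtures are written as YAML configs named after the
#' fixture (sweeps get one file per member).
#'
#' @param dir destination directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
generate_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  fx <- fig_params()
  for (nm in names(fx)) {
    obj <- fx[[nm]]
    if (inherits(obj, "model_params")) {
      p <- file.path(dir, paste0(nm, ".yaml"))
      write_model_config(obj, p)
      paths <- c(paths, p)
    } else if (inherits(obj, "eden_params")) {
      p <- file.path(dir, paste0(nm, ".yaml"))
      yaml::write_yaml(unclass(obj), p)
      paths <- c(paths, p)
    } else {
      for (i in seq_along(obj)) {
        p <- file.path(dir, sprintf("%s_%d.yaml", nm, i))
        write_model_config(obj[[i]], p)
        paths <- c(paths, p)
      }
    }
  }
  invisible(paths)
}
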