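#' Model parameterization
#'
#' Construct a complete parameter set for one variant of the microlesion
#' model.  A tumour is a collection of non-interacting microlesions; a lesion
#' of type \code{n} (its founder cell carried \code{n} drivers) and age
#' \code{a} has volume \code{V_n(a)} (cells), seeds new lesions at rate
#' \code{phi_n(a)} (1/day), and a fraction \code{r_n(a)} of its
#' migration-competent cells still carry exactly \code{n} drivers.
#'
#' @param growth_mode one of \code{"surface"} (cells replicate in a thin
#'   layer at the lesion boundary; volume grows cubically in age),
#'   \code{"surface_slowdown"} (surface growth damped exponentially at rate
#'   \code{lam}), or \code{"volumetric"} (all cells replicate; exponential
#'   lesion growth).
#' @param v1 radial expansion speed of a type-1 lesion, cells/day (surface
#'   modes only).
#' @param b net cell replication rate, 1/day (volumetric mode only).
#' @param M migration probability: in surface modes the dimensionless
#'   fraction of surface cells that escape and seed new lesions (in [0,1]);
#'   in the volumetric mode a per-cell migration rate, 1/day.
#' @param mu driver acquisition rate, 1/day.
#' @param lam slow-down rate lambda, 1/day; required (positive) iff
#'   \code{growth_mode = "surface_slowdown"}.
#' @param schedule driver-advantage schedule, a list with element
#'   \code{type} in \code{c("linear", "three_strong", "custom")}.
#'   \code{linear}: speed (or rate) of type n is \code{n} times that of type
#'   1.  \code{three_strong}: the first three drivers each add a full
#'   \code{v1} (\code{v_n = n v1} for n <= 3) and each later driver
#'   multiplies the speed by \code{1 + s_hat} (element \code{s_hat}, small).
#'   \code{custom}: element \code{values} gives per-type speeds/rates, the
#'   last value repeated beyond the list.
#' @param r_model mutant-fraction kernel, a list with element \code{type} in
#'   \code{c("exponential", "quadratic_surfing", "logistic_taylor")}.
#'   \code{exponential}: \code{r_n(a) = exp(-mu a)}.
#'   \code{quadratic_surfing}: \code{r_n(a) = 1 - eta_n a^2}, with
#'   \code{eta_n} either given directly (element \code{eta}) or computed from
#'   the surfing constant \code{c} and per-division mutation probability
#'   \code{p_mu} (elements \code{c}, \code{p_mu}).
#'   \code{logistic_taylor}: Taylor truncation (element \code{order},
#'   default 4) of the logistic mutant-takeover solution.
#' @param n_max maximum driver count tracked (truncation), >= 1.
#' @param volumetric_exponent exponent convention for the volumetric lesion
#'   volume: \code{"b_minus_M"} (default; migrating cells deplete the
#'   lesion, \code{V_n(a) = exp((b_n - M) a)}, so the single-type tumour
#'   growth rate is exactly \code{b}) or \code{"b"}
#'   (\code{V_n(a) = exp(b_n a)}).
#'
#' @return an object of class \code{model_params}.
#' @export
model_params <- function(growth_mode = c("surface", "surface_slowdown", "volumetric"),
                         v1 = NULL, b = NULL, M, mu = 0, lam = NULL,
                         schedule = list(type = "linear"),
                         r_model = list(type = "exponential"),
                         n_max = 32L,
                         volumetric_exponent = c("b_minus_M", "b")) {
  growth_mode <- match.arg(growth_mode)
  volumetric_exponent <- match.arg(volumetric_exponent)
  surface_mode <- growth_mode %in% c("surface", "surface_slowdown")

  if (surface_mode) {
    if (is.null(v1) || !is.null(b))
      stop("surface modes require `v1` (and no `b`)")
    if (v1 < 0) stop("`v1` must be >= 0")
    if (M < 0 || M > 1)
      stop("in surface modes `M` is a probability and must lie in [0, 1]")
  } else {
    if (is.null(b) || !is.null(v1))
      stop("volumetric mode requires `b` (and no `v1`)")
    if (b <= 0) stop("`b` must be > 0")
    if (M < 0) stop("`M` must be >= 0")
  }
  if (mu < 0) stop("`mu` must be >= 0")
  if (growth_mode == "surface_slowdown") {
    if (is.null(lam) || lam <= 0)
      stop("surface_slowdown requires `lam` > 0")
  } else if (!is.null(lam) && lam != 0) {
    stop("`lam` is only meaningful for growth_mode = 'surface_slowdown'")
  }
  n_max <- as.integer(n_max)
  if (is.na(n_max) || n_max < 1L) stop("`n_max` must be >= 1")

  schedule <- validate_schedule(schedule)
  r_model <- validate_r_model(r_model)

  structure(list(growth_mode = growth_mode, v1 = v1, b = b, M = M, mu = mu,
                 lam = if (growth_mode == "surface_slowdown") lam else 0,
                 schedule = schedule, r_model = r_model, n_max = n_max,
                 volumetric_exponent = volumetric_exponent),
            class = "model_params")
}

validate_schedule <- function(schedule) {
  if (is.null(schedule$type)) stop("schedule needs a `type`")
  type <- match.arg(schedule$type, c("linear", "three_strong", "custom"))
  out <- list(type = type)
  if (type == "three_strong") {
    out$s_hat <- if (is.null(schedule$s_hat)) 0.01 else schedule$s_hat
    if (out$s_hat < 0) stop("`s_hat` must be >= 0")
  }
  if (type == "custom") {
    if (is.null(schedule$values) || length(schedule$values) == 0)
      stop("custom schedule needs a non-empty `values` list")
    if (any(schedule$values < 0)) stop("custom schedule values must be >= 0")
    out$values <- as.numeric(schedule$values)
  }
  out
}

validate_r_model <- function(r_model) {
  if (is.null(r_model$type)) stop("r_model needs a `type`")
  type <- match.arg(r_model$type,
                    c("exponential", "quadratic_surfing", "logistic_taylor"))
  out <- list(type = type)
  if (type == "quadratic_surfing") {
    if (!is.null(r_model$eta)) {
      if (any(r_model$eta < 0)) stop("`eta` must be >= 0")
      out$eta <- r_model$eta
    } else {
      if (is.null(r_model$c) || is.null(r_model$p_mu))
        stop("quadratic_surfing needs either `eta` or both `c` and `p_mu`")
      if (r_model$c < 0 || r_model$p_mu < 0)
        stop("`c` and `p_mu` must be >= 0")
      out$c <- r_model$c
      out$p_mu <- r_model$p_mu
    }
  }
  if (type == "logistic_taylor") {
    out$order <- if (is.null(r_model$order)) 4L else as.integer(r_model$order)
    if (out$order < 1L) stop("logistic_taylor `order` must be >= 1")
  }
  out
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>", x$growth_mode, "\n")
  if (!is.null(x$v1)) cat("  v1  =", x$v1, "cells/day\n")
  if (!is.null(x$b))  cat("  b   =", x$b, "1/day",
                          sprintf("(exponent: %s)", x$volumetric_exponent), "\n")
  cat("  M   =", x$M, "\n  mu  =", x$mu, "1/day\n")
  if (x$growth_mode == "surface_slowdown") cat("  lam =", x$lam, "1/day\n")
  cat("  schedule:", x$schedule$type,
      if (x$schedule$type == "three_strong") sprintf("(s_hat = %g)", x$schedule$s_hat) else "",
      "\n  r_model:", x$r_model$type, "\n  n_max =", x$n_max, "\n")
  invisible(x)
}

#' Per-type expansion speed or replication rate
#'
#' Returns the radial expansion speed \code{v_n} (surface modes) or net
#' replication rate \code{b_n} (volumetric mode) of a lesion whose founder
#' carried \code{n} drivers, according to the driver-advantage schedule.
#'
#' Schedules: \code{linear} gives \code{n} times the type-1 value;
#' \code{three_strong} gives the linear value for \code{n <= 3} and
#' multiplies by \code{(1 + s_hat)} per driver beyond the third;
#' \code{custom} reads a user table, repeating its last entry.
#'
#' @param params a \code{\link{model_params}} object.
#' @param n lesion type (founder driver count), >= 1; vectorized.
#' @return speed (cells/day) or rate (1/day) for each \code{n}.
#' @export
driver_speed_schedule <- function(params, n) {
  if (any(n < 1)) stop("lesion type `n` must be >= 1")
  base <- if (is.null(params$v1)) params$b else params$v1
  sched <- params$schedule
  switch(sched$type,
    linear = n * base,
    three_strong = ifelse(n <= 3, n * base,
                          3 * base * (1 + sched$s_hat)^(n - 3)),
    custom = sched$values[pmin(n, length(sched$values))]
  )
}
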