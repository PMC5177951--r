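# Parameter-region scan: which (v1, M) pairs give clinically plausible
# tumours?  A pair is accepted when the exact solution reaches a total
# volume inside the target window at some evaluation age; because the
# growth rate scales as (M v^3)^(1/3), the accepted band follows
# M ~ v^(-3) on the log-log plane.

#' Scan the (v1, M) parameter plane
#'
#' Samples \code{n_points} pairs log-uniformly, solves the model exactly at
#' the evaluation ages, and classifies each point by whether the total
#' volume falls in \code{size_window} (optionally also requiring the mean
#' driver count to stay below \code{mean_n_max}).
#'
#' @param family "surface", "surface_slowdown" (needs \code{lam}) or
#'   "surface_multi" (multi-type surface growth with mutation rate
#'   \code{mu}).
#' @param v_range,M_range log-uniform sampling ranges.
#' @param n_points number of sampled points.
#' @param ages evaluation ages in days (default 10, 15, 20 years).
#' @param size_window acceptance window on V_tot, cells.
#' @param mean_n_max optional upper bound on the mean driver count at the
#'   accepting age (NA = no bound).
#' @param age_rule "any" (accept if any evaluated age meets the window,
#'   default) or "all".
#' @param mu,lam auxiliary rates for the multi-type / slow-down families.
#' @param seed RNG seed for the sampling.
#' @return a data.frame (class \code{scan_result}) with columns \code{v1},
#'   \code{M}, \code{accepted}, \code{V_age1..}, \code{mean_n_age1..};
#'   failed solves are recorded with NA and \code{accepted = FALSE}.
#' @export
scan_parameter_region <- function(family = c("surface", "surface_slowdown",
                                             "surface_multi"),
                                  v_range = c(0.01, 0.5),
                                  M_range = c(1e-9, 1e-2),
                                  n_points = 1000,
                                  ages = c(10, 15, 20) * 365,
                                  size_window = c(1e10, 1e12),
                                  mean_n_max = NA,
                                  age_rule = c("any", "all"),
                                  mu = 1e-5, lam = 1e-3, seed = 1L) {
  family <- match.arg(family)
  age_rule <- match.arg(age_rule)
  set.seed(seed)
  if (n_points == 0)
    return(structure(data.frame(v1 = numeric(0), M = numeric(0),
                                accepted = logical(0)),
                     class = c("scan_result", "data.frame")))
  v <- exp(stats::runif(n_points, log(v_range[1]), log(v_range[2])))
  M <- exp(stats::runif(n_points, log(M_range[1]), log(M_range[2])))
  na <- length(ages)
  Vm <- matrix(NA_real_, n_points, na)
  Mn <- matrix(NA_real_, n_points, na)
  acc <- logical(n_points)
  for (i in seq_len(n_points)) {
    p <- switch(family,
      surface = model_params("surface", v1 = v[i], M = M[i], mu = 0,
                             n_max = 1L),
      surface_slowdown = model_params("surface_slowdown", v1 = v[i],
                                      M = M[i], mu = 0, lam = lam,
                                      n_max = 1L),
      surface_multi = model_params("surface", v1 = v[i], M = M[i], mu = mu,
                                   n_max = 12L))
    sol <- tryCatch(
      suppressWarnings(solve_exact(p, times = c(0, ages),
                                   n_types = if (family == "surface_multi") 10L else 1L)),
      error = function(e) NULL)
    if (is.null(sol)) next
    Vm[i, ] <- sol$V_tot[-1]
    Mn[i, ] <- sol$mean_n[-1]
    in_win <- Vm[i, ] >= size_window[1] & Vm[i, ] <= size_window[2]
    if (!is.na(mean_n_max)) in_win <- in_win & Mn[i, ] < mean_n_max
    acc[i] <- if (age_rule == "any") any(in_win) else all(in_win)
  }
  out <- data.frame(v1 = v, M = M, accepted = acc)
  for (j in seq_len(na)) {
    out[[paste0("V_age", j)]] <- Vm[, j]
    out[[paste0("mean_n_age", j)]] <- Mn[, j]
  }
  attr(out, "ages") <- ages
  attr(out, "size_window") <- size_window
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Log-log slope of the accepted band
#'
#' Linear regression of \code{log10 M} on \code{log10 v1} over accepted
#' points; the surface-growth scaling \code{G ~ (M v^3)^(1/3)} implies a
#' slope close to -3.
#'
#' @param scan a \code{scan_result}.
#' @return the fitted slope (NA if fewer than 3 accepted points).
#' @export
scan_band_slope <- function(scan) {
  a <- scan[scan$accepted, ]
  if (nrow(a) < 3) return(NA_real_)
  unname(stats::coef(stats::lm(log10(a$M) ~ log10(a$v1)))[2])
}
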