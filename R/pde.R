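# Direct numerical integration of the discretized age-structured equations
# -- the independent cross-check for the exact Laplace solution.

#' Integrate the age-structured lesion equations on a grid
#'
#' First-order explicit scheme: time is discretized in steps of
#' \code{dt} days and the age distribution of type-n lesions is stored as
#' counts per birth step.  Each step ages every cohort by one cell (the
#' transport part of the dynamics) and injects a new age-0 cohort from the
#' boundary sums over \code{phi_n r_n} (same-type seeding) and
#' \code{phi_(n-1) (1 - r_(n-1))} (seeding with one more driver), with
#' kernels evaluated at the cohort ages of the previous step (left-endpoint
#' quadrature).  Volumes and the mean driver count are quadrature sums over
#' the cohorts.
#'
#' @param params a \code{\link{model_params}} object.
#' @param dt time step in days (default 1, the reference resolution).
#' @param t_max horizon in days (default 15 years).
#' @param n_max number of lesion types tracked; the top type is absorbing
#'   (mutations out of it are suppressed) and an error is raised if it
#'   accumulates more than \code{top_type_tol} of the final volume.
#' @param output_every output cadence in steps (default 10).
#' @param top_type_tol truncation-bias guard threshold.
#' @return a data.frame with the same column layout as
#'   \code{\link{solve_exact}} (\code{t}, \code{N_n}, \code{V_n},
#'   \code{V_tot}, \code{mean_n}).
#' @export
integrate_pde <- function(params, dt = 1, t_max = 5475, n_max = params$n_max,
                          output_every = 10L, top_type_tol = 1e-3) {
  if (dt <= 0) stop("`dt` must be > 0")
  n_max <- as.integer(n_max)
  steps <- floor(t_max / dt)
  laws <- lapply(seq_len(n_max), function(n) make_growth_law(params, n))

  ages <- (0:steps) * dt
  # kernel tables: K[n, i+1] = phi_n(i dt) r_n(i dt), etc.
  Ktab <- t(vapply(laws, function(l) l$phi(ages) * l$r(ages),
                   numeric(steps + 1)))
  Ptab <- t(vapply(laws, function(l) l$phi(ages) * (1 - l$r(ages)),
                   numeric(steps + 1)))
  Vtab <- t(vapply(laws, function(l) l$V(ages), numeric(steps + 1)))

  # B[n, j+1] = number of type-n lesions born at step j (cohorts)
  B <- matrix(0, n_max, steps + 1)
  B[1, 1] <- 1

  out_steps <- seq(0, steps, by = output_every)
  Nout <- matrix(0, length(out_steps), n_max)
  Vout <- matrix(0, length(out_steps), n_max)
  oi <- 1L
  record <- function(tstep, oi) {
    for (n in seq_len(n_max)) {
      jj <- 1:(tstep + 1)                       # cohorts born at steps 0..tstep
      Nout[oi, n] <<- sum(B[n, jj])
      Vout[oi, n] <<- sum(B[n, jj] * Vtab[n, (tstep + 1):1])
    }
  }
  if (out_steps[1] == 0L) { record(0L, 1L); oi <- 2L }

  for (tstep in seq_len(steps)) {
    jj <- 1:tstep                               # previous-step cohorts 0..tstep-1
    arev <- tstep:1                             # their ages (in steps) last step + 1... see below
    # ages at the previous step: (tstep-1-j) dt for cohort j -> index tstep-j
    inj <- numeric(n_max)
    for (n in seq_len(n_max)) {
      own <- sum(B[n, jj] * Ktab[n, arev])
      cross <- if (n > 1) sum(B[n - 1, jj] * Ptab[n - 1, arev]) else 0
      inj[n] <- dt * (own + cross)
    }
    # absorbing top type: mutations out of n_max are suppressed, i.e. its
    # seeding uses phi (not phi r); add the (1-r) part back
    inj[n_max] <- inj[n_max] +
      dt * sum(B[n_max, jj] * Ptab[n_max, arev])
    B[cbind(seq_len(n_max), tstep + 1)] <- inj
    if (oi <= length(out_steps) && out_steps[oi] == tstep) {
      record(tstep, oi)
      oi <- oi + 1L
    }
  }

  Vtot <- rowSums(Vout)
  ilast <- length(out_steps)
  if (n_max > 1L && params$mu > 0 && Vtot[ilast] > 0 &&
      Vout[ilast, n_max] / Vtot[ilast] > top_type_tol)
    stop(sprintf(paste0("type n_max = %d holds %.2g%% of the final volume; ",
                        "the truncation biases the result, increase n_max"),
                 n_max, 100 * Vout[ilast, n_max] / Vtot[ilast]))

  mean_n <- ifelse(Vtot > 0, as.vector(Vout %*% seq_len(n_max)) / Vtot, 1)
  out <- data.frame(t = out_steps * dt, Nout, Vout, Vtot, mean_n)
  names(out) <- c("t", paste0("N_", seq_len(n_max)),
                  paste0("V_", seq_len(n_max)), "V_tot", "mean_n")
  attr(out, "dt") <- dt
  class(out) <- c("lesion_timeseries", "data.frame")
  out
}

#' Convergence of the grid integrator against the exact solution
#'
#' Integrates the same model at several step sizes and reports the maximum
#' relative error of the total volume against the exact Laplace solution.
#' The scheme is first order: errors decrease (approximately halve) as
#' \code{dt} halves.
#'
#' @param params a \code{\link{model_params}} object.
#' @param dts numeric vector of step sizes (days).
#' @param t_max horizon in days.
#' @param n_max types tracked.
#' @param t_min errors are measured for t >= t_min (relative error is not
#'   meaningful while the volume is below a few cells).
#' @return data.frame with columns \code{dt} and \code{max_rel_err_Vtot}.
#' @export
convergence_report <- function(params, dts = c(2, 1, 0.5), t_max = 1500,
                               n_max = 8, t_min = t_max / 10) {
  exact <- solve_exact(params, times = seq(0, t_max, by = 10),
                       n_types = min(n_max, 12))
  err <- vapply(dts, function(dt) {
    pde <- integrate_pde(params, dt = dt, t_max = t_max, n_max = n_max,
                         output_every = round(10 / dt))
    tt <- intersect(exact$t, pde$t)
    tt <- tt[tt >= t_min]
    ve <- exact$V_tot[match(tt, exact$t)]
    vp <- pde$V_tot[match(tt, pde$t)]
    max(abs(vp - ve) / pmax(ve, .Machine$double.eps))
  }, numeric(1))
  data.frame(dt = dts, max_rel_err_Vtot = err)
}
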