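# Large-time asymptotics: per-type growth rates, amplitude coefficients,
# and the exponential accumulation law for the mean driver count.
#
# Each per-type volume behaves as V_tot,n(t) ~ A_n t^k exp(G_n t) at late
# times.  For linear driver schedules the rate gaps G_{n+1} - G_n are
# constant, so the volume-weighted mean driver count grows exponentially
# (rate = the gap) and the total volume super-exponentially; with a
# slow-down the whole spectrum shifts by lambda and the gaps -- hence the
# driver accumulation rate -- are unchanged.

#' Closed-form growth rate, surface growth
#'
#' \code{G_n = (8 pi M)^(1/3) v_n - mu}; for the linear schedule
#' \code{v_n = n v_1} this is \code{n (8 pi M)^(1/3) v_1 - mu}.  Agrees with
#' the Euler-Lotka root of the corresponding kernel to 1e-10.
#'
#' @param params a \code{\link{model_params}} object (surface mode).
#' @param n lesion type; vectorized.
#' @return growth rate(s), 1/day.
#' @export
growth_rate_surface <- function(params, n) {
  (8 * pi * params$M)^(1 / 3) * driver_speed_schedule(params, n) - params$mu
}

#' Closed-form growth rate, slow-down surface growth
#'
#' The surface-growth rate shifted down by exactly \code{lam}; the gaps
#' \code{G_(n+1) - G_n} do not depend on \code{lam}.
#'
#' @param params a \code{\link{model_params}} object (slow-down mode; a
#'   plain surface parameter set with \code{lam = 0} is also accepted for
#'   the continuity limit).
#' @param n lesion type; vectorized.
#' @return growth rate(s), 1/day.
#' @export
growth_rate_slowdown <- function(params, n) {
  lam <- if (is.null(params$lam)) 0 else params$lam
  (8 * pi * params$M)^(1 / 3) * driver_speed_schedule(params, n) -
    params$mu - lam
}

#' Per-type asymptotic coefficients
#'
#' For each lesion type, the dominant large-t term of \code{V_tot,n(t)},
#' i.e. \code{A_n t^k exp(G_n t)}.  Computed exactly from the residues of
#' the inverted transforms (\code{method = "exact"}) or, for the surface
#' families with linear schedule, from the closed-form limit
#' \code{mu/G_1 -> 0} (\code{method = "limit"}):
#' \code{Res F_n~(G_n) = ((n-1)!)^2 (3 mu / (n D))^(n-1) n D /
#' (3 prod_(m<n)(n^2 + n m + m^2))} with \code{D = (8 pi M)^(1/3) v_1},
#' multiplied by the volume transform at \code{G_n}.
#'
#' @param params a \code{\link{model_params}} object.
#' @param n_types number of types.
#' @param method "exact" (residues) or "limit" (small-mu closed form).
#' @return data.frame with columns \code{n}, \code{G} (rate, 1/day),
#'   \code{power} (polynomial order \code{k}), \code{A} (amplitude).
#' @export
asymptotic_coefficients <- function(params, n_types = 8L,
                                    method = c("exact", "limit")) {
  method <- match.arg(method)
  n_types <- as.integer(n_types)
  if (method == "limit") {
    if (!params$growth_mode %in% c("surface", "surface_slowdown"))
      stop("the closed-form limit coefficients cover the surface families")
    if (params$schedule$type != "linear")
      stop("the closed-form limit coefficients cover the linear schedule")
    D <- (8 * pi * params$M)^(1 / 3) * params$v1
    mu <- params$mu
    G1 <- growth_rate_surface(params, 1) -
      (if (params$growth_mode == "surface_slowdown") params$lam else 0)
    if (mu / max(G1, .Machine$double.eps) > 0.1)
      warning("mu/G_1 > 0.1: outside the validity of the small-mu limit")
    out <- data.frame(n = seq_len(n_types), G = NA_real_, power = 0L,
                      A = NA_real_)
    for (n in seq_len(n_types)) {
      G <- if (params$growth_mode == "surface_slowdown")
        growth_rate_slowdown(params, n) else growth_rate_surface(params, n)
      m <- seq_len(max(n - 1, 0))
      resid <- if (n == 1) {
        # single-type: F~ = K/(1-K), residue of K/(1-K) at G: w/(3(G+mu)^2)
        D / 3
      } else {
        factorial(n - 1)^2 * (3 * mu / (n * D))^(n - 1) * n * D /
          (3 * prod(n^2 + n * m + m^2))
      }
      vn <- driver_speed_schedule(params, n)
      Vt_at_G <- if (params$growth_mode == "surface_slowdown") {
        8 * pi * vn^3 / (G * (G + params$lam)^3)
      } else 8 * pi * vn^3 / G^4
      out$G[n] <- G
      out$A[n] <- resid * Vt_at_G
    }
    return(out)
  }
  # exact residues via the partial-fraction machinery
  laws <- lapply(seq_len(n_types), function(n) make_growth_law(params, n))
  H <- cumulative_flux_transforms(laws)
  out <- data.frame(n = seq_len(n_types), G = NA_real_, power = NA_integer_,
                    A = NA_real_)
  for (n in seq_len(n_types)) {
    Ft <- if (n == 1) {
      if (rt_is_zero(laws[[1]]$K)) rational_transform(0)
      else rt_mul(laws[[1]]$K, H[[1]])
    } else H[[n]]
    if (rt_is_zero(Ft)) {
      out$G[n] <- -Inf; out$power[n] <- 0L; out$A[n] <- 0
      next
    }
    dom <- eps_dominant(invert_rational(rt_mul(Ft, laws[[n]]$Vt)))
    out$G[n] <- dom$rate
    out$power[n] <- dom$power
    out$A[n] <- dom$coef
  }
  out
}

#' Large-time asymptote of the mean driver count
#'
#' Builds the asymptote from the per-type dominant terms: the
#' volume-weighted mean of \code{n} over \code{A_n t^k exp(G_n t)}.  For
#' the slow-down family the common shift \code{-lam} cancels from the
#' weights, so the accumulation rate is independent of \code{lam}.  For the
#' volumetric family the limit method sums the generating-function series in
#' closed (Bessel) form, see \code{\link{z_volumetric}}.
#'
#' @param params a \code{\link{model_params}} object.
#' @param t times in days.
#' @param method "exact" residues or small-mu "limit" closed forms.
#' @param n_types number of types summed.
#' @return numeric vector of asymptotic mean driver counts.
#' @export
asymptotic_mean_drivers <- function(params, t, method = c("exact", "limit"),
                                    n_types = 8L) {
  method <- match.arg(method)
  if (params$mu == 0) return(rep(1, length(t)))
  if (method == "limit" && params$growth_mode == "volumetric") {
    y <- volumetric_y(params, t)
    x <- 2 * sqrt(y)
    return(1 + sqrt(y) * besselI(x, 1, expon.scaled = TRUE) /
             besselI(x, 0, expon.scaled = TRUE))
  }
  ac <- asymptotic_coefficients(params, n_types = n_types, method = method)
  vapply(t, function(ti) {
    logw <- log(pmax(abs(ac$A), 1e-300)) + ac$power * log(max(ti, 1e-300)) +
      ac$G * ti
    w <- sign(ac$A) * exp(logw - max(logw))
    sum(ac$n * w) / sum(w)
  }, numeric(1))
}

#' Large-time asymptote of the total volume
#'
#' Sum of the per-type dominant terms \code{A_n t^k exp(G_n t)}.  For linear
#' schedules the log-slope increases with time (super-exponential growth);
#' for the three-strong schedule with small residual advantage it
#' approaches a constant.
#'
#' @inheritParams asymptotic_mean_drivers
#' @return numeric vector of cell counts.
#' @export
asymptotic_volume <- function(params, t, method = c("exact", "limit"),
                              n_types = 8L) {
  method <- match.arg(method)
  if (method == "limit" && params$growth_mode == "volumetric") {
    # C e^{(b-M)t} I_0(2 sqrt(y)) with C matched to the exact type-1 term
    ac1 <- asymptotic_coefficients(params, n_types = 1L, method = "exact")
    y <- volumetric_y(params, t)
    x <- 2 * sqrt(y)
    return(ac1$A[1] * exp(ac1$G[1] * t + x) *
             besselI(x, 0, expon.scaled = TRUE))
  }
  ac <- asymptotic_coefficients(params, n_types = n_types, method = method)
  vapply(t, function(ti) {
    sum(ac$A * max(ti, 1e-300)^ac$power * exp(ac$G * ti))
  }, numeric(1))
}

# expansion variable of the volumetric generating function:
# y(t) = (M mu / b^2) exp(b t)
volumetric_y <- function(params, t) {
  b <- params$b
  params$M * params$mu / b^2 * exp(b * t)
}

#' Volumetric generating function Z(t, q)
#'
#' \code{Z(t, q) = sum_(n>=1) q^(n-1) y^(n-1) / ((n-1)!)^2} with
#' \code{y = (M mu / b^2) exp(b t)}: the generating function over types of
#' the dominant volumetric amplitudes, summed in closed form as the
#' modified Bessel function \code{I_0(2 sqrt(q y))}.  The mean driver count
#' asymptote is \code{1 + d log Z / d q} at \code{q = 1}.
#'
#' @param params a volumetric \code{\link{model_params}} object.
#' @param t time in days (scalar).
#' @param q generating variable (scalar, > 0).
#' @param method "bessel" (closed form) or "series" (direct summation, for
#'   cross-checking on small truncations).
#' @param terms number of series terms when \code{method = "series"}.
#' @return value of Z (may be large; computed unscaled).
#' @export
z_volumetric <- function(params, t, q = 1, method = c("bessel", "series"),
                         terms = 40L) {
  method <- match.arg(method)
  y <- volumetric_y(params, t)
  if (method == "bessel") return(besselI(2 * sqrt(q * y), 0))
  k <- 0:(terms - 1L)
  sum((q * y)^k / factorial(k)^2)
}

#' Crossover time of an asymptote
#'
#' The earliest time from which the asymptote tracks the exact solution:
#' detected as the earliest grid time where the asymptote/exact ratio
#' changes by less than 5 percent over the following factor-10 span.
#'
#' @param params a \code{\link{model_params}} object.
#' @param what "mean_n" or "V_tot".
#' @param t_range search range in days (log-spaced grid).
#' @param n_types types resolved.
#' @return crossover time in days (NA if not reached in the range).
#' @export
crossover_time <- function(params, what = c("mean_n", "V_tot"),
                           t_range = c(200, 20000), n_types = 8L) {
  what <- match.arg(what)
  tg <- exp(seq(log(t_range[1]), log(t_range[2]), length.out = 25))
  sol <- solve_exact(params, times = sort(unique(c(0, tg, 10 * tg))),
                     n_types = n_types)
  ex <- if (what == "mean_n") sol$mean_n else sol$V_tot
  asy <- if (what == "mean_n") asymptotic_mean_drivers(params, sol$t, n_types = n_types)
         else asymptotic_volume(params, sol$t, n_types = n_types)
  ratio <- asy / ex
  for (ti in tg) {
    r1 <- ratio[match(ti, sol$t)]
    r2 <- ratio[match(10 * ti, sol$t)]
    if (is.finite(r1) && is.finite(r2) && abs(r2 / r1 - 1) < 0.05) return(ti)
  }
  NA_real_
}
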