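# Hierarchical Laplace-domain solution of the age-structured lesion
# equations.
#
# Let f_n(a, t) be the expected number of type-n lesions of age a at time t,
# with one type-1 lesion of age 0 at t = 0.  Writing f_n(a, t) =
# F_n(t - a) + delta_{n,1} delta(t - a), the boundary condition (new lesions
# seeded by migration) becomes a renewal equation whose Laplace transform
# solves hierarchically:
#   F1~ = K1~ / (1 - K1~),
#   Fn~ = [prod_{m<n} Psi_m~] / [prod_{m<=n} (1 - K_m~)]      (n >= 2),
# where K_m~ = L[phi_m r_m] (same-type seeding) and Psi_m~ =
# L[phi_m (1 - r_m)] (seeding of the next type).  All kernels are rational,
# so each F_n inverts exactly to a finite sum of t^k exp(G t) terms.

poly_from_roots <- function(roots) {
  co <- 1 + 0i
  for (z in roots) co <- c(0 + 0i, co) - c(z * co, 0 + 0i)
  co   # ascending powers
}

poly_eval_c <- function(co, s) {
  acc <- 0 + 0i
  for (j in rev(seq_along(co))) acc <- acc * s + co[j]
  acc
}

# roots of 1 - K(s) = 0, i.e. of P(s) = prod(s - den) - const * prod(s - num)
flip_roots <- function(K) {
  den_poly <- poly_from_roots(K$den_roots)
  num_poly <- K$const * poly_from_roots(K$num_roots)
  length(num_poly) <- length(den_poly)
  num_poly[is.na(num_poly)] <- 0
  P <- den_poly - num_poly
  # coefficients are real up to rounding (roots close under conjugation)
  P <- complex(real = Re(P), imaginary = 0)
  r <- polyroot(Re(P))
  dP <- P[-1] * seq_len(length(P) - 1)
  for (it in 1:3) {       # Newton polish
    fr <- vapply(r, function(s) poly_eval_c(P, s), complex(1))
    dfr <- vapply(r, function(s) poly_eval_c(dP, s), complex(1))
    step <- ifelse(Mod(dfr) > 0, fr / dfr, 0)
    r <- r - step
  }
  r
}

#' Euler-Lotka growth rate of a seeding kernel
#'
#' Solves the renewal condition \code{K~(s) = 1} for the transform of the
#' same-type seeding kernel \code{phi_n r_n} and returns the root with the
#' largest real part -- the asymptotic exponential growth rate of the number
#' of lesions of that type.  The dominant root is asserted to be real
#' (Perron-type property of the model's kernels); negative values are
#' meaningful and mean the subpopulation cannot grow exponentially on its
#' own.  A kernel that is identically zero (no migration) returns
#' \code{-Inf}.
#'
#' @param kernel a \code{\link{rational_transform}} of \code{phi_n r_n}
#'   (e.g. the \code{K} element of a \code{\link{growth_law}}).
#' @param tol relative tolerance on the imaginary part of the dominant root.
#' @return growth rate G in 1/day.
#' @export
euler_lotka_root <- function(kernel, tol = 1e-8) {
  if (rt_is_zero(kernel)) return(-Inf)
  r <- flip_roots(kernel)
  dom <- r[which.max(Re(r))]
  if (abs(Im(dom)) > tol * max(1, abs(Re(dom))))
    stop("dominant Euler-Lotka root is complex; kernel not supported")
  Re(dom)
}

#' Laplace transform of the lesion-creation flux of type n
#'
#' Assembles \code{F_n~} from the growth laws of types \code{1..n}, keeping
#' the result root-factored.  Its poles are the Euler-Lotka roots of types
#' \code{1..n} together with the poles of the cross kernels.
#'
#' @param laws list of \code{\link{growth_law}} objects for types
#'   \code{1..n} (in order).
#' @return a \code{\link{rational_transform}}.
#' @export
build_Fn_transform <- function(laws) {
  n <- length(laws)
  H <- cumulative_flux_transforms(laws)[[n]]
  if (n == 1) {
    if (rt_is_zero(laws[[1]]$K)) return(rational_transform(0))
    return(rt_mul(laws[[1]]$K, H))
  }
  H
}

# H_n~ = F_n~ + delta_{n,1}: H_1 = 1/(1-K_1), H_n = H_{n-1} Psi_{n-1}/(1-K_n)
cumulative_flux_transforms <- function(laws) {
  out <- vector("list", length(laws))
  H <- rational_transform(1)
  for (m in seq_along(laws)) {
    if (m > 1) {
      Psi <- laws[[m - 1]]$Psi
      if (rt_is_zero(Psi)) {
        for (k in m:length(laws)) out[[k]] <- rational_transform(0)
        return(out)
      }
      H <- rt_mul(H, Psi)
    }
    K <- laws[[m]]$K
    if (!rt_is_zero(K)) {
      H <- rt_mul(H, rational_transform(1, num_roots = K$den_roots,
                                        den_roots = flip_roots(K)))
    }
    out[[m]] <- H
  }
  out
}

#' Expected number of type-n lesions
#'
#' \code{N_n(t)} is the founder indicator plus the time integral of the
#' lesion-creation flux \code{F_n}.
#'
#' @param F an \code{\link{exp_poly_sum}}: the inverted flux transform of
#'   type \code{n} (see \code{\link{build_Fn_transform}} and
#'   \code{\link{invert_rational}}).
#' @param t times in days, >= 0.
#' @param n lesion type (the founder term enters only for \code{n = 1}).
#' @return numeric vector \code{N_n(t)}; \code{N_1(0) = 1}.
#' @export
lesion_count <- function(F, t, n = 1L) {
  as.numeric(n == 1L) + eps_integral(F, t)
}

#' Total volume of cells in type-n lesions
#'
#' The convolution of the creation flux \code{F_n} with the single-lesion
#' volume \code{V_n}, i.e. the inverse transform of \code{F_n~ V_n~}, plus
#' the founder lesion's own volume for \code{n = 1}.
#'
#' @param Fn_transform \code{\link{rational_transform}} of the type-n flux.
#' @param law the \code{\link{growth_law}} of type n.
#' @param t times in days.
#' @return numeric vector \code{V_tot,n(t)} in cells.
#' @export
type_volume <- function(Fn_transform, law, t) {
  founder <- if (law$n == 1L) law$V(t) else 0
  if (rt_is_zero(Fn_transform)) return(founder + numeric(length(t)))
  eps <- invert_rational(rt_mul(Fn_transform, law$Vt))
  # the exact solution is non-negative; values at or below the residue
  # noise floor (well under one billionth of a cell) are truncated to zero
  out <- pmax(eps_eval(eps, t) + founder, 0)
  out[out < 1e-9] <- 0
  out
}

#' Exact solution of the multi-type lesion model
#'
#' Computes per-type lesion counts \code{N_n(t)}, per-type total volumes
#' \code{V_tot,n(t)}, the total tumour volume and the volume-weighted mean
#' driver count, by exact Laplace inversion.
#'
#' @param params a \code{\link{model_params}} object.
#' @param times output times in days (default every 10 days to 15 years).
#' @param n_types number of lesion types to resolve exactly (default
#'   \code{min(n_max, 12)}; contributions beyond that are negligible for the
#'   parameter regimes the model targets, and the top-type share is checked).
#' @param top_type_tol warn if the top resolved type carries more than this
#'   share of the final total volume (truncation bias guard).
#' @return a data.frame with columns \code{t}, \code{N_1..N_k},
#'   \code{V_1..V_k}, \code{V_tot}, \code{mean_n}, with attributes
#'   \code{growth_rates} (per-type Euler-Lotka roots) and \code{poles}
#'   (per-type pole sets of \code{F_n~}).
#' @export
solve_exact <- function(params, times = seq(0, 5475, by = 10),
                        n_types = min(params$n_max, 12L),
                        top_type_tol = 1e-3) {
  n_types <- as.integer(n_types)
  laws <- lapply(seq_len(n_types), function(n) make_growth_law(params, n))
  H <- cumulative_flux_transforms(laws)
  Fts <- vector("list", n_types)
  for (n in seq_len(n_types)) {
    if (n == 1) {
      Fts[[n]] <- if (rt_is_zero(laws[[1]]$K)) rational_transform(0)
                  else rt_mul(laws[[1]]$K, H[[1]])
    } else Fts[[n]] <- H[[n]]
  }
  # growth rates are reported as metadata; a kernel whose dominant root is
  # complex (possible for strongly clamped surfing fractions) yields NA
  # rather than aborting the solve
  G <- vapply(laws, function(l)
    tryCatch(euler_lotka_root(l$K), error = function(e) NA_real_),
    numeric(1))

  Nmat <- matrix(0, length(times), n_types)
  Vmat <- matrix(0, length(times), n_types)
  for (n in seq_len(n_types)) {
    if (!rt_is_zero(Fts[[n]])) {
      Fn <- invert_rational(Fts[[n]])
      Nmat[, n] <- lesion_count(Fn, times, n)
    } else Nmat[, n] <- as.numeric(n == 1L)
    Vmat[, n] <- type_volume(Fts[[n]], laws[[n]], times)
  }
  Vtot <- rowSums(Vmat)
  mean_n <- ifelse(Vtot > 0, as.vector(Vmat %*% seq_len(n_types)) / Vtot, 1)

  top_share <- Vmat[length(times), n_types] / max(Vtot[length(times)], .Machine$double.xmin)
  if (n_types > 1L && params$mu > 0 && is.finite(top_share) &&
      top_share > top_type_tol)
    warning(sprintf(paste0("top resolved type carries %.2g%% of the final ",
                           "volume; increase n_types"), 100 * top_share))

  out <- data.frame(t = times, Nmat, Vmat, Vtot, mean_n)
  names(out) <- c("t", paste0("N_", seq_len(n_types)),
                  paste0("V_", seq_len(n_types)), "V_tot", "mean_n")
  attr(out, "growth_rates") <- G
  attr(out, "poles") <- lapply(Fts, rt_poles)
  attr(out, "params") <- params
  class(out) <- c("lesion_timeseries", "data.frame")
  out
}

#' Volume-weighted mean driver count
#'
#' \code{<n(t)> = sum_n n V_tot,n(t) / V_tot(t)}.  Equals 1 identically when
#' \code{mu = 0}; at \code{t = 0} (zero volume in surface modes) the founder
#' limit 1 is returned.
#'
#' @param series a time series from \code{\link{solve_exact}},
#'   \code{\link{integrate_pde}} or a simulator (needs columns \code{t},
#'   \code{V_1..V_k}).
#' @param t times at which to evaluate (must lie in the series grid).
#' @return numeric vector of mean driver counts.
#' @export
mean_drivers <- function(series, t = series$t) {
  ix <- match(t, series$t)
  if (anyNA(ix)) stop("requested times are not on the series grid")
  vcols <- grep("^V_[0-9]+$", names(series))
  nn <- as.integer(sub("V_", "", names(series)[vcols]))
  V <- as.matrix(series[ix, vcols, drop = FALSE])
  vtot <- rowSums(V)
  bad <- vtot <= 0 & t > 0
  if (any(bad)) stop("zero total volume at positive time")
  unname(ifelse(vtot > 0, as.vector(V %*% nn) / vtot, 1))
}
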