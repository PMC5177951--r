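# Rational Laplace transforms kept in root-factored form
#
# Every seeding kernel and volume transform in the model is a proper rational
# function of the Laplace variable s.  Products of kernels across lesion
# types make expanded polynomial coefficients grow quickly and destroy the
# near-degenerate root structure (for small mutation rates the growth-rate
# roots of consecutive types almost coincide), so transforms are stored as
#   T(s) = const * prod(s - num_roots) / prod(s - den_roots)
# and only ever manipulated through their root multisets.  Expansion happens
# locally, inside the partial-fraction inversion.

#' Rational Laplace transform in root-factored form
#'
#' @param const scalar multiplier.
#' @param num_roots complex vector of numerator roots (possibly empty).
#' @param den_roots complex vector of denominator roots (poles, with
#'   multiplicity).
#' @return an object of class \code{rational_transform}.
#' @export
rational_transform <- function(const, num_roots = complex(0), den_roots = complex(0)) {
  structure(list(const = as.complex(const),
                 num_roots = as.complex(num_roots),
                 den_roots = as.complex(den_roots)),
            class = "rational_transform")
}

#' @export
print.rational_transform <- function(x, ...) {
  cat("<rational_transform> const =", format(x$const),
      "| deg num =", length(x$num_roots),
      "| deg den =", length(x$den_roots), "\n")
  invisible(x)
}

rt_is_proper <- function(rt) length(rt$num_roots) < length(rt$den_roots)

rt_is_zero <- function(rt) Mod(rt$const) == 0

#' Multiply rational transforms
#'
#' Root multisets are concatenated and exactly coincident numerator and
#' denominator roots cancelled, so products stay factored.
#' @param a,b \code{rational_transform} objects.
#' @return their product as a \code{rational_transform}.
#' @export
rt_mul <- function(a, b) {
  rt_cancel(rational_transform(a$const * b$const,
                               c(a$num_roots, b$num_roots),
                               c(a$den_roots, b$den_roots)))
}

# remove numerator/denominator root pairs that coincide to near machine
# precision (these arise by construction when kernels share factors)
rt_cancel <- function(rt, tol = 1e-12) {
  if (length(rt$num_roots) == 0 || length(rt$den_roots) == 0) return(rt)
  num <- rt$num_roots; den <- rt$den_roots
  scale <- max(1, Mod(c(num, den)))
  keep_d <- rep(TRUE, length(den))
  keep_n <- rep(TRUE, length(num))
  for (i in seq_along(num)) {
    j <- which(keep_d & Mod(den - num[i]) <= tol * scale)
    if (length(j) > 0) {
      keep_d[j[1]] <- FALSE
      keep_n[i] <- FALSE
    }
  }
  rational_transform(rt$const, num[keep_n], den[keep_d])
}

#' Evaluate a rational transform
#'
#' @param rt a \code{rational_transform}.
#' @param s numeric or complex vector of Laplace-variable values.
#' @return complex vector of the same length as \code{s}.
#' @export
rt_eval <- function(rt, s) {
  s <- as.complex(s)
  vapply(s, function(si) {
    num <- if (length(rt$num_roots)) prod(si - rt$num_roots) else 1 + 0i
    den <- if (length(rt$den_roots)) prod(si - rt$den_roots) else 1 + 0i
    rt$const * num / den
  }, complex(1))
}

#' Poles of a rational transform
#' @param rt a \code{rational_transform}.
#' @return complex vector of denominator roots (with multiplicity).
#' @export
rt_poles <- function(rt) rt$den_roots

# ---- truncated power-series helpers (complex coefficient vectors, the
#      j-th element is the coefficient of u^(j-1)) ----

ser_mul_linear <- function(ser, a, len) {
  # multiply series by (a + u), truncate to `len` terms
  out <- a * ser
  shifted <- c(0, ser[-length(ser)])
  out <- out + shifted
  length(out) <- len
  out[is.na(out)] <- 0
  out
}

ser_prod_linears <- function(constants, len) {
  # product over i of (constants[i] + u), truncated
  ser <- c(1 + 0i, rep(0 + 0i, len - 1))
  for (a in constants) ser <- ser_mul_linear(ser, a, len)
  ser
}

ser_div <- function(num, den, len) {
  # power-series division num/den, den[1] != 0
  out <- complex(len)
  for (j in seq_len(len)) {
    acc <- if (j <= length(num)) num[j] else 0 + 0i
    if (j > 1) acc <- acc - sum(den[2:j] * out[(j - 1):1])
    out[j] <- acc / den[1]
  }
  out
}

# ---- root clustering ----

cluster_roots <- function(roots, tol) {
  # single-linkage clustering of complex roots at relative tolerance `tol`
  m <- length(roots)
  scale <- max(1, Mod(roots))
  id <- seq_len(m)
  if (m > 1) {
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      if (Mod(roots[i] - roots[j]) <= tol * scale) {
        old <- id[j]; id[id == old] <- id[i]
      }
    }
  }
  split(seq_len(m), id)
}

#' Invert a proper rational transform to closed form
#'
#' Exact partial-fraction inversion.  Denominator roots closer than
#' \code{multiplicity_tol} (relative) are merged into one root of higher
#' multiplicity, contributing \code{t^k exp(p t)} terms; the inverse of
#' \code{c/(s-p)^(k+1)} is \code{c t^k exp(p t)/k!}.  The result is checked
#' by forward-transforming it back at real points above all poles.
#'
#' @param rt a proper \code{rational_transform}.
#' @param multiplicity_tol relative tolerance for merging clustered roots.
#' @param check_tol relative tolerance of the forward-transform round-trip
#'   check (raises an error when exceeded, signalling ill-conditioned
#'   residues).
#' @return an \code{\link{exp_poly_sum}}.
#' @export
invert_rational <- function(rt, multiplicity_tol = 1e-8, check_tol = 1e-6) {
  if (rt_is_zero(rt))
    return(exp_poly_sum(complex(0), integer(0), complex(0)))
  if (!rt_is_proper(rt))
    stop("transform is not proper (numerator degree >= denominator degree)")
  clusters <- cluster_roots(rt$den_roots, multiplicity_tol)
  centers <- vapply(clusters, function(ix) mean(rt$den_roots[ix]), complex(1))

  coefs <- complex(0); powers <- integer(0); rates <- complex(0)
  for (ci in seq_along(clusters)) {
    p <- centers[ci]
    k <- length(clusters[[ci]])
    others <- rt$den_roots[-clusters[[ci]]]
    # Taylor-expand const * prod(p + u - z_num) / prod(p + u - z_other).
    # The local variable is rescaled by the geometric-mean distance to the
    # other singular points and the overall magnitude carried in log space
    # (raw magnitudes straddle the double exponent range for deep
    # hierarchies); the series arithmetic runs in compensated double-double
    # (see dd.R).
    cn <- p - rt$num_roots
    cd <- p - others
    dists <- Mod(c(cn, cd)); dists <- dists[dists > 0]
    rho <- if (length(dists)) exp(mean(log(dists))) else 1
    num_ser <- cdd_ser_prod_linears(cn / rho, k)
    h <- if (length(cd)) {
      den_ser <- cdd_ser_prod_linears(cd / rho, k)
      cdd_value(cdd_ser_div(num_ser, den_ser, k))
    } else cdd_value(num_ser)
    # T(s) ~ sum_j h_j (s-p)^(j-k)  ->  terms h_j t^(k-j-1) e^(pt)/(k-j-1)!
    j <- seq_len(k) - 1L
    pw <- k - j - 1L
    logmag <- log(Mod(rt$const)) + log(pmax(Mod(h), 1e-300)) +
      log(rho) * (length(cn) - length(cd) - j) - lgamma(pw + 1)
    cf <- ifelse(Mod(h) == 0, 0 + 0i,
                 exp(logmag) * complex(argument = Arg(rt$const) + Arg(h)))
    coefs <- c(coefs, cf)
    powers <- c(powers, pw)
    rates <- c(rates, rep(p, k))
  }
  eps <- exp_poly_sum(coefs, powers, rates)
  eps <- eps_symmetrize(eps)

  # Round-trip check at real s above all poles.  Points are taken at a
  # distance comparable to the pole-set diameter: far from the poles the
  # partial-fraction form cancels catastrophically by construction (the
  # rational decays much faster than its individual terms), which says
  # nothing about the quality of the residues, so the admissible error is
  # floored at machine precision times the term-magnitude sum.
  d <- max(Mod(rt$den_roots - rt$den_roots[which.max(Re(rt$den_roots))]), 1e-9)
  s_test <- max(Re(rt$den_roots)) + d * c(0.51, 1.03, 2.07)
  T_direct <- rt_eval(rt, s_test)
  T_round <- eps_laplace(eps, s_test)
  tsum <- vapply(s_test, function(si)
    sum(Mod(eps$coef) * factorial(eps$power) / Mod(si - eps$rate)^(eps$power + 1)),
    numeric(1))
  # the admissible absolute error combines the relative tolerance on T with
  # a term-magnitude floor: the forward sum cancels far below its term
  # magnitudes by construction, and coefficients carry ~1e-13 relative
  # accuracy, so discrepancies below 1e-13 * tsum are representation noise
  excess <- Mod(T_round - T_direct) /
    pmax(check_tol * Mod(T_direct) + 1e-13 * tsum, 1e-300)
  if (any(excess > 1))
    stop(sprintf(paste0("partial-fraction inversion failed the round-trip ",
                        "check (error %.2e times the admissible level); ",
                        "residues are ill-conditioned for this parameter ",
                        "combination"),
                 max(excess)))
  eps
}
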