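# Finite sums of c * t^k * exp(s t) -- the time-domain image of every
# rational transform in the model.

#' Exponential-polynomial sum
#'
#' A finite sum of terms \code{c * t^k * exp(s t)} with complex coefficient
#' \code{c} and rate \code{s} and non-negative integer power \code{k}.  All
#' closed-form time courses of the model (lesion counts, per-type volumes)
#' live in this algebra.  Term sets are closed under complex conjugation so
#' evaluation at real times is real.
#'
#' @param coef complex coefficients.
#' @param power non-negative integer powers of t.
#' @param rate complex exponential rates (1/day).
#' @return an object of class \code{exp_poly_sum}.
#' @export
exp_poly_sum <- function(coef, power, rate) {
  stopifnot(length(coef) == length(power), length(coef) == length(rate))
  if (any(power < 0)) stop("powers must be non-negative integers")
  structure(list(coef = as.complex(coef), power = as.integer(power),
                 rate = as.complex(rate)),
            class = "exp_poly_sum")
}

#' @export
print.exp_poly_sum <- function(x, ...) {
  cat("<exp_poly_sum>", length(x$coef), "terms\n")
  if (length(x$coef)) {
    ord <- order(-Re(x$rate), -x$power)
    show <- utils::head(ord, 8)
    for (i in show)
      cat(sprintf("  (%s) * t^%d * exp((%s) t)\n",
                  format(x$coef[i], digits = 4), x$power[i],
                  format(x$rate[i], digits = 6)))
    if (length(x$coef) > 8) cat("  ...\n")
  }
  invisible(x)
}

eps_n_terms <- function(eps) length(eps$coef)

# pair terms whose rates are complex conjugates and enforce exact conjugate
# symmetry of the coefficients (removes numerical asymmetry from clustering)
eps_symmetrize <- function(eps, tol = 1e-9) {
  m <- length(eps$coef)
  if (m == 0) return(eps)
  scale <- max(1, Mod(eps$rate))
  used <- rep(FALSE, m)
  for (i in seq_len(m)) {
    if (used[i] || abs(Im(eps$rate[i])) <= tol * scale) next
    j <- which(!used & seq_len(m) != i & eps$power == eps$power[i] &
                 Mod(eps$rate - Conj(eps$rate[i])) <= tol * scale)
    if (length(j)) {
      j <- j[1]
      c1 <- (eps$coef[i] + Conj(eps$coef[j])) / 2
      r1 <- (eps$rate[i] + Conj(eps$rate[j])) / 2
      eps$coef[i] <- c1; eps$coef[j] <- Conj(c1)
      eps$rate[i] <- r1; eps$rate[j] <- Conj(r1)
      used[i] <- used[j] <- TRUE
    }
  }
  eps
}

eps_add <- function(a, b) {
  exp_poly_sum(c(a$coef, b$coef), c(a$power, b$power), c(a$rate, b$rate))
}

eps_scale <- function(eps, x) {
  exp_poly_sum(eps$coef * x, eps$power, eps$rate)
}

#' Evaluate an exponential-polynomial sum at real times
#'
#' Values whose terms exceed the double-precision exponent range are
#' returned as \code{Inf} with a warning.  The imaginary residue of the
#' complex sum is checked to be below \code{1e-10} relative before the real
#' part is returned.
#'
#' @param eps an \code{exp_poly_sum}.
#' @param t numeric vector of times (days), >= 0.
#' @return numeric vector of values.
#' @export
eps_eval <- function(eps, t) {
  if (any(t < 0)) stop("negative times are not in the model's domain")
  if (length(eps$coef) == 0) return(numeric(length(t)))
  out <- numeric(length(t))
  logt <- ifelse(t > 0, log(t), -Inf)
  for (i in seq_along(t)) {
    logmag <- log(pmax(Mod(eps$coef), 1e-300)) + eps$power * max(logt[i], -745) +
      Re(eps$rate) * t[i]
    if (any(logmag > 700)) {
      warning("value exceeds double-precision range; returning Inf")
      out[i] <- Inf
      next
    }
    tp <- if (t[i] == 0) as.numeric(eps$power == 0L) else t[i]^eps$power
    terms <- eps$coef * tp * exp(eps$rate * t[i])
    val <- sum(terms)
    # the imaginary part must vanish up to coefficient-level noise
    # (~1e-13 relative to the term magnitudes, which may cancel deeply)
    if (abs(Im(val)) > 1e-10 * Mod(val) + 1e-12 * sum(Mod(terms)))
      warning(sprintf("imaginary residue %.2e above tolerance", abs(Im(val))))
    out[i] <- Re(val)
  }
  out
}

# closed-form integral  int_0^t tau^k exp(p tau) dtau  for scalar (k, p) and
# vector t; series form when the exponent argument is moderate, stable
# by-parts closed form when it is large
int_power_exp <- function(k, p, t) {
  if (Mod(p) < 1e-300) return(t^(k + 1) / (k + 1))
  out <- complex(length(t))
  z <- p * t
  small <- Mod(z) <= k + 20
  if (any(small)) {
    for (i in which(small)) {
      term <- 1 / (k + 1)
      acc <- term
      j <- 0
      repeat {
        j <- j + 1
        term <- term * z[i] / j * (k + j) / (k + j + 1)
        acc <- acc + term
        if (Mod(term) <= 1e-17 * Mod(acc) || j > 500) break
      }
      out[i] <- acc * t[i]^(k + 1)
    }
  }
  if (any(!small)) {
    jj <- 0:k
    fall <- factorial(k) / factorial(k - jj)   # k!/(k-j)!
    for (i in which(!small)) {
      s1 <- sum((-1)^jj * fall * t[i]^(k - jj) / p^(jj + 1))
      out[i] <- exp(z[i]) * s1 - (-1)^k * factorial(k) / p^(k + 1)
    }
  }
  out
}

#' Integrate an exponential-polynomial sum from 0 to t
#'
#' Term-wise closed-form integration (used for lesion counts, which are time
#' integrals of the lesion-creation flux).
#'
#' @param eps an \code{exp_poly_sum}.
#' @param t numeric vector of times (days), >= 0.
#' @return numeric vector of \code{int_0^t eps}.
#' @export
eps_integral <- function(eps, t) {
  if (any(t < 0)) stop("negative times are not in the model's domain")
  if (length(eps$coef) == 0) return(numeric(length(t)))
  acc <- complex(length(t))
  mag <- numeric(length(t))
  for (i in seq_along(eps$coef)) {
    term <- eps$coef[i] * int_power_exp(eps$power[i], eps$rate[i], t)
    acc <- acc + term
    mag <- mag + Mod(term)
  }
  if (any(abs(Im(acc)) > 1e-8 * Mod(acc) + 1e-12 * mag))
    warning("imaginary residue above tolerance in eps_integral")
  Re(acc)
}

#' Forward Laplace transform of an exponential-polynomial sum
#'
#' Closed form: \code{c t^k exp(p t)} transforms to
#' \code{c k! / (s - p)^(k+1)}.
#'
#' @param eps an \code{exp_poly_sum}.
#' @param s numeric or complex vector, \code{Re(s)} above all rates.
#' @return complex vector.
#' @export
eps_laplace <- function(eps, s) {
  s <- as.complex(s)
  vapply(s, function(si)
    sum(eps$coef * factorial(eps$power) / (si - eps$rate)^(eps$power + 1)),
    complex(1))
}

# dominant term(s): the largest real-part rate (merging its conjugate), with
# the highest power at that rate; returns list(rate, power, coef) where coef
# combines the conjugate pair so that coef * t^power * exp(rate t) is real
eps_dominant <- function(eps, tol = 1e-9) {
  if (length(eps$coef) == 0) return(NULL)
  scale <- max(1, Mod(eps$rate))
  rmax <- max(Re(eps$rate))
  at <- which(Re(eps$rate) >= rmax - tol * scale & abs(Im(eps$rate)) <= 1e-6 * scale)
  if (length(at) == 0) at <- which.max(Re(eps$rate))
  pmax_ <- max(eps$power[at])
  at <- at[eps$power[at] == pmax_]
  list(rate = Re(mean(eps$rate[at])), power = pmax_, coef = Re(sum(eps$coef[at])))
}
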