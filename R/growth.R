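# Deterministic single-lesion laws
#
# A lesion of type n is described by the triple {V_n(a), phi_n(a), r_n(a)}:
# volume in cells, lesion-seeding rate (1/day) and the fraction of
# migration-competent cells still carrying exactly n drivers.  Each law also
# carries exact Laplace-transform descriptors of phi_n*r_n ("K", the renewal
# kernel of same-type seeding), phi_n*(1-r_n) ("Psi", the cross kernel
# feeding type n+1) and V_n ("Vt"), in root-factored rational form.

#' Single-lesion growth law
#'
#' Builds the growth law of a type-\code{n} lesion under the growth mode,
#' driver schedule and mutant-fraction kernel of \code{params}.  Usually
#' called via \code{\link{make_surface_law}}, \code{\link{make_slowdown_law}}
#' or \code{\link{make_volumetric_law}}.
#'
#' @param params a \code{\link{model_params}} object.
#' @param n lesion type (founder driver count), 1 <= n <= \code{n_max}.
#' @return an object of class \code{growth_law} with elements \code{V},
#'   \code{phi}, \code{r} (vectorized functions of age in days), the
#'   transforms \code{K}, \code{Psi}, \code{Vt}
#'   (\code{\link{rational_transform}}s), the type \code{n}, the per-type
#'   speed/rate, and the validity window of \code{r}.
#' @export
make_growth_law <- function(params, n) {
  n <- as.integer(n)
  if (n < 1L) stop("lesion type `n` must be >= 1")
  if (n > params$n_max) stop("lesion type `n` exceeds n_max")
  switch(params$growth_mode,
         surface = make_surface_law(params, n),
         surface_slowdown = make_slowdown_law(params, n),
         volumetric = make_volumetric_law(params, n))
}

check_age <- function(a) {
  if (any(a < 0)) stop("lesion age must be >= 0")
  a
}

#' Surface growth law
#'
#' Cells replicate only in a thin layer at the lesion surface, so the radius
#' grows linearly in age with speed \code{v_n} and
#' \code{V_n(a) = (4 pi/3) (v_n a)^3} cells.  A dimensionless fraction
#' \code{M} of surface cells migrates, giving the seeding rate
#' \code{phi_n(a) = 4 pi M v_n^3 a^2} whose Laplace transform is
#' \code{8 pi M v_n^3 / s^3}.
#'
#' @inheritParams make_growth_law
#' @return a \code{growth_law}; see \code{\link{make_growth_law}}.
#' @export
make_surface_law <- function(params, n) {
  if (params$growth_mode != "surface")
    stop("make_surface_law requires growth_mode = 'surface'")
  v <- driver_speed_schedule(params, n)
  mf <- make_mutant_fraction(params, n)
  w <- 8 * pi * params$M * v^3          # transform of phi is w/s^3
  law <- list(
    n = n, mode = "surface", speed = v,
    V = function(a) (4 * pi / 3) * (v * check_age(a))^3,
    phi = function(a) 4 * pi * params$M * v^3 * check_age(a)^2,
    r = mf$r,
    Vt = rational_transform(8 * pi * v^3, den_roots = rep(0 + 0i, 4)),
    K = phi_r_transform(w, shift = 0, mf),
    Psi = phi_1mr_transform(w, shift = 0, mf),
    validity = mf$validity, r_model = params$r_model$type
  )
  structure(law, class = "growth_law")
}

#' Slow-down surface growth law
#'
#' Surface growth whose replication decays exponentially at rate
#' \code{lam}: \code{phi_n(a) = 4 pi M v_n^3 a^2 exp(-lam a)} and the
#' consistent sigmoid volume
#' \code{V_n(a) = (4 pi v_n^3/lam^3) [2 - exp(-lam a)(lam^2 a^2 + 2 lam a + 2)]},
#' which saturates at \code{8 pi v_n^3 / lam^3} and reduces to the plain
#' surface law as \code{lam -> 0}.  The single-type growth rate is
#' \code{(8 pi M)^{1/3} v - lam} (minus \code{mu} with mutation), i.e. the
#' surface-growth rate shifted down by exactly \code{lam}.
#'
#' @inheritParams make_growth_law
#' @return a \code{growth_law}; see \code{\link{make_growth_law}}.
#' @export
make_slowdown_law <- function(params, n) {
  if (params$growth_mode != "surface_slowdown")
    stop("make_slowdown_law requires growth_mode = 'surface_slowdown'")
  lam <- params$lam
  if (is.null(lam) || lam <= 0) stop("slow-down law requires `lam` > 0")
  v <- driver_speed_schedule(params, n)
  mf <- make_mutant_fraction(params, n)
  w <- 8 * pi * params$M * v^3
  law <- list(
    n = n, mode = "surface_slowdown", speed = v,
    V = function(a) {
      x <- lam * check_age(a)
      # 2 - exp(-x)(x^2 + 2x + 2) = x^3/3 - x^4/4 + x^5/10 - ... cancels
      # catastrophically for small x; switch to the series there
      f <- numeric(length(x))
      big <- x >= 0.05
      f[big] <- 2 - exp(-x[big]) * (x[big]^2 + 2 * x[big] + 2)
      if (any(!big)) {
        xs <- x[!big]
        m <- 3:12
        cm <- (-1)^(m + 1) * (2 / factorial(m) - 2 / factorial(m - 1) +
                                1 / factorial(m - 2))
        f[!big] <- drop(outer(xs, m, `^`) %*% cm)
      }
      (4 * pi * v^3 / lam^3) * f
    },
    phi = function(a) 4 * pi * params$M * v^3 * check_age(a)^2 * exp(-lam * a),
    r = mf$r,
    # L[V] = 8 pi v^3 / (s (s+lam)^3)
    Vt = rational_transform(8 * pi * v^3,
                            den_roots = c(0, rep(-lam + 0i, 3))),
    K = phi_r_transform(w, shift = lam, mf),
    Psi = phi_1mr_transform(w, shift = lam, mf),
    validity = mf$validity, r_model = params$r_model$type
  )
  structure(law, class = "growth_law")
}

#' Volumetric growth law
#'
#' All cells replicate (net rate \code{b_n}) and migrate (rate \code{M}
#' per cell per day), so single lesions grow exponentially.  Under the
#' default exponent convention (\code{volumetric_exponent = "b_minus_M"})
#' migrating cells deplete the lesion, \code{V_n(a) = exp((b_n - M) a)} and
#' \code{phi_n(a) = M V_n(a)}; the single-type renewal equation then gives a
#' tumour growth rate of exactly \code{b}.  The alternative convention
#' \code{"b"} uses \code{V_n(a) = exp(b_n a)}.
#'
#' @inheritParams make_growth_law
#' @return a \code{growth_law}; see \code{\link{make_growth_law}}.
#' @export
make_volumetric_law <- function(params, n) {
  if (params$growth_mode != "volumetric")
    stop("make_volumetric_law requires growth_mode = 'volumetric'")
  bn <- driver_speed_schedule(params, n)
  if (bn <= 0) stop("net replication rate must be > 0")
  alpha <- if (params$volumetric_exponent == "b_minus_M") bn - params$M else bn
  mf <- make_mutant_fraction(params, n)
  law <- list(
    n = n, mode = "volumetric", speed = bn, alpha = alpha,
    V = function(a) exp(alpha * check_age(a)),
    phi = function(a) params$M * exp(alpha * check_age(a)),
    r = mf$r,
    Vt = rational_transform(1, den_roots = alpha + 0i),
    K = phi_r_transform_vol(params$M, alpha, mf),
    Psi = phi_1mr_transform_vol(params$M, alpha, mf),
    validity = mf$validity, r_model = params$r_model$type
  )
  structure(law, class = "growth_law")
}

#' @export
print.growth_law <- function(x, ...) {
  cat("<growth_law> type n =", x$n, "|", x$mode, "| speed/rate =", x$speed,
      "| r:", x$r_model, "\n")
  invisible(x)
}

# ---- mutant-fraction kernels -------------------------------------------

#' Mutant fraction r_n(a)
#'
#' The fraction of migration-competent cells in a type-\code{n} lesion of
#' age \code{a} that still carry exactly \code{n} drivers.  Three kernels:
#' \describe{
#'   \item{exponential}{\code{r_n(a) = exp(-mu a)}: surface cells mutate at
#'     a small rate \code{mu} and the mutants' selective advantage inside
#'     the lesion is neglected.}
#'   \item{quadratic_surfing}{\code{r_n(a) = 1 - eta_n a^2}: mutants arise
#'     on an expanding front and survive ("surf") with probability
#'     \code{c/a}; \code{eta_n} is either supplied directly or computed as
#'     \code{c p_mu v_n (v_{n+1}^2 - v_n^2)}, which vanishes when the next
#'     driver confers no speed advantage.  Valid for
#'     \code{a < eta_n^{-1/2}}; beyond that \code{r} is clamped to 0 with a
#'     warning.}
#'   \item{logistic_taylor}{Taylor truncation (configurable order) of the
#'     logistic mutant-takeover solution
#'     \code{1 - r = mu (e^{g a} - 1) / (Db + mu e^{g a})} with
#'     \code{g = Db + mu} and \code{Db} the per-driver growth-rate
#'     increment; agrees with \code{exp(-mu a)} for \code{a << 1/mu}.}
#' }
#'
#' @inheritParams make_growth_law
#' @return a list with the vectorized function \code{r(a)}, the kernel type,
#'   polynomial/exponential descriptors used to assemble transforms, and the
#'   validity window (days).
#' @export
make_mutant_fraction <- function(params, n) {
  mu <- params$mu
  type <- params$r_model$type
  if (type == "exponential" || mu == 0 && type != "quadratic_surfing") {
    return(list(type = "exponential", mu = mu,
                r = function(a) exp(-mu * check_age(a)),
                validity = c(0, Inf)))
  }
  if (type == "quadratic_surfing") {
    eta <- quadratic_eta(params, n)
    a_star <- if (eta > 0) 1 / sqrt(eta) else Inf
    warned <- FALSE
    rfun <- function(a) {
      a <- check_age(a)
      if (any(a >= a_star) && !warned) {
        warned <<- TRUE
        warning(sprintf(paste0("quadratic surfing fraction clamped to 0 at ",
                               "ages >= %.6g days (outside its validity ",
                               "window)"), a_star))
      }
      pmax(1 - eta * a^2, 0)
    }
    return(list(type = "quadratic_surfing", eta = eta,
                r = rfun, validity = c(0, a_star)))
  }
  # logistic_taylor
  ord <- params$r_model$order
  db <- growth_rate_increment(params, n)
  g <- db + mu
  # Taylor series of x(a) = mu (e^{ga} - 1) / (db + mu e^{ga}) to `ord`
  len <- ord + 1L
  E <- g^(0:ord) / factorial(0:ord)
  numc <- mu * (E - c(1, rep(0, ord)))
  denc <- mu * E + c(db, rep(0, ord))
  x_ser <- Re(ser_div(as.complex(numc), as.complex(denc), len))
  r_ser <- c(1, rep(0, ord)) - x_ser        # coefficients of r(a) in a^j
  a_star <- if (g > 0) 1 / g else Inf       # truncation trustworthy below this
  list(type = "logistic_taylor", coef = r_ser, order = ord,
       r = function(a) {
         a <- check_age(a)
         out <- numeric(length(a))
         for (j in seq_along(r_ser)) out <- out + r_ser[j] * a^(j - 1)
         pmin(pmax(out, 0), 1)
       },
       validity = c(0, a_star))
}

quadratic_eta <- function(params, n) {
  rm <- params$r_model
  if (!is.null(rm$eta)) {
    if (length(rm$eta) >= n) return(rm$eta[n]) else return(rm$eta[length(rm$eta)])
  }
  vn <- driver_speed_schedule(params, n)
  vn1 <- driver_speed_schedule(params, n + 1)
  rm$c * rm$p_mu * vn * (vn1^2 - vn^2)
}

growth_rate_increment <- function(params, n) {
  if (params$growth_mode == "volumetric") {
    driver_speed_schedule(params, n + 1) - driver_speed_schedule(params, n)
  } else {
    (8 * pi * params$M)^(1 / 3) *
      (driver_speed_schedule(params, n + 1) - driver_speed_schedule(params, n))
  }
}

# ---- transform assembly -------------------------------------------------
# Surface-type seeding: phi(a) = (w/2) a^2 e^{-shift a}, transform w/(s+shift)^3
# (shift = 0 plain surface, shift = lam slow-down).

phi_r_transform <- function(w, shift, mf) {
  if (w == 0) return(rational_transform(0))
  if (mf$type == "exponential") {
    mu <- mf$mu
    return(rational_transform(w, den_roots = rep(-shift - mu + 0i, 3)))
  }
  if (mf$type == "quadratic_surfing") {
    # L[(w/2)(a^2 - eta a^4) e^{-shift a}] = w[(s+shift)^2 - 12 eta]/(s+shift)^5
    eta <- mf$eta
    if (eta == 0) return(rational_transform(w, den_roots = rep(-shift + 0i, 3)))
    return(rational_transform(w,
                              num_roots = -shift + c(1, -1) * sqrt(12 * eta),
                              den_roots = rep(-shift + 0i, 5)))
  }
  # logistic_taylor: r = sum_j c_j a^j -> phi r = (w/2) sum_j c_j a^{j+2} e^{-shift a}
  poly_exp_transform(mf$coef * w / 2, shift)
}

phi_1mr_transform <- function(w, shift, mf) {
  if (w == 0) return(rational_transform(0))
  if (mf$type == "exponential") {
    mu <- mf$mu
    if (mu == 0) return(rational_transform(0))
    # w[(s+shift+mu)^3 - (s+shift)^3] / ((s+shift)^3 (s+shift+mu)^3)
    num_roots <- -shift + mu * (-3 + c(1, -1) * sqrt(3) * 1i) / 6
    return(rational_transform(3 * mu * w, num_roots = num_roots,
                              den_roots = c(rep(-shift + 0i, 3),
                                            rep(-shift - mu + 0i, 3))))
  }
  if (mf$type == "quadratic_surfing") {
    # L[(w/2) eta a^4 e^{-shift a}] = 12 w eta / (s+shift)^5
    eta <- mf$eta
    if (eta == 0) return(rational_transform(0))
    return(rational_transform(12 * w * eta, den_roots = rep(-shift + 0i, 5)))
  }
  co <- -mf$coef; co[1] <- co[1] + 1        # 1 - r coefficients
  poly_exp_transform(co * w / 2, shift)
}

# L[ sum_j c_j a^{j+2} e^{-shift a} ] = sum_j c_j (j+2)! / (s+shift)^{j+3}
poly_exp_transform <- function(co, shift) {
  jj <- seq_along(co) - 1L
  deg <- max(jj) + 3L
  # numerator polynomial in u = s + shift: sum_j c_j (j+2)! u^{deg-j-3}
  pc <- numeric(deg)                         # ascending powers of u, deg terms
  for (j in jj) pc[deg - j - 2L] <- co[j + 1L] * factorial(j + 2L)
  nz <- which(pc != 0)
  if (length(nz) == 0) return(rational_transform(0))
  lead <- max(nz)
  pc <- pc[seq_len(lead)]
  roots_u <- if (lead > 1) polyroot(pc) else complex(0)
  rational_transform(pc[lead], num_roots = roots_u - shift,
                     den_roots = rep(-shift + 0i, deg))
}

# Volumetric seeding: phi(a) = M e^{alpha a}, transform M/(s - alpha)
phi_r_transform_vol <- function(M, alpha, mf) {
  if (M == 0) return(rational_transform(0))
  if (mf$type == "exponential")
    return(rational_transform(M, den_roots = alpha - mf$mu + 0i))
  if (mf$type == "quadratic_surfing") {
    eta <- mf$eta
    if (eta == 0) return(rational_transform(M, den_roots = alpha + 0i))
    # L[M(1 - eta a^2) e^{alpha a}] = M[(s-alpha)^2 - 2 eta]/(s-alpha)^3
    return(rational_transform(M,
                              num_roots = alpha + c(1, -1) * sqrt(2 * eta),
                              den_roots = rep(alpha + 0i, 3)))
  }
  poly_exp_transform_vol(mf$coef * M, alpha)
}

phi_1mr_transform_vol <- function(M, alpha, mf) {
  if (M == 0) return(rational_transform(0))
  if (mf$type == "exponential") {
    mu <- mf$mu
    if (mu == 0) return(rational_transform(0))
    # M mu / ((s - alpha)(s - alpha + mu))
    return(rational_transform(M * mu,
                              den_roots = c(alpha + 0i, alpha - mu + 0i)))
  }
  if (mf$type == "quadratic_surfing") {
    eta <- mf$eta
    if (eta == 0) return(rational_transform(0))
    return(rational_transform(2 * M * eta, den_roots = rep(alpha + 0i, 3)))
  }
  co <- -mf$coef; co[1] <- co[1] + 1
  poly_exp_transform_vol(co * M, alpha)
}

# L[ sum_j c_j a^j e^{alpha a} ] = sum_j c_j j! / (s-alpha)^{j+1}
poly_exp_transform_vol <- function(co, alpha) {
  jj <- seq_along(co) - 1L
  deg <- max(jj) + 1L
  pc <- numeric(deg)
  for (j in jj) pc[deg - j] <- co[j + 1L] * factorial(j)
  nz <- which(pc != 0)
  if (length(nz) == 0) return(rational_transform(0))
  lead <- max(nz)
  pc <- pc[seq_len(lead)]
  roots_u <- if (lead > 1) polyroot(pc) else complex(0)
  rational_transform(pc[lead], num_roots = roots_u + alpha,
                     den_roots = rep(alpha + 0i, deg))
}
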