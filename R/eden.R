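# R interface to the 3D Eden lattice simulator, plus the calibration
# operations that link it to the analytic model: the surface mutant
# fraction (quadratic in age) and the front speed (v ~ 0.53 b1 sites/day
# on the von Neumann lattice).

#' Eden lattice model parameters
#'
#' @param b1 division rate of a one-driver cell, 1/day.
#' @param p_mu mutation probability per daughter cell.
#' @param M migration rate, 1/day per eligible cell.
#' @param n_max maximum driver count (absorbing).
#' @param b_n optional explicit per-type division rates; default linear
#'   \code{n * b1}.
#' @param neighborhood 6 (von Neumann, default) or 26 (Moore); the front
#'   speed constant depends on this choice.
#' @param migrate_surface if TRUE (default) only surface cells (cells with
#'   at least one empty neighbour) migrate; otherwise all cells.
#' @param remove_migrant if TRUE the migrating cell is removed from its
#'   source lesion; default FALSE (the source is unaffected).
#' @return a list of validated parameters (class \code{eden_params}).
#' @export
eden_params <- function(b1, p_mu = 0, M = 0, n_max = 3L, b_n = NULL,
                        neighborhood = 6L, migrate_surface = TRUE,
                        remove_migrant = FALSE) {
  if (b1 <= 0) stop("`b1` must be > 0")
  if (p_mu < 0 || p_mu > 1) stop("`p_mu` must be in [0, 1]")
  if (M < 0) stop("`M` must be >= 0")
  n_max <- as.integer(n_max)
  if (is.null(b_n)) b_n <- seq_len(n_max) * b1
  if (length(b_n) != n_max || any(diff(b_n) < 0))
    stop("`b_n` must have length n_max and be non-decreasing")
  if (!neighborhood %in% c(6L, 26L)) stop("neighborhood must be 6 or 26")
  structure(list(b1 = b1, p_mu = p_mu, M = M, n_max = n_max, b_n = b_n,
                 neighborhood = as.integer(neighborhood),
                 migrate_surface = isTRUE(migrate_surface),
                 remove_migrant = isTRUE(remove_migrant)),
            class = "eden_params")
}

#' Run the Eden lattice simulation
#'
#' Continuous-time (Gillespie) dynamics: each cell attempts to divide into
#' a uniformly random neighbouring site with rate \code{b_n} (success only
#' if the site is empty), daughters gain a driver with probability
#' \code{p_mu}, and eligible cells migrate with rate \code{M}, founding an
#' independent one-cell lesion of the migrant's type.
#'
#' @param ep an \code{\link{eden_params}} object.
#' @param t_max horizon in days.
#' @param seed RNG seed (runs are bit-reproducible given the seed).
#' @param out_dt output cadence in days.
#' @param max_cells abort threshold on the total cell count.
#' @return a data.frame with columns \code{t}, \code{V_1..V_nmax} (cell
#'   counts per type), \code{V_tot}, \code{mean_n}, \code{n_lesions},
#'   \code{surf_mutant_frac}, \code{radius}, \code{anisotropy} (the last
#'   three for the first lesion), plus attributes \code{n_divisions},
#'   \code{n_attempts}, \code{final_cells}.
#' @export
run_eden <- function(ep, t_max, seed = NULL, out_dt = 10,
                     max_cells = 2e6) {
  stopifnot(inherits(ep, "eden_params"))
  if (!is.null(seed)) set.seed(seed)
  res <- run_eden_cpp(ep$b_n, ep$p_mu, ep$M, ep$n_max, t_max, out_dt,
                      ep$neighborhood, ep$migrate_surface,
                      ep$remove_migrant, max_cells)
  counts <- res$counts
  vtot <- rowSums(counts)
  mean_n <- ifelse(vtot > 0, as.vector(counts %*% seq_len(ep$n_max)) / vtot, 1)
  out <- data.frame(t = res$time, counts, V_tot = vtot, mean_n = mean_n,
                    n_lesions = res$n_lesions,
                    surf_mutant_frac = res$surf_mutant_frac,
                    radius = res$radius, anisotropy = res$anisotropy)
  names(out)[2:(1 + ep$n_max)] <- paste0("V_", seq_len(ep$n_max))
  attr(out, "n_divisions") <- res$n_divisions
  attr(out, "n_attempts") <- res$n_attempts
  attr(out, "final_cells") <- res$final_cells
  out
}

#' Replicate-averaged Eden trajectories
#'
#' @param ep an \code{\link{eden_params}} object.
#' @param replicates number of independent runs.
#' @param t_max horizon (days).
#' @param seed master seed; replicate r uses the sequential RNG stream.
#' @param out_dt output cadence (days).
#' @param max_cells per-run cell cap.
#' @return a list with \code{times}, \code{V_mean} (matrix), \code{V_se},
#'   \code{Vtot_mean}, \code{Vtot_se}, \code{mean_n} (from averaged
#'   volumes), \code{surf_mutant_frac_mean}, \code{radius_mean},
#'   \code{replicates}.
#' @export
eden_replicates <- function(ep, replicates, t_max, seed = 1L, out_dt = 10,
                            max_cells = 2e6) {
  set.seed(seed)
  acc <- NULL
  for (r in seq_len(replicates)) {
    sim <- run_eden(ep, t_max = t_max, out_dt = out_dt,
                    max_cells = max_cells)
    V <- as.matrix(sim[, paste0("V_", seq_len(ep$n_max))])
    if (is.null(acc)) {
      acc <- list(V = V * 0, V2 = V * 0, sf = 0, rad = 0)
      times <- sim$t
    }
    acc$V <- acc$V + V
    acc$V2 <- acc$V2 + V^2
    acc$sf <- acc$sf + sim$surf_mutant_frac
    acc$rad <- acc$rad + sim$radius
  }
  R <- replicates
  Vmean <- acc$V / R
  Vse <- sqrt(pmax(acc$V2 / R - Vmean^2, 0) / max(R - 1, 1))
  vt <- rowSums(Vmean)
  vt_se <- sqrt(rowSums(pmax(acc$V2 / R - Vmean^2, 0)) / max(R - 1, 1))
  list(times = times, V_mean = Vmean, V_se = Vse,
       Vtot_mean = vt, Vtot_se = vt_se,
       mean_n = ifelse(vt > 0, as.vector(Vmean %*% seq_len(ep$n_max)) / vt, 1),
       surf_mutant_frac_mean = acc$sf / R,
       radius_mean = acc$rad / R,
       replicates = R)
}

#' Surface mutant fraction of a single lattice lesion
#'
#' For single-lesion runs (M = 0) the fraction of surface cells carrying
#' more than one driver, \code{1 - r_1(a)}, is fitted to the power law
#' \code{C a^gamma} and to the quadratic \code{eta_1 a^2} predicted for
#' mutants surfing on an expanding front.
#'
#' @param traj either a data.frame from \code{\link{run_eden}} or a list
#'   from \code{\link{eden_replicates}}.
#' @param a_min ages below this (days) are excluded from the fits (the
#'   front must be established before the scaling law applies).
#' @return list with \code{gamma}, \code{C} (power-law fit), \code{eta1}
#'   (least-squares quadratic coefficient), and the fitted data.
#' @export
surface_mutant_fraction <- function(traj, a_min = NULL) {
  if (is.data.frame(traj)) {
    a <- traj$t; frac <- traj$surf_mutant_frac
  } else {
    a <- traj$times; frac <- traj$surf_mutant_frac_mean
  }
  if (is.null(a_min)) a_min <- max(a) / 5
  keep <- a >= a_min & frac > 0
  if (sum(keep) < 3)
    return(list(gamma = NA_real_, C = NA_real_, eta1 = 0,
                data = data.frame(age = a, frac = frac)))
  fit <- stats::lm(log(frac[keep]) ~ log(a[keep]))
  eta1 <- sum(frac[keep] * a[keep]^2) / sum(a[keep]^4)
  list(gamma = unname(stats::coef(fit)[2]), C = exp(unname(stats::coef(fit)[1])),
       eta1 = eta1, data = data.frame(age = a, frac = frac))
}

#' Calibrate the lattice front speed against the analytic model
#'
#' Fits the single-type analytic total volume (surface growth with the
#' run's migration rate, growth rate G free) to replicate-mean lattice
#' volumes from mutation-free runs, and converts the fitted G to the
#' radial expansion speed \code{v = G / (8 pi M)^(1/3)} in sites/day.  On
#' the von Neumann lattice the ratio \code{v / b1} is about 0.53.
#'
#' @param vtot_mean replicate-mean total volume (cells) on \code{times}.
#' @param times output times (days).
#' @param M migration rate used in the runs (> 0: the analytic form is the
#'   single-type exact solution with migration).
#' @param b1 lattice division rate (for the reported ratio).
#' @param v_min fit window: only times with \code{vtot_mean >= v_min}
#'   cells enter the fit.
#' @return list with \code{G1}, \code{v}, \code{ratio} (= v/b1) and the
#'   fit residual.
#' @export
calibrate_front_speed <- function(vtot_mean, times, M, b1,
                                  v_min = 50) {
  keep <- vtot_mean >= v_min & times > 0
  if (sum(keep) < 3) stop("not enough usable points for the fit")
  tt <- times[keep]; vv <- vtot_mean[keep]
  model_logV <- function(G) {
    v <- G / (8 * pi * M)^(1 / 3)
    p <- model_params("surface", v1 = v, M = M, mu = 0, n_max = 1L)
    sol <- solve_exact(p, times = c(0, tt), n_types = 1L)
    log(pmax(sol$V_tot[-1], .Machine$double.xmin))
  }
  obj <- function(logG) sum((model_logV(exp(logG)) - log(vv))^2)
  # bracket around the naive guess v ~ 0.5 b1
  G0 <- (8 * pi * M)^(1 / 3) * 0.5 * b1
  opt <- stats::optimize(obj, interval = log(G0) + c(-2, 2))
  G1 <- exp(opt$minimum)
  v <- G1 / (8 * pi * M)^(1 / 3)
  list(G1 = G1, v = v, ratio = v / b1, residual = opt$objective)
}
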