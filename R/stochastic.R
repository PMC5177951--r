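# Event-driven Monte Carlo simulation of the lesion process: growth and
# mutation are deterministic within lesions, seeding of new lesions is an
# inhomogeneous Poisson process with the law's intensity phi_n(a).
#
# Because lesions never interact, each lesion's offspring process is
# independent given its birth time and type, so a replicate is generated
# breadth-first: a lesion's seeding ages are drawn exactly (conditional on
# the Poisson count, event ages are order statistics of the inverted
# cumulative intensity), each offspring's type is n with probability
# r_n(age) and n+1 otherwise, and offspring are pushed on a queue.

# cumulative seeding intensity Phi_n(a) = int_0^a phi_n, and its inverse;
# closed forms exist for every in-scope law
cumulative_intensity <- function(params, law) {
  M <- params$M
  switch(law$mode,
    surface = {
      v <- law$speed
      list(Phi = function(a) (4 * pi / 3) * M * v^3 * a^3,
           Phi_inv = function(u) (3 * u / (4 * pi * M * v^3))^(1 / 3),
           Phi_max = Inf)
    },
    surface_slowdown = {
      v <- law$speed; lam <- params$lam
      tot <- M * 8 * pi * v^3 / lam^3          # Phi(Inf) = M V(Inf)
      list(Phi = function(a) tot * stats::pgamma(lam * a, 3),
           Phi_inv = function(u) stats::qgamma(pmin(u / tot, 1), 3) / lam,
           Phi_max = tot)
    },
    volumetric = {
      al <- law$alpha
      if (abs(al) < 1e-14) {
        list(Phi = function(a) M * a,
             Phi_inv = function(u) u / M, Phi_max = Inf)
      } else if (al > 0) {
        list(Phi = function(a) M * (exp(al * a) - 1) / al,
             Phi_inv = function(u) log1p(al * u / M) / al, Phi_max = Inf)
      } else {
        list(Phi = function(a) M * (exp(al * a) - 1) / al,
             Phi_inv = function(u) log1p(al * u / M) / al,
             Phi_max = -M / al)
      }
    })
}

#' Simulate one tumour replicate
#'
#' Event-driven exact simulation: every lesion grows deterministically
#' according to its growth law and seeds offspring as an inhomogeneous
#' Poisson process with intensity \code{phi_n(age)}.  An offspring seeded
#' by a type-n parent of age \code{a} is type n with probability
#' \code{r_n(a)} and type n+1 otherwise (type \code{n_max} is absorbing).
#'
#' @param params a \code{\link{model_params}} object.
#' @param t_max horizon in days.
#' @param times output grid (days).
#' @param cap_lesions abort threshold on the total lesion count
#'   (supercritical runaway guard).
#' @return a data.frame in the standard schema (\code{t}, \code{N_n},
#'   \code{V_n}, \code{V_tot}, \code{mean_n}) for this replicate, with the
#'   lesion table (birth, type) as attribute \code{"lesions"}.
#' @export
simulate_tumour <- function(params, t_max = 2500,
                            times = seq(0, t_max, by = 10),
                            cap_lesions = 1e6) {
  n_max <- params$n_max
  laws <- lapply(seq_len(n_max), function(n) make_growth_law(params, n))
  cum <- lapply(laws, function(l) cumulative_intensity(params, l))

  # breadth-first over generations, vectorized within (lesions never
  # interact, so a lesion's offspring process depends only on its own birth
  # time and type); deterministic iteration order keeps runs reproducible
  birth <- 0; type <- 1L; parent <- 0L
  processed <- 0L
  while (processed < length(birth)) {
    idx <- (processed + 1L):length(birth)
    processed <- length(birth)
    for (n in sort(unique(type[idx]))) {
      sel <- idx[type[idx] == n]
      ci <- cum[[n]]
      lam <- pmin(ci$Phi(t_max - birth[sel]), ci$Phi_max)
      # guard on the projected event count before materializing anything
      if (length(birth) + sum(lam) > cap_lesions)
        stop(sprintf(paste0("projected lesion count exceeds cap_lesions ",
                            "= %g; the parameter set is too supercritical ",
                            "for this horizon"), cap_lesions))
      k <- stats::rpois(length(sel), lam)
      tot <- sum(k)
      if (tot == 0) next
      par <- rep(sel, k)
      ages <- ci$Phi_inv(stats::runif(tot) * rep(lam, k))
      same <- stats::runif(tot) <= laws[[n]]$r(ages)
      birth <- c(birth, birth[par] + ages)
      type <- c(type, ifelse(same, n, min(n + 1L, n_max)))
      parent <- c(parent, par)
      if (length(birth) > cap_lesions)
        stop(sprintf(paste0("lesion count exceeded cap_lesions = %g; the ",
                            "parameter set is too supercritical for this ",
                            "horizon"), cap_lesions))
    }
  }
  type <- as.integer(type)

  Nmat <- matrix(0, length(times), n_max)
  Vmat <- matrix(0, length(times), n_max)
  for (n in sort(unique(type))) {
    bt <- birth[type == n]
    # chunked accumulation keeps memory bounded when lesion counts are large
    for (lo in seq(1, length(bt), by = 20000L)) {
      chunk <- bt[lo:min(lo + 19999L, length(bt))]
      age_mat <- outer(times, chunk, "-")
      alive <- age_mat >= 0
      Nmat[, n] <- Nmat[, n] + rowSums(alive)
      Vmat[, n] <- Vmat[, n] + rowSums(laws[[n]]$V(pmax(age_mat, 0)) * alive)
    }
  }
  Vtot <- rowSums(Vmat)
  mean_n <- ifelse(Vtot > 0, as.vector(Vmat %*% seq_len(n_max)) / Vtot, 1)
  out <- data.frame(t = times, Nmat, Vmat, Vtot, mean_n)
  names(out) <- c("t", paste0("N_", seq_len(n_max)),
                  paste0("V_", seq_len(n_max)), "V_tot", "mean_n")
  attr(out, "lesions") <- data.frame(birth = birth, type = type,
                                     parent = parent)
  class(out) <- c("lesion_timeseries", "data.frame")
  out
}

#' Replicate-averaged simulation with both mean-driver estimators
#'
#' Runs \code{n_replicates} independent tumours and reports replicate means
#' of the per-type volumes plus the two estimators of the mean driver
#' count: "Method 1" averages the per-replicate volume-weighted means over
#' replicates; "Method 2" computes the volume-weighted mean from the
#' replicate-averaged per-type volumes, which is the quantity the analytic
#' solution describes.  Method 1 is dragged down at late times by small
#' tumours whose drivers arrived late.
#'
#' @param params a \code{\link{model_params}} object.
#' @param n_replicates number of replicates, >= 2.
#' @param t_max horizon (days).
#' @param seed RNG seed (replicates are drawn sequentially from it;
#'   identical seeds give bit-identical summaries).
#' @param times output grid.
#' @param cap_lesions per-replicate lesion cap.
#' @return a list with elements \code{times}, \code{V_mean} (replicate mean
#'   per-type volumes, matrix), \code{V_se}, \code{Vtot_mean},
#'   \code{Vtot_se}, \code{N_mean}, \code{mean_n_method1} (+ \code{_se}),
#'   \code{mean_n_method2}, \code{n_replicates}, \code{seed}.
#' @export
replicate_average <- function(params, n_replicates = 500, t_max = 2500,
                              seed = 1L, times = seq(0, t_max, by = 10),
                              cap_lesions = 1e6) {
  if (n_replicates < 2) stop("need at least 2 replicates")
  set.seed(seed)
  n_max <- params$n_max
  nt <- length(times)
  Vsum <- matrix(0, nt, n_max); Vsq <- matrix(0, nt, n_max)
  Nsum <- matrix(0, nt, n_max)
  Vtsum <- numeric(nt); Vtsq <- numeric(nt)
  m1sum <- numeric(nt); m1sq <- numeric(nt)
  for (r in seq_len(n_replicates)) {
    sim <- simulate_tumour(params, t_max = t_max, times = times,
                           cap_lesions = cap_lesions)
    V <- as.matrix(sim[, paste0("V_", seq_len(n_max))])
    Vsum <- Vsum + V; Vsq <- Vsq + V^2
    Nsum <- Nsum + as.matrix(sim[, paste0("N_", seq_len(n_max))])
    Vtsum <- Vtsum + sim$V_tot; Vtsq <- Vtsq + sim$V_tot^2
    m1sum <- m1sum + sim$mean_n; m1sq <- m1sq + sim$mean_n^2
  }
  R <- n_replicates
  Vmean <- Vsum / R
  Vtmean <- Vtsum / R
  # standard error of the replicate mean
  sdv <- function(sq, sm) sqrt(pmax(sq / R - (sm / R)^2, 0) / (R - 1))
  list(times = times,
       V_mean = Vmean,
       V_se = sdv(Vsq, Vsum),
       N_mean = Nsum / R,
       Vtot_mean = Vtmean,
       Vtot_se = sdv(Vtsq, Vtsum),
       mean_n_method1 = m1sum / R,
       mean_n_method1_se = sdv(m1sq, m1sum),
       mean_n_method2 = ifelse(Vtmean > 0,
                               as.vector(Vmean %*% seq_len(n_max)) / Vtmean, 1),
       n_replicates = R, seed = seed)
}
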