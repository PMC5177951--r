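# Large-time asymptotics: closed-form rates, amplitudes, accumulation laws.

test_that("closed-form growth rates match the renewal roots to 1e-10", {
  p3 <- fig3_surface()
  for (n in 1:5)
    expect_rel(growth_rate_surface(p3, n),
               euler_lotka_root(make_growth_law(p3, n)$K), 1e-10)
  ps <- fig3_slowdown()
  for (n in 1:5)
    expect_rel(growth_rate_slowdown(ps, n),
               euler_lotka_root(make_growth_law(ps, n)$K), 1e-10)
  # documented value of G_1 at the fig3_surface fixture parameters
  expect_rel(growth_rate_surface(p3, 1), 1.372e-3, 1e-3)
  # G_1 becomes negative for large enough mutation rates
  pbig <- model_params("surface", v1 = 0.0475, M = 1e-6, mu = 2e-3)
  expect_lt(growth_rate_surface(pbig, 1), 0)
  # gap is independent of mu
  pa <- model_params("surface", v1 = 0.0475, M = 1e-6, mu = 1e-6)
  pb <- model_params("surface", v1 = 0.0475, M = 1e-6, mu = 1e-4)
  expect_equal(growth_rate_surface(pa, 2) - growth_rate_surface(pa, 1),
               growth_rate_surface(pb, 2) - growth_rate_surface(pb, 1))
  expect_rel(growth_rate_surface(pa, 2) - growth_rate_surface(pa, 1),
             (8 * pi * 1e-6)^(1 / 3) * 0.0475, 1e-12)
})

test_that("slow-down rates: lambda shift and lambda-independent gaps", {
  ps <- fig3_slowdown()
  p0 <- model_params("surface", v1 = 0.053, M = 1e-6, mu = 2e-5)
  for (n in 1:4) {
    expect_equal(growth_rate_slowdown(ps, n),
                 growth_rate_surface(p0, n) - 1e-3)
  }
  gaps_lam <- diff(vapply(1:5, function(n) growth_rate_slowdown(ps, n),
                          numeric(1)))
  gaps_0 <- diff(vapply(1:5, function(n) growth_rate_surface(p0, n),
                        numeric(1)))
  expect_equal(gaps_lam, gaps_0, tolerance = 1e-14)
  # continuity: lambda -> 0 recovers the surface rate
  expect_equal(growth_rate_slowdown(p0, 3), growth_rate_surface(p0, 3))
})

test_that("limit-method amplitudes approximate the exact residues at small mu", {
  p3 <- fig3_surface()
  ace <- asymptotic_coefficients(p3, 5, "exact")
  acl <- asymptotic_coefficients(p3, 5, "limit")
  expect_equal(ace$G, acl$G, tolerance = 1e-12)
  expect_true(all(abs(ace$A - acl$A) / ace$A < 0.05))
  expect_true(all(ace$A > 0))
  # the limit method warns outside its validity
  pbig <- model_params("surface", v1 = 0.0475, M = 1e-6, mu = 5e-4)
  expect_warning(asymptotic_coefficients(pbig, 3, "limit"), "mu/G_1")
})

test_that("mean-driver asymptote tends to the exact solution and is 1 without mutation", {
  p3 <- fig3_surface()
  tt <- c(3000, 5475, 7000, 9000)
  sol <- suppressWarnings(solve_exact(p3, times = c(0, tt), n_types = 12))
  asy <- asymptotic_mean_drivers(p3, tt, n_types = 12)
  ratio <- asy / sol$mean_n[-1]
  expect_true(all(ratio > 0.5 & ratio < 2))
  # monotone approach to 1 beyond the crossover
  expect_true(all(diff(abs(ratio - 1)) <= 1e-12))
  expect_lt(abs(ratio[4] - 1), 1e-3)
  pmu0 <- model_params("surface", v1 = 0.1, M = 1e-6, mu = 0)
  expect_equal(asymptotic_mean_drivers(pmu0, tt), rep(1, 4))
})

test_that("driver accumulation rate of the asymptote is unchanged by the slow-down", {
  ps <- fig3_slowdown()
  p0 <- model_params("surface", v1 = 0.053, M = 1e-6, mu = 2e-5)
  tt <- seq(400, 1600, by = 100)
  r_lam <- unname(coef(lm(log(asymptotic_mean_drivers(ps, tt, n_types = 10) - 1) ~ tt))[2])
  r_0 <- unname(coef(lm(log(asymptotic_mean_drivers(p0, tt, n_types = 10) - 1) ~ tt))[2])
  D <- (8 * pi * 1e-6)^(1 / 3) * 0.053
  expect_rel(r_lam, D, 0.01)
  expect_rel(r_0, D, 0.01)
  expect_lt(abs(r_lam - r_0) / D, 0.01)
})

test_that("volume asymptote: super-exponential for linear schedules, exponential for three-strong", {
  p3 <- fig3_surface()
  tt <- seq(4000, 8000, by = 500)
  lv <- log(asymptotic_volume(p3, tt, n_types = 12))
  slopes <- diff(lv) / diff(tt)
  expect_true(all(diff(slopes) > 0))
  # ratio to the exact solution approaches 1
  sol <- suppressWarnings(solve_exact(p3, times = c(0, 6000, 12000),
                                      n_types = 12))
  r1 <- asymptotic_volume(p3, 6000, n_types = 12) / sol$V_tot[2]
  r2 <- asymptotic_volume(p3, 12000, n_types = 12) / sol$V_tot[3]
  expect_lt(abs(r2 - 1), abs(r1 - 1))
  expect_lt(abs(r2 - 1), 0.05)
  # three strong drivers with vanishing residual advantage: late log-slope
  # settles to a constant
  p40 <- model_params("surface", v1 = 0.015, M = 1e-4, mu = 2e-5,
                      schedule = list(type = "three_strong", s_hat = 0),
                      n_max = 8L)
  tt2 <- seq(6000, 12000, by = 1000)
  lv2 <- log(asymptotic_volume(p40, tt2, n_types = 6))
  sl2 <- diff(lv2) / diff(tt2)
  expect_lt((max(sl2) - min(sl2)) / mean(sl2), 0.01)
})

test_that("volumetric generating function: Bessel closed form equals the series", {
  pv <- fig3_volumetric()
  for (t in c(1000, 3000, 5475)) for (q in c(0.5, 1, 2)) {
    expect_rel(z_volumetric(pv, t, q, "bessel"),
               z_volumetric(pv, t, q, "series"), 1e-8)
  }
  # Bessel-form mean tracks the exact solution at late times (checked at a
  # time where 12 resolved types still cover the driver distribution)
  sol <- suppressWarnings(solve_exact(pv, times = c(0, 5475), n_types = 12))
  m <- asymptotic_mean_drivers(pv, 5475, method = "limit")
  expect_rel(m, sol$mean_n[2], 0.1)
})

test_that("crossover detection returns a finite onset for the reference surface model", {
  p3 <- fig3_surface()
  tc <- suppressWarnings(crossover_time(p3, "V_tot", t_range = c(500, 5000),
                                        n_types = 8))
  expect_true(is.finite(tc))
  expect_gt(tc, 0)
})
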