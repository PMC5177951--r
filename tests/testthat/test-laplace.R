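# Laplace-domain machinery: inversion, renewal roots, hierarchical
# solution, and the exact solver's internal consistency.

test_that("invert_rational handles the elementary transforms", {
  # 1/s^2 -> t
  eps <- invert_rational(rational_transform(1, den_roots = c(0, 0)))
  expect_equal(eps_eval(eps, c(0, 1, 2.5, 10)), c(0, 1, 2.5, 10))
  # M/(s - c - M) -> M exp((c + M) t)
  M <- 1e-5; cc <- 2e-3
  eps2 <- invert_rational(rational_transform(M, den_roots = cc + M))
  tt <- c(0, 100, 1000)
  expect_equal(eps_eval(eps2, tt), M * exp((cc + M) * tt), tolerance = 1e-12)
})

test_that("single-type surface inversion: three conjugate-closed terms, F(0) = 0, growth at rate G", {
  p <- model_params("surface", v1 = 0.1, M = 1e-6, mu = 0, n_max = 1L)
  l <- make_growth_law(p, 1)
  Ft <- build_Fn_transform(list(l))
  # F~ = w/(s^3 - w)
  w <- 8 * pi * 1e-6 * 0.1^3
  ss <- c(0.01, 0.02, 0.05)
  expect_equal(Re(rt_eval(Ft, ss)), w / (ss^3 - w), tolerance = 1e-12)
  eps <- invert_rational(Ft)
  expect_equal(length(eps$coef), 3L)
  # rates are G, G omega, G conj(omega)
  G <- (8 * pi * 1e-6)^(1 / 3) * 0.1
  expect_rel(max(Re(eps$rate)), G, 1e-12)
  expect_equal(sort(Im(eps$rate))[1], -sort(Im(eps$rate))[3])
  expect_equal(eps_eval(eps, 0), 0, tolerance = 1e-15)
  # forward round trip at real points
  s5 <- G + c(0.3, 0.7, 1.3, 2.9, 5.1) * G
  expect_true(all(Mod(eps_laplace(eps, s5) - rt_eval(Ft, s5)) /
                    Mod(rt_eval(Ft, s5)) < 1e-6))
  # asymptotically proportional to exp(G z)
  expect_rel(eps_eval(eps, 8000) / eps_eval(eps, 7000), exp(1000 * G), 1e-6)
})

test_that("euler_lotka_root agrees with a bisection oracle and printed closed forms", {
  # surface, no mutation
  p <- model_params("surface", v1 = 0.1, M = 1e-6, mu = 0, n_max = 1L)
  G <- euler_lotka_root(make_growth_law(p, 1)$K)
  expect_rel(G, el_root_bisect(1e-6, 0.1), 1e-10)
  expect_rel(G, 2.931e-3, 1e-3)
  # multi-driver surface: G_n = n (8 pi M)^(1/3) v1 - mu
  p3 <- fig3_surface()
  for (n in 1:4) {
    Gn <- euler_lotka_root(make_growth_law(p3, n)$K)
    expect_rel(Gn, n * (8 * pi * 1e-6)^(1 / 3) * 0.0475 - 2e-5, 1e-10)
  }
  # volumetric: G = b exactly
  pv <- model_params("volumetric", b = 0.0026, M = 1e-5, mu = 0)
  expect_rel(euler_lotka_root(make_growth_law(pv, 1)$K), 0.0026, 1e-12)
  # M = 0: zero kernel, no renewal
  p0 <- model_params("surface", v1 = 0.1, M = 0, mu = 0)
  expect_equal(euler_lotka_root(make_growth_law(p0, 1)$K), -Inf)
})

test_that("hierarchical flux transforms: M = 0 gives no lesions, cross poles appear", {
  p0 <- model_params("surface", v1 = 0.1, M = 0, mu = 2e-5, n_max = 4L)
  laws0 <- lapply(1:2, function(n) make_growth_law(p0, n))
  expect_true(Mod(build_Fn_transform(laws0)$const) == 0)
  # volumetric n = 2: pole near b - M - mu (the cross-kernel pole; the
  # printed Methods set is reproduced up to an O(mu) shift, see vignette)
  pv <- model_params("volumetric", b = 0.0026, M = 1e-5, mu = 2e-5)
  laws <- lapply(1:2, function(n) make_growth_law(pv, n))
  poles <- rt_poles(build_Fn_transform(laws))
  expect_lt(min(Mod(poles - (0.0026 - 1e-5 - 2e-5))), 3e-5)
})

test_that("exact solver: initial conditions, totals, volume identities", {
  p <- fig3_surface()
  sol <- suppressWarnings(solve_exact(p, times = seq(0, 3000, by = 50),
                                      n_types = 8))
  expect_equal(sol$N_1[1], 1)
  expect_true(all(sol[1, paste0("N_", 2:8)] == 0))
  # V_tot is the exact row sum of the per-type volumes
  expect_equal(sol$V_tot,
               rowSums(sol[, paste0("V_", 1:8)]), tolerance = 1e-14)
  # mean_n is the volume-weighted mean and stays in [1, n_types]
  expect_equal(sol$mean_n[-1], mean_drivers(sol, sol$t[-1]), tolerance = 1e-14)
  expect_true(all(sol$mean_n >= 1 - 1e-12 & sol$mean_n <= 8))
  # with mu = 0 the mean is identically 1 and V_tot,1 is the whole tumour
  pmu0 <- model_params("surface", v1 = 0.1, M = 1e-6, mu = 0, n_max = 4L)
  s0 <- solve_exact(pmu0, times = seq(0, 2000, by = 100), n_types = 3)
  expect_true(all(s0$mean_n == 1))
  expect_equal(s0$V_tot, s0$V_1, tolerance = 1e-14)
  # M = 0: single founder lesion forever
  pM0 <- model_params("surface", v1 = 0.1, M = 0, mu = 0, n_max = 2L)
  sM0 <- solve_exact(pM0, times = seq(0, 2000, by = 100), n_types = 2)
  expect_true(all(sM0$N_1 == 1))
  l1 <- make_growth_law(pM0, 1)
  expect_equal(sM0$V_tot, l1$V(sM0$t), tolerance = 1e-12)
})

test_that("late-time lesion count slope equals the renewal root", {
  p <- model_params("surface", v1 = 0.1, M = 1e-6, mu = 0, n_max = 1L)
  Fn <- invert_rational(build_Fn_transform(list(make_growth_law(p, 1))))
  tt <- seq(5000, 10000, by = 100)
  slope <- unname(coef(lm(log(lesion_count(Fn, tt)) ~ tt))[2])
  expect_rel(slope, euler_lotka_root(make_growth_law(p, 1)$K), 1e-3)
})

test_that("subcritical kernels give bounded lesion counts", {
  p <- model_params("surface_slowdown", v1 = 0.1, M = 1e-8, mu = 0,
                    lam = 0.004, n_max = 1L)
  l <- make_growth_law(p, 1)
  expect_lt(Re(rt_eval(l$K, 0)), 1)   # K~(0) < 1
  expect_lt(euler_lotka_root(l$K), 0)
  Fn <- invert_rational(build_Fn_transform(list(l)))
  N <- lesion_count(Fn, c(1e4, 1e5, 1e6))
  expect_true(all(is.finite(N)))
  expect_lt(abs(N[3] - N[2]), 1e-6 * N[2] + 1e-9)
})

test_that("all returned time-domain values are real and volumes non-negative", {
  for (p in list(fig3_surface(), fig3_slowdown(), fig3_volumetric())) {
    sol <- suppressWarnings(solve_exact(p, times = seq(0, 4000, by = 200),
                                        n_types = 6))
    expect_true(all(is.finite(as.matrix(sol))))
    expect_true(all(as.matrix(sol[, paste0("V_", 1:6)]) >= 0))
  }
})
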