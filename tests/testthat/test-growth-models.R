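# Single-lesion growth laws: closed forms, transforms, limits.

test_that("parameter validation enforces the model's domain", {
  expect_error(model_params("surface", v1 = 0.1, b = 0.1, M = 1e-6),
               "surface modes")
  expect_error(model_params("surface", v1 = 0.1, M = 2), "probability")
  expect_error(model_params("surface_slowdown", v1 = 0.1, M = 1e-6),
               "lam")
  expect_error(model_params("volumetric", b = -1, M = 0), "> 0")
  expect_error(model_params("surface", v1 = 0.1, M = 1e-6, n_max = 0),
               "n_max")
  expect_error(model_params("surface", v1 = 0.1, M = 1e-6,
                            schedule = list(type = "custom",
                                            values = numeric(0))),
               "non-empty")
  p <- model_params("surface", v1 = 0.1, M = 1e-6, mu = 2e-5)
  expect_error(make_growth_law(p, 0), ">= 1")
  expect_error(make_growth_law(p, 33), "n_max")
  expect_error(make_growth_law(p, 1)$V(-1), "age")
})

test_that("surface law matches its closed forms and printed transform", {
  p <- model_params("surface", v1 = 0.1, M = 1e-6, mu = 0, n_max = 1L)
  l <- make_growth_law(p, 1)
  # V = (4 pi/3)(v a)^3: at v a = 1 this is 4 pi/3
  expect_rel(l$V(10), 4 * pi / 3, 1e-12)
  expect_equal(l$V(0), 0)
  expect_equal(l$phi(0), 0)
  # transform of phi is 8 pi M v^3 / s^3; at M = 1, v = 1, s = 1 -> 8 pi
  p1 <- model_params("surface", v1 = 1, M = 1, mu = 0, n_max = 1L)
  l1 <- make_growth_law(p1, 1)
  expect_rel(Re(rt_eval(l1$K, 1)), 8 * pi, 1e-12)
})

test_that("slow-down law saturates, reduces to the surface law, and can be subcritical", {
  p <- model_params("surface_slowdown", v1 = 0.1, M = 1e-6, mu = 0,
                    lam = 0.01, n_max = 1L)
  l <- make_growth_law(p, 1)
  # saturation at 8 pi v^3 / lam^3
  expect_rel(l$V(1e7), 8 * pi * 0.1^3 / 0.01^3, 1e-6)
  # lambda -> 0 reduces pointwise to the plain surface law
  ptiny <- model_params("surface_slowdown", v1 = 0.1, M = 1e-6, mu = 0,
                        lam = 1e-9, n_max = 1L)
  lt <- make_growth_law(ptiny, 1)
  p0 <- model_params("surface", v1 = 0.1, M = 1e-6, mu = 0, n_max = 1L)
  l0 <- make_growth_law(p0, 1)
  aa <- c(1, 10, 100, 300)   # lam * a stays below the 1e-6 tolerance
  expect_true(all(abs(lt$V(aa) - l0$V(aa)) / l0$V(aa) < 1e-6))
  expect_true(all(abs(lt$phi(aa) - l0$phi(aa)) / l0$phi(aa) < 1e-6))
  # single-type renewal root is the surface root minus lambda, and
  # subcritical for small M
  psub <- model_params("surface_slowdown", v1 = 0.1, M = 1e-6, mu = 0,
                       lam = 0.004, n_max = 1L)
  G <- euler_lotka_root(make_growth_law(psub, 1)$K)
  expect_rel(G, (8 * pi * 1e-6)^(1 / 3) * 0.1 - 0.004, 1e-10)
  expect_lt(G, 0)
})

test_that("volumetric law: founder volume 1, growth rate exactly b, pole structure", {
  p <- model_params("volumetric", b = 0.0026, M = 1e-5, mu = 0)
  l <- make_growth_law(p, 1)
  expect_equal(l$V(0), 1)
  expect_rel(euler_lotka_root(l$K), 0.0026, 1e-12)
  # with mutation, poles of F_3~ include s = k b up to O(mu) shifts
  pm <- model_params("volumetric", b = 0.0026, M = 1e-5, mu = 2e-5)
  laws <- lapply(1:3, function(n) make_growth_law(pm, n))
  poles <- rt_poles(build_Fn_transform(laws))
  for (k in 1:3) {
    d <- min(Mod(poles - k * 0.0026))
    expect_lt(d, 2 * pm$mu + 1e-12)
  }
  # alternative exponent convention: lesion volume exp(b_n a)
  pb <- model_params("volumetric", b = 0.0026, M = 1e-5, mu = 0,
                     volumetric_exponent = "b")
  expect_rel(make_growth_law(pb, 1)$V(1000), exp(2.6), 1e-12)
})

test_that("driver speed schedules", {
  p <- model_params("surface", v1 = 0.0475, M = 1e-6, mu = 2e-5)
  expect_equal(driver_speed_schedule(p, 3), 3 * 0.0475)
  # zero residual advantage: constant speed beyond the third driver
  p0 <- model_params("surface", v1 = 0.015, M = 1e-4, mu = 2e-5,
                     schedule = list(type = "three_strong", s_hat = 0))
  expect_equal(driver_speed_schedule(p0, 4), driver_speed_schedule(p0, 3))
  expect_equal(driver_speed_schedule(p0, 9), driver_speed_schedule(p0, 3))
  # three-strong regime: strong gains for drivers 2-3, weak after
  p4 <- fig4_params()
  v <- driver_speed_schedule(p4, 1:5)
  expect_gt(v[2] - v[1], 10 * (v[4] - v[3]))
  expect_gt(v[3] - v[2], 10 * (v[5] - v[4]))
  # custom schedule pads with its last value
  pc <- model_params("surface", v1 = 0.1, M = 1e-6,
                     schedule = list(type = "custom",
                                     values = c(0.1, 0.25)))
  expect_equal(driver_speed_schedule(pc, 5), 0.25)
})

test_that("mutant fraction kernels: values, limits, clamping", {
  p <- model_params("surface", v1 = 0.0475, M = 1e-6, mu = 2e-5)
  mf <- make_mutant_fraction(p, 1)
  expect_equal(mf$r(0), 1)
  expect_rel(mf$r(1000), exp(-0.02), 1e-12)
  # quadratic surfing: eta vanishes when the next driver adds no speed
  pq <- model_params("surface", v1 = 0.1, M = 1e-6, mu = 2e-5,
                     schedule = list(type = "custom", values = 0.1),
                     r_model = list(type = "quadratic_surfing",
                                    c = 10, p_mu = 1e-4))
  mq <- make_mutant_fraction(pq, 1)
  expect_equal(mq$eta, 0)
  expect_equal(mq$r(c(0, 100, 1e4)), c(1, 1, 1))
  # with a speed gain the fraction is quadratic and clamps at its window
  pq2 <- model_params("surface", v1 = 0.1, M = 1e-6, mu = 2e-5,
                      r_model = list(type = "quadratic_surfing", eta = 1e-6))
  mq2 <- make_mutant_fraction(pq2, 1)
  expect_rel(mq2$r(100), 1 - 1e-6 * 100^2, 1e-12)
  expect_warning(val <- mq2$r(2000), "clamped")
  expect_equal(val, 0)
  # logistic Taylor agrees with the exponential kernel at leading order
  # (the takeover term separates them at order mu*Db*a^2)
  pl <- model_params("volumetric", b = 0.0026, M = 1e-5, mu = 2e-5,
                     r_model = list(type = "logistic_taylor", order = 4))
  ml <- make_mutant_fraction(pl, 1)
  expect_rel(ml$coef[2], -2e-5, 1e-10)
  aa <- c(1, 2, 5)   # the takeover term separates the two at mu*Db*a^2/2
  expect_true(all(abs(ml$r(aa) - exp(-2e-5 * aa)) < 1e-6))
})

test_that("transform descriptors equal adaptive-quadrature Laplace integrals", {
  cases <- list(fig3_surface(), fig3_slowdown(), fig3_volumetric())
  for (p in cases) {
    for (n in c(1L, 2L)) {
      l <- make_growth_law(p, n)
      poles <- Re(c(rt_poles(l$K), rt_poles(l$Psi), rt_poles(l$Vt)))
      s <- max(poles) + c(0.002, 0.005, 0.01, 0.03, 0.1)
      for (tr in list(list(l$K, function(a) l$phi(a) * l$r(a)),
                      list(l$Psi, function(a) l$phi(a) * (1 - l$r(a))),
                      list(l$Vt, l$V))) {
        got <- Re(rt_eval(tr[[1]], s))
        want <- laplace_quadrature(tr[[2]], s)
        expect_true(all(abs(got - want) / pmax(abs(want), 1e-300) < 1e-8))
      }
    }
  }
})

test_that("law invariants: r in [0,1] non-increasing, phi >= 0, V non-decreasing, M = 0 means no seeding", {
  cases <- list(fig3_surface(), fig3_slowdown(), fig3_volumetric())
  aa <- seq(0, 4000, by = 50)
  for (p in cases) for (n in 1:3) {
    l <- make_growth_law(p, n)
    r <- l$r(aa)
    expect_true(all(r >= 0 & r <= 1))
    expect_true(all(diff(r) <= 1e-15))
    expect_true(all(l$phi(aa) >= 0))
    expect_true(all(diff(l$V(aa)) >= 0))
  }
  p0 <- model_params("surface", v1 = 0.1, M = 0, mu = 2e-5)
  l0 <- make_growth_law(p0, 1)
  expect_true(all(l0$phi(aa) == 0))
  expect_true(rt_eval(l0$K, 1) == 0)
})
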