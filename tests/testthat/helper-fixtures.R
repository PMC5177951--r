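# Shared fixtures and small oracles.

fig3_surface <- function() fig_params("fig3_surface")
fig3_slowdown <- function() fig_params("fig3_slowdown")
fig3_volumetric <- function() fig_params("fig3_volumetric")
fig4_params <- function() fig_params("fig4")

# numerical Laplace transform by adaptive quadrature (independent oracle
# for the analytic transform descriptors)
laplace_quadrature <- function(f, s, rel.tol = 1e-12) {
  vapply(s, function(si)
    stats::integrate(function(a) {
      v <- f(a) * exp(-si * a)
      # Inf * 0 at huge ages for exponential laws: the true product -> 0
      v[!is.finite(v)] <- 0
      v
    }, 0, Inf, rel.tol = rel.tol, subdivisions = 2000L)$value,
    numeric(1))
}

# bisection oracle for the single-type surface renewal root:
# 8 pi M v^3 / (G + mu)^3 = 1
el_root_bisect <- function(M, v, mu = 0) {
  f <- function(G) 8 * pi * M * v^3 / (G + mu)^3 - 1
  stats::uniroot(f, c(-mu + 1e-12, 1), tol = 1e-15)$root
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), .Machine$double.eps),
            tol)
}
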