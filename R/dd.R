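# Compensated (double-double) complex arithmetic for the partial-fraction
# cluster expansions.
#
# The dominant numerical hazard of the model is the high-multiplicity pole
# at s = 0 that the surface-growth cross kernels accumulate (order 3(n-1)+4
# for the type-n volume transform): the truncated-series division that
# extracts its Laurent coefficients cancels catastrophically in plain double
# precision once n exceeds ~4.  The inputs (pole locations) are analytic
# constructs known to full double accuracy, so carrying the series
# arithmetic in error-free-transformation double-double (~32 significant
# digits) recovers the residues to well below the round-trip tolerance.
#
# All operations are vectorized over aligned component vectors.  A dd number
# is list(hi, lo); a complex dd number is list(re = dd, im = dd).

dd_new <- function(hi, lo = 0) list(hi = hi, lo = lo + numeric(length(hi)))

dd_two_sum <- function(a, b) {
  s <- a + b
  bb <- s - a
  list(s = s, e = (a - (s - bb)) + (b - bb))
}

dd_split <- function(a) {
  c <- 134217729 * a      # 2^27 + 1
  hi <- c - (c - a)
  list(hi = hi, lo = a - hi)
}

dd_two_prod <- function(a, b) {
  p <- a * b
  sa <- dd_split(a); sb <- dd_split(b)
  e <- ((sa$hi * sb$hi - p) + sa$hi * sb$lo + sa$lo * sb$hi) + sa$lo * sb$lo
  list(p = p, e = e)
}

dd_norm <- function(hi, lo) {
  s <- hi + lo
  list(hi = s, lo = lo - (s - hi))
}

dd_add <- function(x, y) {
  t <- dd_two_sum(x$hi, y$hi)
  dd_norm(t$s, t$e + x$lo + y$lo)
}

dd_neg <- function(x) list(hi = -x$hi, lo = -x$lo)

dd_sub <- function(x, y) dd_add(x, dd_neg(y))

dd_mul <- function(x, y) {
  t <- dd_two_prod(x$hi, y$hi)
  dd_norm(t$p, t$e + x$hi * y$lo + x$lo * y$hi)
}

dd_div <- function(x, y) {
  q1 <- x$hi / y$hi
  r <- dd_sub(x, dd_mul(y, dd_new(q1)))
  q2 <- (r$hi + r$lo) / y$hi
  dd_norm(q1, q2)
}

dd_value <- function(x) x$hi + x$lo

# ---- complex double-double ----

cdd_new <- function(z) {
  z <- as.complex(z)
  list(re = dd_new(Re(z)), im = dd_new(Im(z)))
}

cdd_add <- function(x, y) list(re = dd_add(x$re, y$re), im = dd_add(x$im, y$im))

cdd_mul <- function(x, y) {
  list(re = dd_sub(dd_mul(x$re, y$re), dd_mul(x$im, y$im)),
       im = dd_add(dd_mul(x$re, y$im), dd_mul(x$im, y$re)))
}

cdd_div <- function(x, y) {
  den <- dd_add(dd_mul(y$re, y$re), dd_mul(y$im, y$im))
  num <- cdd_mul(x, list(re = y$re, im = dd_neg(y$im)))
  list(re = dd_div(num$re, den), im = dd_div(num$im, den))
}

cdd_value <- function(x) complex(real = dd_value(x$re), imaginary = dd_value(x$im))

cdd_index <- function(x, i) {
  list(re = list(hi = x$re$hi[i], lo = x$re$lo[i]),
       im = list(hi = x$im$hi[i], lo = x$im$lo[i]))
}

# ---- series operations in complex double-double ----
# a series is a cdd whose component vectors hold the coefficients of
# u^0, u^1, ... (fixed length `len`)

cdd_series_one <- function(len) {
  cdd_new(c(1 + 0i, rep(0 + 0i, len - 1)))
}

# multiply series by the linear factor (a + u), truncating
cdd_ser_mul_linear <- function(ser, a_cdd, len) {
  shifted <- cdd_index(ser, c(NA, seq_len(len - 1)))
  shifted$re$hi[1] <- 0; shifted$re$lo[1] <- 0
  shifted$im$hi[1] <- 0; shifted$im$lo[1] <- 0
  shifted$re$hi[is.na(shifted$re$hi)] <- 0
  shifted$re$lo[is.na(shifted$re$lo)] <- 0
  shifted$im$hi[is.na(shifted$im$hi)] <- 0
  shifted$im$lo[is.na(shifted$im$lo)] <- 0
  prod <- cdd_mul(ser, list(re = list(hi = rep(a_cdd$re$hi, len), lo = rep(a_cdd$re$lo, len)),
                            im = list(hi = rep(a_cdd$im$hi, len), lo = rep(a_cdd$im$lo, len))))
  cdd_add(prod, shifted)
}

# product over i of (constants[i] + u), truncated to len terms
cdd_ser_prod_linears <- function(constants, len) {
  ser <- cdd_series_one(len)
  for (a in constants) ser <- cdd_ser_mul_linear(ser, cdd_new(a), len)
  ser
}

# power-series division num/den (den[1] != 0), truncated to len terms
cdd_ser_div <- function(num, den, len) {
  out <- cdd_new(complex(len))
  den1 <- cdd_index(den, 1)
  for (j in seq_len(len)) {
    acc <- cdd_index(num, j)
    if (j > 1) {
      for (m in 2:j) {
        acc <- cdd_add(acc, cdd_mul(cdd_index(den, m),
                                    cdd_mul(cdd_index(out, j - m + 1),
                                            cdd_new(-1 + 0i))))
      }
    }
    q <- cdd_div(acc, den1)
    out$re$hi[j] <- q$re$hi; out$re$lo[j] <- q$re$lo
    out$im$hi[j] <- q$im$hi; out$im$lo[j] <- q$im$lo
  }
  out
}
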