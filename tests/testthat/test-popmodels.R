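test_that("population size evaluation covers the three history kinds", {
  expect_equal(pop_size(const_pop(1000), 5), 1000)
  expect_equal(pop_size(exp_pop(1000, r = 0), 7), 1000)
  expect_equal(pop_size(exp_pop(1000, r = 0.01), 100), 1000 * exp(-1))
  g <- general_pop(function(t) 500 + 10 * t)
  expect_equal(pop_size(g, c(0, 10)), c(500, 600))
  expect_error(pop_size(const_pop(1000), -1), "negative")
  expect_error(pop_size(general_pop(function(t) 1 - t), 2), "non-positive")
})

test_that("exp_pop accepts exactly one of r and rho", {
  expect_equal(exp_pop(1e4, rho = 100)$r, 0.01)
  expect_equal(exp_pop(1e4, r = 0.01)$rho, 100)
  expect_error(exp_pop(1e4), "exactly one")
  expect_error(exp_pop(1e4, r = 0.01, rho = 100), "exactly one")
})

test_that("time scale change has closed forms and a quadrature fallback", {
  expect_equal(time_scale(const_pop(2), 3), 1.5)
  expect_equal(time_scale(exp_pop(1000, r = 1e-12), 100), 0.1,
               tolerance = 1e-9)
  m <- exp_pop(1000, r = 0.01)
  expect_equal(time_scale(m, 100), (exp(1) - 1) / 10, tolerance = 1e-12)
  # general path against the exponential closed form
  g <- general_pop(function(t) 1000 * exp(-0.01 * t))
  expect_equal(time_scale(g, c(20, 100)), time_scale(m, c(20, 100)),
               tolerance = 1e-10)
})

test_that("inverse time scale round-trips on all kinds", {
  models <- list(const_pop(2), exp_pop(1000, r = 0.01),
                 general_pop(function(t) 800 + 50 * sin(t / 30)))
  for (m in models) {
    t0 <- c(0, 0.5, 3, 47, 211)
    expect_equal(inverse_time_scale(m, time_scale(m, t0)), t0,
                 tolerance = 1e-9)
  }
  expect_equal(inverse_time_scale(const_pop(2), 1.5), 3)
  expect_equal(inverse_time_scale(exp_pop(1000, r = 0.01), (exp(1) - 1) / 10),
               100, tolerance = 1e-10)
})

test_that("first coalescence density is exponential-family and normalized", {
  expect_equal(first_coal_density(const_pop(1), 2, c(0.3, 1, 2)),
               exp(-c(0.3, 1, 2)))
  t10 <- seq(0.1, 5000, length.out = 10)
  expect_equal(first_coal_density(exp_pop(1e3, r = 0), 4, t10),
               first_coal_density(const_pop(1e3), 4, t10))
  for (j in c(2, 10, 100, 1000)) {
    for (rho in c(0, 1, 10, 1e4)) {
      m <- if (rho == 0) const_pop(1e4) else exp_pop(1e4, rho = rho)
      # integrate by substitution tau = g(t): exact unit exponential in tau
      q <- stats::integrate(function(t) first_coal_density(m, j, t), 0,
                            inverse_time_scale(m, 30 / (j * (j - 1) / 2)),
                            rel.tol = 1e-10)
      expect_equal(q$value, 1, tolerance = 1e-8)
    }
  }
  expect_error(first_coal_density(const_pop(1), 1, 1), "j")
})

test_that("expected first coalescence times match closed forms and quadrature", {
  expect_equal(expected_first_coal_time(const_pop(500), 2), 500)
  expect_equal(expected_first_coal_time(exp_pop(500, r = 1e-14), 4), 500 / 6,
               tolerance = 1e-6)
  # independent quadrature oracle for the scaled-E1 closed form
  m <- exp_pop(2e6, r = 0.001)
  ej <- expected_first_coal_time(m, 3)
  q <- stats::integrate(function(t) t * first_coal_density(m, 3, t),
                        0, 5e4, rel.tol = 1e-11)$value
  expect_equal(ej, q, tolerance = 1e-8)
  # general history path
  g <- general_pop(function(t) 2e6 * exp(-0.001 * t))
  expect_equal(expected_first_coal_time(g, 5),
               expected_first_coal_time(m, 5), tolerance = 1e-7)
})

test_that("expected first coalescence time decreases in j and in rho", {
  e1 <- expected_first_coal_time(exp_pop(1e4, rho = 10), 2:60)
  expect_true(all(diff(e1) < 0))
  for (j in c(2, 7, 40)) {
    by_rho <- sapply(c(1, 10, 100, 1000),
                     function(rho) expected_first_coal_time(
                       exp_pop(1e4, rho = rho), j))
    expect_true(all(diff(by_rho) < 0))
  }
})

test_that("scaled exponential integral matches reference evaluations", {
  # pracma as the independent oracle where exp(x) is representable
  x <- 10^seq(-6, 2.5, length.out = 60)
  ref <- exp(x) * pracma::expint_E1(x)
  expect_rel(e1_scaled(x), ref, 1e-12)
  # far outside the overflow range: asymptotic series with a rigorous
  # truncation bound (first omitted term < 1e-18 relative for x >= 1e4)
  xl <- 10^seq(4, 8, length.out = 30)
  asym <- (1 / xl) * (1 - 1 / xl + 2 / xl^2 - 6 / xl^3 + 24 / xl^4)
  expect_rel(e1_scaled(xl), asym, 1e-12)
  expect_true(all(is.finite(e1_scaled(10^seq(-6, 8, length.out = 100)))))
})
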