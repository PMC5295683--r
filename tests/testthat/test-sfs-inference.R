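test_that("the packaged mtDNA spectrum reads back exactly", {
  sfs <- mtdna_spectrum()
  expect_equal(sfs$n, 2704)
  expect_true(sfs$folded)
  expect_equal(sfs$count[sfs$b == 1], 1231L)
  expect_equal(sfs$count[sfs$b == 944], 1L)
  expect_equal(sfs$total_sites, 3213L)
})

test_that("spectrum TSV round-trips and rejects malformed input", {
  sfs <- mtdna_spectrum()
  tmp <- tempfile(fileext = ".tsv")
  write_sfs(sfs, tmp)
  back <- read_sfs(tmp)
  expect_equal(back[c("n", "b", "count", "folded")],
               sfs[c("n", "b", "count", "folded")])
  writeLines(c("# folded=TRUE", "1\t10"), tmp)
  expect_error(read_sfs(tmp), "n=")
  writeLines(c("# n=10", "1\t2.5"), tmp)
  expect_error(read_sfs(tmp), "line 1")
  expect_error(as_sfs(10, c(1, 9), c(3, 1), folded = TRUE), "n/2")
})

test_that("site-class probabilities are normalized, rho-only, and reduce to
           the 1/b law", {
  for (folded in c(FALSE, TRUE)) {
    p <- site_class_probability(2704, rho = 339.3, folded = folded)
    expect_equal(sum(p), 1, tolerance = 1e-10)
  }
  n <- 200
  p0 <- site_class_probability(n, rho = 0)
  expect_rel(p0, (1 / (1:(n - 1))) / sum(1 / (1:(n - 1))), 1e-8)
  # folding adds complementary classes
  pf <- site_class_probability(n, rho = 5, folded = TRUE)
  pu <- site_class_probability(n, rho = 5)
  expect_equal(pf[3], pu[3] + pu[n - 3])
  expect_equal(pf[n / 2], pu[n / 2])
})

test_that("the likelihood depends on the demography only through rho", {
  # the internal reference N0 cancels: check through the two backends'
  # scale-free construction by refitting a small spectrum under rescaled
  # parameterizations of the same rho
  sfs <- as_sfs(50, b = c(1, 2, 3, 7), count = c(60, 25, 11, 4))
  l1 <- sfs_loglik(sfs, 80)
  # direct spectrum computed at two (N0, r) pairs with equal product
  f1 <- expected_spectrum(exp_pop(1e4, r = 80 / 1e4), 50, 1e-6)$p
  f2 <- expected_spectrum(exp_pop(1e6, r = 80 / 1e6), 50, 1e-6)$p
  expect_equal(f1, f2, tolerance = 1e-10)
  expect_true(is.finite(l1))
})

test_that("log-likelihood is the multinomial kernel in the counts", {
  s1 <- as_sfs(4, b = 1, count = 1)
  expect_equal(sfs_loglik(s1, 0), log(6 / 11))
  s2 <- as_sfs(4, b = c(1, 3), count = c(4, 2))
  s2_doubled <- as_sfs(4, b = c(1, 3), count = c(8, 4))
  expect_equal(sfs_loglik(s2_doubled, 10), 2 * sfs_loglik(s2, 10))
})

test_that("growth fits recover simulated parameters and flag boundary
           argmaxes", {
  sim <- simulate_sfs(300, exp_pop(1e4, rho = 300), 3000, seed = 21)
  fit <- fit_exponential_growth(sim, 30, 2000, grid_points = 30)
  expect_gt(fit$rho_hat, 200)
  expect_lt(fit$rho_hat, 450)
  # constant-size data: no spurious growth signal
  sim0 <- simulate_sfs(300, const_pop(1e4), 3000, seed = 22)
  expect_warning(
    fit0 <- fit_exponential_growth(sim0, 0.5, 2000, grid_points = 25),
    "boundary")
  expect_equal(fit0$rho_hat, 0.5)
})

test_that("the mtDNA bootstrap interval overlaps the externally simulated
           reference interval", {
  # the reference (285, 403) came from 1000 external coalescent
  # simulations; only stochastic overlap is a meaningful check
  sfs <- mtdna_spectrum()
  ci <- bootstrap_ci(sfs, 339.2, replicates = 120, seed = 7)
  expect_lt(ci$lower, 403)
  expect_gt(ci$upper, 285)
  expect_lt(ci$lower, 339.2)
  expect_gt(ci$upper, 339.2)
})

test_that("bootstrap interval brackets the estimate and narrows with more
           sites", {
  set.seed(5)
  m <- exp_pop(1e4, rho = 300)
  sim <- simulate_sfs(400, m, 3000, seed = 31)
  fit <- fit_exponential_growth(sim, 30, 2000, grid_points = 25)
  ci <- bootstrap_ci(sim, fit$rho_hat, replicates = 100, seed = 32,
                     rho_min = 30, rho_max = 2000)
  expect_lt(ci$lower, fit$rho_hat)
  expect_gt(ci$upper, fit$rho_hat)
  expect_equal(ci$failures, 0)
  # width shrinks with total sites
  sim_big <- simulate_sfs(400, m, 10000, seed = 33)
  fit_big <- fit_exponential_growth(sim_big, 30, 2000, grid_points = 25)
  ci_big <- bootstrap_ci(sim_big, fit_big$rho_hat, replicates = 100,
                         seed = 34, rho_min = 30, rho_max = 2000)
  expect_lt(ci_big$upper - ci_big$lower, ci$upper - ci$lower)
})
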