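# shared oracles, independent of the package's computational paths

# hypoexponential moments of T_k on the coalescent scale (constant size,
# N0 = 1): sum of independent exponentials with rates C(j,2), j = k..n
hypo_rates <- function(n, k) {
  j <- k:n
  j * (j - 1) / 2
}
hypo_mean <- function(n, k) sum(1 / hypo_rates(n, k))
hypo_var <- function(n, k) sum(1 / hypo_rates(n, k)^2)
hypo_skew <- function(n, k) {
  lam <- hypo_rates(n, k)
  2 * sum(1 / lam^3) / sum(1 / lam^2)^1.5
}

# brute-force expected spectrum through the direct combinatorial formula,
# small n only (naive factorials)
brute_spectrum <- function(es_k, mu = 1) {
  n <- length(es_k) + 1
  sapply(1:(n - 1), function(b) {
    kk <- 2:n
    mu * factorial(n - b - 1) * factorial(b - 1) / factorial(n - 1) *
      sum(choose(n - kk, b - 1) * kk * (kk - 1) * es_k)
  })
}

expect_rel <- function(x, y, tol) {
  expect_lt(max(abs(x - y) / abs(y)), tol)
}

grid_cdf <- function(grid) {
  cumsum(coaltimes:::integ_weights(grid$times) * grid$values)
}
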