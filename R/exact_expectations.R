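#' Expected height of the coalescent tree, stable for large samples
#'
#' Expected time to the most recent common ancestor of a sample of size
#' \code{n} under an arbitrary size history, computed from the
#' hypergeometric-sum representation
#' \deqn{ETMRCA = \sum_{j=2}^{n} (2j-1)
#'   \frac{n!\,(n-1)!}{(n+j-1)!\,(n-j)!} (-1)^j e_j,}
#' with the factorial ratio accumulated multiplicatively term to term, so
#' that no factorial is ever formed and the sum remains finite and accurate
#' for \code{n} into the hundreds of thousands.
#'
#' @param model a \code{coal_history}.
#' @param n sample size, \eqn{n \ge 2}.
#' @return expected TMRCA in generations.
#' @examples
#' etmrca_stable(const_pop(1e4), 10)  # 2e4 * (1 - 1/10)
#' @export
etmrca_stable <- function(model, n) {
  check_model(model)
  stopifnot(length(n) == 1L, n == as.integer(n), n >= 2)
  e <- expected_first_coal_time(model, 2:n)
  sum(hyper_coef(n, signed = TRUE) * e)
}

#' Expected total branch length of the coalescent tree, stable for large
#' samples
#'
#' Companion of \code{\link{etmrca_stable}}: the same hypergeometric sum
#' with the alternating sign \eqn{(-1)^j} replaced by \eqn{1 + (-1)^j}, so
#' odd-\eqn{j} terms vanish.
#'
#' @inheritParams etmrca_stable
#' @return expected total branch length (TLBT) in generations.
#' @examples
#' etlbt_stable(const_pop(1e4), 4)  # 2e4 * (1 + 1/2 + 1/3)
#' @export
etlbt_stable <- function(model, n) {
  check_model(model)
  stopifnot(length(n) == 1L, n == as.integer(n), n >= 2)
  e <- expected_first_coal_time(model, 2:n)
  d <- hyper_coef(n, signed = FALSE)
  j <- 2:n
  sum(d * (1 + (-1)^j) * e)
}

# coefficients (2j-1) n!(n-1)!/[(n+j-1)!(n-j)!], j = 2..n, built by the
# term ratio c_{j+1}/c_j = (2j+1)/(2j-1) * (n-j)/(n+j); signed = TRUE adds
# the (-1)^j factor
hyper_coef <- function(n, signed = FALSE) {
  out <- numeric(n - 1)
  c_j <- 3 * (n - 1) / (n + 1)             # j = 2
  out[1] <- c_j
  j <- 2
  while (j < n) {
    c_j <- c_j * (2 * j + 1) / (2 * j - 1) * (n - j) / (n + j)
    out[j] <- c_j
    j <- j + 1
  }
  if (signed) out <- out * (-1)^(2:n)
  out
}

#' Spectrum recursion coefficients
#'
#' The coefficients \eqn{W_{bjn}} linking expected first-coalescence times
#' to the expected allele-frequency spectrum,
#' \eqn{f_{nb} = \mu \sum_{j=2}^n W_{bjn} e_j}. They satisfy a three-term
#' recursion in \eqn{j} seeded by
#' \eqn{W_{b2n} = 6/(n+1)} and \eqn{W_{b3n} = 30(n-2b)/[(n+1)(n+2)]}
#' (the divided reading of both seeds is the one consistent with the
#' constant-size \eqn{1/b} spectrum, which the test suite checks).
#' Exposed mainly for testing and didactic use; spectrum assembly in
#' \code{\link{expected_spectrum}} runs the recursion in C without storing
#' it.
#'
#' @param n sample size, \eqn{n \ge 2}.
#' @param b allele count, \eqn{1 \le b \le n-1}.
#' @return numeric vector of \eqn{W_{bjn}} for \eqn{j = 2, \dots, n}.
#' @export
w_coefficients <- function(n, b) {
  stopifnot(length(n) == 1L, n == as.integer(n), n >= 2,
            length(b) == 1L, b == as.integer(b))
  if (b < 1 || b > n - 1) stop("`b` must satisfy 1 <= b <= n - 1")
  w <- numeric(n - 1)
  w[1] <- 6 / (n + 1)
  if (n >= 3) w[2] <- 30 * (n - 2 * b) / ((n + 1) * (n + 2))
  if (n >= 4) {
    for (j in 2:(n - 2)) {
      w[j + 1] <- -((1 + j) * (3 + 2 * j) * (n - j)) /
                    (j * (2 * j - 1) * (n + j + 1)) * w[j - 1] +
                  (3 + 2 * j) * (n - 2 * b) / (j * (n + j + 1)) * w[j]
    }
  }
  names(w) <- paste0("j", 2:n)
  w
}

#' Expected allele-frequency spectrum
#'
#' Expected number \eqn{f_{nb}} of segregating sites with \eqn{b} mutant
#' copies in a sample of \code{n} sequences under the infinite-sites model,
#' and the normalized class probabilities \eqn{p_{nb} = f_{nb}/\sum_b
#' f_{nb}}. Uses the numerically stable recursion of
#' \code{\link{w_coefficients}} accumulated against the expected
#' first-coalescence times \eqn{e_j}; the whole spectrum costs
#' \eqn{O(n^2)} time and \eqn{O(n)} memory and remains accurate for sample
#' sizes of order \eqn{10^5}.
#'
#' @inheritParams etmrca_stable
#' @param mu per-locus mutation intensity (mutations per generation),
#'   positive. Only \eqn{f_{nb}} depends on it; \eqn{p_{nb}} does not.
#' @return An object of class \code{coal_spectrum}: list with \code{n},
#'   \code{mu}, \code{f} (length \eqn{n-1}), \code{p} (length \eqn{n-1}),
#'   and the \code{model}.
#' @examples
#' sp <- expected_spectrum(const_pop(1e4), 4, mu = 1e-6)
#' sp$p  # (6, 3, 2)/11: the 1/b spectrum, normalized
#' @export
expected_spectrum <- function(model, n, mu) {
  check_model(model)
  stopifnot(length(n) == 1L, n == as.integer(n), n >= 2,
            length(mu) == 1L, is.finite(mu), mu > 0)
  e <- expected_first_coal_time(model, 2:n)
  f <- mu * cpp_spectrum_from_ej(e)
  structure(list(n = n, mu = mu, f = f, p = f / sum(f), model = model),
            class = "coal_spectrum")
}

#' @export
print.coal_spectrum <- function(x, ...) {
  cat(sprintf("<coal_spectrum> n = %d, mu = %g, %d allele classes\n",
              x$n, x$mu, length(x$f)))
  cat(sprintf("  singleton share p_n1 = %.4f, E(#sites)/locus = %g\n",
              x$p[1], sum(x$f)))
  invisible(x)
}

#' Partial-fraction coefficients of a hypoexponential coalescence time
#'
#' Coefficients \eqn{A_{jkn} = \prod_{l=k, l \ne j}^{n}
#' \lambda_l/(\lambda_l - \lambda_j)} with \eqn{\lambda_m = \binom{m}{2}},
#' arising from the partial-fraction expansion of the product transform of
#' \eqn{T_k}. They grow combinatorially with alternating signs, which is
#' why everything downstream of them is guarded to \eqn{n \le 50}.
#'
#' @param n sample size, \eqn{2 \le n \le 50}.
#' @param k target lineage count, \eqn{2 \le k \le n}.
#' @return numeric vector of \eqn{A_{jkn}}, \eqn{j = k, \dots, n}.
#' @export
partial_fraction_coef <- function(n, k) {
  stopifnot(length(n) == 1L, n == as.integer(n),
            length(k) == 1L, k == as.integer(k), 2 <= k, k <= n)
  if (n > 50)
    stop("partial-fraction coefficients diverge for n > 50; ",
         "use etmrca_stable/expected_spectrum or the inversion paths")
  lam <- (k:n) * ((k:n) - 1) / 2
  vapply(seq_along(lam), function(i) {
    prod(lam[-i] / (lam[-i] - lam[i]))
  }, numeric(1))
}

#' Exact per-k expectations for small samples
#'
#' Classical partial-fraction route to \eqn{E(T_k)} for all
#' \eqn{k = 2, \dots, n}: \eqn{E(T_k) = \sum_{j=k}^{n} A_{jkn} e_j}, with
#' \eqn{E(S_k)} recovered by differencing
#' (\eqn{E(S_k) = E(T_k) - E(T_{k+1})}, \eqn{E(T_{n+1}) = 0}). The
#' coefficients \eqn{A_{jkn}} blow up with alternating signs as \eqn{n}
#' grows, so this path is guarded to \eqn{n \le 50}; it serves as the
#' oracle against which the large-\eqn{n} machinery is validated.
#'
#' @inheritParams etmrca_stable
#' @return An object of class \code{coal_expectations}: list with \code{n},
#'   \code{model}, \code{e_j} (\eqn{j = 2..n}), \code{et_k}, \code{es_k}
#'   (both \eqn{k = 2..n}), \code{etmrca}, \code{etlbt}.
#' @examples
#' ex <- expected_times_smalln(const_pop(1), 3)
#' ex$et_k[["k2"]]  # 4/3: hypoexponential mean 1 + 1/3
#' @export
expected_times_smalln <- function(model, n) {
  check_model(model)
  stopifnot(length(n) == 1L, n == as.integer(n), n >= 2)
  if (n > 50)
    stop("expected_times_smalln is guarded to n <= 50 (coefficients ",
         "diverge); use etmrca_stable/etlbt_stable or the inversion paths")
  e <- expected_first_coal_time(model, 2:n)
  et <- vapply(2:n, function(k) {
    sum(partial_fraction_coef(n, k) * e[(k - 1):(n - 1)])
  }, numeric(1))
  es <- et - c(et[-1], 0)
  names(et) <- names(es) <- paste0("k", 2:n)
  structure(list(n = n, model = model, e_j = e, et_k = et, es_k = es,
                 etmrca = et[[1]], etlbt = et[[1]] + sum(et)),
            class = "coal_expectations")
}

#' @export
print.coal_expectations <- function(x, ...) {
  cat(sprintf("<coal_expectations> n = %d: ETMRCA = %g, ETLBT = %g\n",
              x$n, x$etmrca, x$etlbt))
  invisible(x)
}
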