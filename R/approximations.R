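#' Large-sample approximation of an expected coalescence time
#'
#' Closed-form deterministic approximation of \eqn{E(T_k)} under
#' exponential growth,
#' \deqn{E(T_k) \approx \frac{1}{r}\ln\left[2rN_0\left(\frac{1}{k-1} -
#'   \frac{1}{n}\right) + 1\right],}
#' obtained by tracking the expected pure-death process of lineage counts
#' through the time-scale change. At \eqn{r = 0} the limit
#' \eqn{2N_0(1/(k-1) - 1/n)} is returned, which is also the exact
#' constant-size value.
#'
#' @param n sample size, \eqn{n \ge 2}.
#' @param k target lineage count(s), \eqn{2 \le k \le n}; may be a vector.
#' @param N0 present-day size (coalescent scale).
#' @param r growth exponent per generation, \eqn{r \ge 0}.
#' @return approximate \eqn{E(T_k)} in generations, one value per \code{k}.
#' @examples
#' approx_expected_time(800, 6, 2e6, 0.001)  # 1000 * log(796) = 6679.599
#' @export
approx_expected_time <- function(n, k, N0, r) {
  stopifnot(length(n) == 1L, n >= 2, all(k >= 2), all(k <= n),
            N0 > 0, length(r) == 1L, r >= 0)
  x <- 2 * N0 * (1 / (k - 1) - 1 / n)
  if (r == 0) x else log1p(r * x) / r
}

#' @rdname approx_expected_time
#' @export
approx_etmrca <- function(n, N0, r) approx_expected_time(n, 2, N0, r)

#' Large-sample approximation of the expected total branch length
#'
#' Deterministic approximation under exponential growth (\eqn{r > 0}):
#' \deqn{ETLBT \approx \frac{2 n N_0}{2 r N_0 - n}
#'   \ln\frac{2 r N_0}{n},}
#' from integrating the expected lineage count over time. At the removable
#' singularity \eqn{n = 2 r N_0 = 2\rho} the limit \eqn{2 N_0} is used.
#' The expression is valid on both sides of \eqn{n = 2\rho} (the sign of
#' the logarithm and of the denominator cancel); its accuracy improves
#' with \eqn{\rho} and \eqn{n}, reaching relative errors of order
#' \eqn{10^{-3}} for \eqn{\rho > 10}, \eqn{n > 100}.
#'
#' @inheritParams approx_expected_time
#' @return approximate expected total branch length in generations.
#' @export
approx_etlbt <- function(n, N0, r) {
  stopifnot(length(n) == 1L, n >= 2, N0 > 0, length(r) == 1L)
  if (r <= 0)
    stop("the total-branch-length approximation requires r > 0 ",
         "(it diverges logarithmically as r -> 0)")
  rho2 <- 2 * r * N0
  if (abs(rho2 - n) < 1e-9 * n) return(2 * N0)  # removable singularity
  2 * n * N0 * log(rho2 / n) / (rho2 - n)
}

#' Approximate expected allele-frequency spectrum
#'
#' Substitutes the closed-form expected coalescence times of
#' \code{\link{approx_expected_time}} (differenced to interval expectations
#' \eqn{E(S_k) = E(T_k) - E(T_{k+1})}) into the combinatorial spectrum
#' formula. Relative errors against the exact spectrum are of order
#' \eqn{10^{-4}}\eqn{-}\eqn{10^{-3}} for low allele counts \eqn{b} and grow
#' toward high \eqn{b}.
#'
#' @inheritParams approx_expected_time
#' @param mu per-locus mutation intensity, positive.
#' @return A \code{coal_spectrum} (same shape as
#'   \code{\link{expected_spectrum}}).
#' @export
approx_spectrum <- function(n, N0, r, mu) {
  stopifnot(length(n) == 1L, n == as.integer(n), n >= 2, mu > 0)
  et <- approx_expected_time(n, 2:n, N0, r)
  es <- et - c(et[-1], 0)
  if (any(es < 0)) {
    warning(sprintf("%d negative differenced E(S_k) values clipped to 0",
                    sum(es < 0)))
    es <- pmax(es, 0)
  }
  f <- mu * cpp_spectrum_from_esk(es)
  model <- if (r == 0) const_pop(N0) else exp_pop(N0, r = r)
  structure(list(n = n, mu = mu, f = f, p = f / sum(f), model = model),
            class = "coal_spectrum")
}

#' Relative-error report for the large-sample approximations
#'
#' Pairs each closed-form approximation with its exact counterpart
#' (stable sums for ETMRCA/ETLBT, small-sample partial fractions or
#' transform inversion for per-k times, the stable recursion for spectra)
#' and reports \eqn{|approx - exact| / exact}.
#'
#' @param n sample size.
#' @param model an exponential or constant \code{coal_history}.
#' @param quantities subset of
#'   \code{c("etmrca", "etlbt", "et_k", "spectrum")}.
#' @param k for \code{"et_k"}: which lineage counts to report (requires
#'   \eqn{n \le 50}, where the exact partial-fraction path is available).
#' @param mu mutation intensity used for the spectrum comparison (cancels
#'   in the relative error).
#' @return data.frame with columns \code{quantity}, \code{n}, \code{rho},
#'   \code{index} (k or b, NA otherwise), \code{exact}, \code{approx},
#'   \code{rel_error}.
#' @export
relative_error_report <- function(n, model,
                                  quantities = c("etmrca", "etlbt"),
                                  k = NULL, mu = 1e-6) {
  check_model(model)
  if (!model$kind %in% c("constant", "exponential"))
    stop("error reports are defined for constant/exponential histories")
  quantities <- match.arg(quantities,
                          c("etmrca", "etlbt", "et_k", "spectrum"),
                          several.ok = TRUE)
  N0 <- model$N0; r <- model$r
  rows <- list()
  add <- function(quantity, index, exact, approx) {
    rows[[length(rows) + 1L]] <<- data.frame(
      quantity = quantity, n = n, rho = model$rho, index = index,
      exact = exact, approx = approx,
      rel_error = abs(approx - exact) / exact)
  }
  if ("etmrca" %in% quantities)
    add("ETMRCA", NA, etmrca_stable(model, n), approx_etmrca(n, N0, r))
  if ("etlbt" %in% quantities)
    add("ETLBT", NA, etlbt_stable(model, n), approx_etlbt(n, N0, r))
  if ("et_k" %in% quantities) {
    if (is.null(k)) k <- unique(round(seq(2, n, length.out = 5)))
    ex <- expected_times_smalln(model, n)
    for (kk in k)
      add("E(T_k)", kk, ex$et_k[[paste0("k", kk)]],
          approx_expected_time(n, kk, N0, r))
  }
  if ("spectrum" %in% quantities) {
    fe <- expected_spectrum(model, n, mu)$f
    fa <- approx_spectrum(n, N0, r, mu)$f
    for (b in seq_len(n - 1)) add("f_nb", b, fe[b], fa[b])
  }
  do.call(rbind, rows)
}

#' Round-off perturbation study for the spectrum recursion
#'
#' Conservative upper bound on the maximum relative error of computed
#' allele frequencies: each expected first-coalescence time \eqn{e_j} is
#' corrupted by multiplicative Gaussian noise of relative standard
#' deviation \code{sigma} (one or two orders of magnitude above the true
#' round-off level of the scaled-exponential-integral evaluation), the
#' spectrum is recomputed through the stable recursion, and
#' \eqn{\max_b |f^{(\sigma)}_{nb} - f_{nb}| / f_{nb}} is reported,
#' maximized over replicates. A small bound certifies that the recursion
#' does not amplify round-off for the given \eqn{(n, \rho)}.
#'
#' @inheritParams etmrca_stable
#' @param sigma relative perturbation standard deviation, \eqn{\ge 0}.
#' @param replicates number of noise replicates, \eqn{\ge 1}.
#' @param seed integer seed for the perturbations.
#' @return the maximum relative spectrum error over all classes and
#'   replicates (0 when \code{sigma = 0}).
#' @export
roundoff_error_bound <- function(model, n, sigma, replicates = 3L,
                                 seed = 1L) {
  check_model(model)
  stopifnot(sigma >= 0, replicates >= 1)
  if (sigma == 0) return(0)
  e <- expected_first_coal_time(model, 2:n)
  f0 <- cpp_spectrum_from_ej(e)
  set.seed(seed)
  mx <- 0
  for (i in seq_len(replicates)) {
    ep <- e * (1 + stats::rnorm(length(e), sd = sigma))
    fp <- cpp_spectrum_from_ej(ep)
    mx <- max(mx, max(abs(fp - f0) / f0))
  }
  mx
}
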