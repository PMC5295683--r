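#' Population-size histories
#'
#' Constructors for deterministic effective population-size trajectories
#' \eqn{N(t)}, with time \eqn{t} measured in generations from the present
#' (\eqn{t = 0}) into the past. \code{const_pop} gives \eqn{N(t) = N_0},
#' \code{exp_pop} gives exponential growth looking forward in time, i.e.
#' \eqn{N(t) = N_0 e^{-rt}} backward, and \code{general_pop} wraps an
#' arbitrary positive size function.
#'
#' \eqn{N_0} is on the coalescent (haploid) scale: under constant size the
#' expected waiting time while \eqn{k} lineages are present is
#' \eqn{N_0 / \binom{k}{2}} generations. No diploid \eqn{2N} conversion is
#' applied anywhere in the package.
#'
#' For the exponential model the product parameter \eqn{\rho = r N_0}
#' determines the shape of coalescent distributions up to a time rescaling;
#' it is stored on the object and printed. Exactly one of \code{r} and
#' \code{rho} must be supplied; \code{rho} implies \code{r = rho / N0}.
#' \code{r = 0} reduces the exponential model to the constant one.
#'
#' @param N0 present-day effective size (coalescent scale), positive.
#' @param r growth exponent per generation, \eqn{r \ge 0}.
#' @param rho alternative parameterization, \eqn{\rho = r N_0}.
#' @param size_fn positive, piecewise-continuous function of \eqn{t \ge 0};
#'   must accept a vector argument.
#' @param breakpoints optional numeric vector of discontinuity locations of
#'   \code{size_fn}, passed to the quadrature routines.
#' @return An object of class \code{coal_history}.
#' @examples
#' const_pop(1e4)
#' exp_pop(2e6, r = 0.001)
#' exp_pop(1e4, rho = 100)
#' general_pop(function(t) 1e4 * (1 + 0.5 * sin(t / 50)))
#' @export
const_pop <- function(N0) {
  stopifnot(is.numeric(N0), length(N0) == 1L, is.finite(N0), N0 > 0)
  structure(list(kind = "constant", N0 = N0, r = 0, rho = 0),
            class = "coal_history")
}

#' @rdname const_pop
#' @export
exp_pop <- function(N0, r = NULL, rho = NULL) {
  stopifnot(is.numeric(N0), length(N0) == 1L, is.finite(N0), N0 > 0)
  if (is.null(r) == is.null(rho))
    stop("supply exactly one of `r` and `rho`")
  if (is.null(r)) r <- rho / N0
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r), r >= 0)
  structure(list(kind = "exponential", N0 = N0, r = r, rho = r * N0),
            class = "coal_history")
}

#' @rdname const_pop
#' @export
general_pop <- function(size_fn, breakpoints = NULL) {
  stopifnot(is.function(size_fn))
  n0 <- size_fn(0)
  if (!is.finite(n0) || n0 <= 0)
    stop("size_fn(0) must be a finite positive number")
  structure(list(kind = "general", N0 = n0, size_fn = size_fn,
                 breakpoints = breakpoints),
            class = "coal_history")
}

#' @export
print.coal_history <- function(x, ...) {
  switch(x$kind,
    constant = cat(sprintf("<coal_history> constant, N0 = %g\n", x$N0)),
    exponential = cat(sprintf(
      "<coal_history> exponential, N0 = %g, r = %g (rho = %g)\n",
      x$N0, x$r, x$rho)),
    general = cat(sprintf("<coal_history> general N(t), N(0) = %g\n", x$N0)))
  invisible(x)
}

is_coal_history <- function(x) inherits(x, "coal_history")

check_model <- function(model) {
  if (!is_coal_history(model))
    stop("`model` must be a coal_history (see const_pop/exp_pop/general_pop)")
  invisible(model)
}

#' Evaluate a population-size history
#'
#' @param model a \code{coal_history}.
#' @param t vector of times in generations, \eqn{t \ge 0}.
#' @return \eqn{N(t)}, same length as \code{t}.
#' @examples
#' pop_size(exp_pop(1000, r = 0.01), 100)  # 1000 * exp(-1)
#' @export
pop_size <- function(model, t) {
  check_model(model)
  stopifnot(is.numeric(t), all(is.finite(t)))
  if (any(t < 0)) stop("negative times are not allowed")
  out <- switch(model$kind,
    constant = rep.int(model$N0, length(t)),
    exponential = model$N0 * exp(-model$r * t),
    general = {
      v <- model$size_fn(t)
      if (length(v) != length(t))
        stop("size_fn must be vectorized over t")
      bad <- !is.finite(v) | v <= 0
      if (any(bad))
        stop(sprintf("size_fn evaluated to a non-positive value at t = %g",
                     t[which(bad)[1L]]))
      v
    })
  as.numeric(out)
}

#' Coalescent time-scale change and its inverse
#'
#' \code{time_scale} maps real time to the coalescent's internal clock,
#' \eqn{\tau = g(t) = \int_0^t d\sigma / N(\sigma)}; on the \eqn{\tau} scale
#' the process is a standard constant-size coalescent with \eqn{N_0 = 1}.
#' \code{inverse_time_scale} computes \eqn{t = g^{-1}(\tau)}.
#'
#' Closed forms are used for the constant (\eqn{\tau = t/N_0}) and
#' exponential (\eqn{\tau = (e^{rt}-1)/(rN_0)},
#' \eqn{t = \ln(1 + N_0 r \tau)/r}) histories. General histories use
#' adaptive quadrature for \eqn{g} and a bracket-growing monotone
#' bisection/secant hybrid for \eqn{g^{-1}} (tolerance 1e-12 in \eqn{\tau});
#' \eqn{g} is strictly increasing because \eqn{N(t) > 0}.
#'
#' @inheritParams pop_size
#' @param tau vector of scaled times, \eqn{\tau \ge 0}.
#' @return Numeric vector of scaled times (\code{time_scale}) or times in
#'   generations (\code{inverse_time_scale}).
#' @examples
#' m <- exp_pop(1000, r = 0.01)
#' time_scale(m, 100)                 # (e - 1)/10
#' inverse_time_scale(m, (exp(1) - 1) / 10)  # 100
#' @export
time_scale <- function(model, t) {
  check_model(model)
  stopifnot(is.numeric(t), all(is.finite(t)))
  if (any(t < 0)) stop("negative times are not allowed")
  switch(model$kind,
    constant = t / model$N0,
    exponential = {
      if (model$r == 0) t / model$N0
      else expm1(model$r * t) / (model$r * model$N0)
    },
    general = general_time_scale(model, t))
}

general_time_scale <- function(model, t) {
  # integrate 1/N once over sorted increments, honouring breakpoints
  ord <- order(t)
  ts <- t[ord]
  out <- numeric(length(ts))
  f <- function(s) 1 / pop_size(model, s)
  lo <- 0
  acc <- 0
  for (i in seq_along(ts)) {
    hi <- ts[i]
    if (hi > lo) {
      bp <- model$breakpoints
      cuts <- sort(unique(c(lo, hi, bp[bp > lo & bp < hi])))
      for (j in seq_len(length(cuts) - 1L)) {
        q <- tryCatch(
          stats::integrate(f, cuts[j], cuts[j + 1L],
                           rel.tol = 1e-12, abs.tol = 0,
                           subdivisions = 500L),
          error = function(e)
            stop(sprintf(
              "quadrature of 1/N(t) failed on [%g, %g]: %s",
              cuts[j], cuts[j + 1L], conditionMessage(e))))
        acc <- acc + q$value
      }
      lo <- hi
    }
    out[i] <- acc
  }
  out[order(ord)]
}

#' @rdname time_scale
#' @export
inverse_time_scale <- function(model, tau) {
  check_model(model)
  stopifnot(is.numeric(tau), all(is.finite(tau)))
  if (any(tau < 0)) stop("negative scaled times are not allowed")
  switch(model$kind,
    constant = tau * model$N0,
    exponential = {
      if (model$r == 0) tau * model$N0
      else log1p(model$N0 * model$r * tau) / model$r
    },
    general = vapply(tau, function(x) general_inverse_ts(model, x),
                     numeric(1)))
}

general_inverse_ts <- function(model, tau, tol = 1e-12) {
  if (tau == 0) return(0)
  # grow the bracket until g(hi) >= tau; start low so that size functions
  # decaying toward zero in the deep past are never evaluated far beyond
  # the root (where they may underflow)
  hi <- model$N0 * 1e-3
  g_hi <- time_scale(model, hi)
  it <- 0L
  while (g_hi < tau) {
    hi <- hi * 2
    g_hi <- time_scale(model, hi)
    it <- it + 1L
    if (it > 200L)
      stop(sprintf(
        "could not bracket g^{-1}(%g): g(%g) = %g still below target",
        tau, hi, g_hi))
  }
  lo <- 0; g_lo <- 0
  for (iter in 1:200) {
    # alternate secant (fast near the root) with bisection (guaranteed
    # interval shrinkage, so a flat-sided secant cannot stall)
    mid <- if (iter %% 2 == 0) (lo + hi) / 2
           else lo + (tau - g_lo) * (hi - lo) / (g_hi - g_lo)
    if (!is.finite(mid) || mid <= lo || mid >= hi) mid <- (lo + hi) / 2
    g_mid <- time_scale(model, mid)
    if (abs(g_mid - tau) <= tol * max(1, tau)) return(mid)
    if (g_mid < tau) { lo <- mid; g_lo <- g_mid } else { hi <- mid; g_hi <- g_mid }
    if (hi - lo <= 1e-13 * max(1, hi)) return((lo + hi) / 2)
  }
  stop(sprintf("root-finder for g^{-1} did not converge on [%g, %g]", lo, hi))
}

#' Density of the first coalescence time
#'
#' Waiting-time density for the first merger in a sample of \code{j}
#' lineages under history \eqn{N(t)}:
#' \eqn{q_j(t) = \binom{j}{2}/N(t) \exp(-\binom{j}{2} g(t))}. It is a proper
#' density on \eqn{[0, \infty)} for any positive \eqn{N(t)}.
#'
#' @inheritParams pop_size
#' @param j number of lineages, \eqn{j \ge 2}.
#' @return density values at \code{t}.
#' @examples
#' first_coal_density(const_pop(1), 2, 1)  # exp(-1)
#' @export
first_coal_density <- function(model, j, t) {
  check_model(model)
  stopifnot(length(j) == 1L, j == as.integer(j), j >= 2)
  lam <- j * (j - 1) / 2
  lam / pop_size(model, t) * exp(-lam * time_scale(model, t))
}

#' Expected time to the first coalescence
#'
#' Mean of \code{\link{first_coal_density}}. Constant history:
#' \eqn{e_j = N_0/\binom{j}{2}}. Exponential history: with
#' \eqn{\beta_j = \binom{j}{2}/(rN_0)},
#' \eqn{e_j = e^{\beta_j} E_1(\beta_j) / r}, evaluated through the scaled
#' exponential integral \code{\link{e1_scaled}} so that no overflow occurs
#' even for \eqn{\beta_j} of order \eqn{10^8} and beyond. General histories
#' integrate \eqn{t\,q_j(t)} numerically.
#'
#' @inheritParams first_coal_density
#' @param j vector of lineage counts, each \eqn{\ge 2}.
#' @return expected first-coalescence times \eqn{e_j}, one per element of
#'   \code{j}, in generations.
#' @examples
#' expected_first_coal_time(const_pop(500), 2)  # 500
#' @export
expected_first_coal_time <- function(model, j) {
  check_model(model)
  stopifnot(is.numeric(j), all(j == as.integer(j)), all(j >= 2))
  lam <- j * (j - 1) / 2
  switch(model$kind,
    constant = model$N0 / lam,
    exponential = {
      if (model$r == 0) model$N0 / lam
      else e1_scaled(lam / model$rho) / model$r
    },
    general = vapply(lam, function(l) general_ej(model, l), numeric(1)))
}

general_ej <- function(model, lam) {
  # E(T) = int_0^inf S(t) dt with survival S(t) = exp(-lam * g(t))
  # (integrating the survival function avoids the t * q(t) peak chasing)
  surv <- function(t) exp(-lam * time_scale(model, t))
  upper <- general_inverse_ts(model, 40 / lam)  # S(upper) = e^-40
  q <- stats::integrate(function(t) surv(t), 0, upper,
                        rel.tol = 1e-10, subdivisions = 500L)
  q$value
}

#' Scaled exponential integral
#'
#' Computes \eqn{e^{x} E_1(x)} for \eqn{x > 0} without overflow, where
#' \eqn{E_1(x) = \int_x^\infty e^{-u}/u \, du = -\mathrm{Ei}(-x)}. A power
#' series is used for \eqn{x < 1} and a modified-Lentz continued fraction
#' otherwise; both branches are accurate to close to machine precision over
#' \eqn{x \in [10^{-300}, 10^{300}]}.
#'
#' This is the workhorse behind exponential-growth expected coalescence
#' times: their closed form contains \eqn{e^{\beta} E_1(\beta)} with
#' \eqn{\beta = \binom{j}{2}/\rho}, and \eqn{e^{\beta}} alone overflows
#' already for moderate sample sizes.
#'
#' @param x positive numeric vector.
#' @return \eqn{e^x E_1(x)}, same length as \code{x}.
#' @examples
#' e1_scaled(1)              # exp(1) * E1(1) = 0.5963474
#' e1_scaled(1e8) * 1e8      # ~ 1: asymptotically x * e^x * E1(x) -> 1
#' @export
e1_scaled <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)), all(x > 0))
  out <- numeric(length(x))
  small <- x < 1
  if (any(small)) {
    xs <- x[small]
    # E1(x) = -gamma - log x + sum_{k>=1} (-1)^(k+1) x^k / (k k!)
    s <- numeric(length(xs))
    term <- rep(1, length(xs))
    for (k in 1:40) {
      term <- term * xs / k
      add <- (-1)^(k + 1) * term / k
      s <- s + add
      if (all(abs(add) < 1e-18 * pmax(abs(s), 1e-300))) break
    }
    out[small] <- exp(xs) * (-0.5772156649015328606 - log(xs) + s)
  }
  if (any(!small)) {
    xl <- x[!small]
    # continued fraction e^x E1(x) = 1/(x+1- 1/(x+3- 4/(x+5- 9/(...))))
    tiny <- 1e-300
    b <- xl + 1
    c0 <- 1 / tiny
    d <- 1 / b
    h <- d
    for (k in 1:200) {
      a <- -k * k
      b <- b + 2
      d <- 1 / (a * d + b)
      c0 <- b + a / c0
      del <- c0 * d
      h <- h * del
      if (all(abs(del - 1) < 1e-16)) break
    }
    out[!small] <- h
  }
  out
}
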