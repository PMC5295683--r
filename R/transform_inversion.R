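#' Product transform of a coalescence time
#'
#' Characteristic-function-style transform of the time \eqn{T_k} on the
#' coalescent (\eqn{\tau}) scale: for a sample of size \code{n},
#' \deqn{P(i\omega) = \prod_{j=k}^{n}
#'   \frac{\binom{j}{2}}{i\omega + \binom{j}{2}}.}
#' Evaluated as a sum of log-moduli and phases, so very long products
#' (large \eqn{n-k}) neither underflow nor lose the phase.
#'
#' @param n sample size.
#' @param k target lineage count, \eqn{2 \le k \le n}: \eqn{T_k} is the
#'   time until only \eqn{k - 1} ancestral lineages remain.
#' @param omega real angular-frequency vector.
#' @return complex vector \eqn{P(i\omega)}; \eqn{P(0) = 1} exactly,
#'   \eqn{|P| \le 1}, and \eqn{P(-i\omega) = \overline{P(i\omega)}}.
#' @examples
#' upsilon_product(10, 2, 0)  # 1+0i
#' @export
upsilon_product <- function(n, k, omega) {
  stopifnot(length(n) == 1L, n == as.integer(n),
            length(k) == 1L, k == as.integer(k), 2 <= k, k <= n)
  lam <- lambda_rates(n, k)
  lm <- logmod_phase(omega, lam)
  complex(modulus = exp(lm$logmod), argument = lm$phase)
}

lambda_rates <- function(n, k) {
  j <- k:n
  j * (j - 1) / 2
}

# log|P(i omega)| and arg P(i omega) for a vector of omegas
logmod_phase <- function(omega, lam) {
  lm <- numeric(length(omega))
  ph <- numeric(length(omega))
  # chunk the outer product to bound memory for long products
  step <- max(1L, floor(2e6 / length(lam)))
  idx <- seq_along(omega)
  for (s in split(idx, ceiling(idx / step))) {
    rat <- outer(omega[s], lam, "/")
    lm[s] <- -0.5 * rowSums(log1p(rat^2))
    ph[s] <- -rowSums(atan(rat))
  }
  list(logmod = lm, phase = ph)
}

# smallest Omega with log|P(i Omega)| < log_thr (doubling + bisection)
find_omega_max <- function(lam, log_thr) {
  f <- function(w) logmod_phase(w, lam)$logmod
  hi <- min(lam)
  while (f(hi) > log_thr) hi <- hi * 2
  lo <- hi / 2
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) > log_thr) lo <- mid else hi <- mid
    if ((hi - lo) < 1e-3 * hi) break
  }
  hi
}

# 15-point Kronrod nodes/weights with the embedded 7-point Gauss weights
# (zeros at pure-Kronrod nodes), on [-1, 1]
gk15 <- local({
  xk <- c(-0.991455371120813, -0.949107912342759, -0.864864423359769,
          -0.741531185599394, -0.586087235467691, -0.405845151377397,
          -0.207784955007898, 0, 0.207784955007898, 0.405845151377397,
          0.586087235467691, 0.741531185599394, 0.864864423359769,
          0.949107912342759, 0.991455371120813)
  wk <- c(0.022935322010529, 0.063092092629979, 0.104790010322250,
          0.140653259715525, 0.169004726639267, 0.190350578064785,
          0.204432940075298, 0.209482141084728, 0.204432940075298,
          0.190350578064785, 0.169004726639267, 0.140653259715525,
          0.104790010322250, 0.063092092629979, 0.022935322010529)
  wg <- numeric(15)
  wg[c(2, 4, 6, 8, 10, 12, 14)] <-
    c(0.129484966168870, 0.279705391489277, 0.381830050505119,
      0.417959183673469, 0.381830050505119, 0.279705391489277,
      0.129484966168870)
  list(x = xk, wk = wk, wg = wg)
})

# Shared-frequency-grid adaptive Gauss-Kronrod panels on [0, omega_max].
# Panels are refined where the 15-vs-7-point estimates of the modulus
# envelope integral disagree; panel width never exceeds `max_width`, which
# the callers tie to the fastest oscillation exp(i omega tau_max) so that
# the oscillatory factor is integrated to machine precision on every panel.
# `mod_fn(omega)` returns the envelope |F(omega)|.
gk_panel_nodes <- function(mod_fn, omega_max, max_width, rel_tol = 1e-9) {
  n0 <- max(16L, ceiling(omega_max / max_width))
  edges <- seq(0, omega_max, length.out = n0 + 1L)
  panels <- cbind(edges[-length(edges)], edges[-1])
  total <- NULL
  for (pass in 1:30) {
    mid <- (panels[, 1] + panels[, 2]) / 2
    half <- (panels[, 2] - panels[, 1]) / 2
    om <- as.vector(outer(gk15$x, half) + rep(mid, each = 15L))
    fv <- matrix(mod_fn(om), nrow = 15L)
    ik <- colSums(fv * gk15$wk) * half
    ig <- colSums(fv * gk15$wg) * half
    err <- abs(ik - ig)
    total <- sum(ik)
    bad <- err > rel_tol * max(total, 1e-300) / nrow(panels)
    if (!any(bad) || nrow(panels) > 20000L) break
    keep <- panels[!bad, , drop = FALSE]
    a <- panels[bad, 1]; b <- panels[bad, 2]; m <- (a + b) / 2
    panels <- rbind(keep, cbind(a, m), cbind(m, b))
    panels <- panels[order(panels[, 1]), , drop = FALSE]
  }
  mid <- (panels[, 1] + panels[, 2]) / 2
  half <- (panels[, 2] - panels[, 1]) / 2
  list(omega = as.vector(outer(gk15$x, half) + rep(mid, each = 15L)),
       weight = as.vector(outer(gk15$wk, half)))
}

# default uniform tau grid for T_k from the constant-size (N0 = 1)
# hypoexponential moments, with a generous right margin for skewness
default_tau_grid <- function(n, k, grid_points, lower_sd = 10, upper_sd = 12) {
  mom <- hypoexp_tau_moments(n, k)
  lo <- max(0, mom$mean - lower_sd * mom$sd)
  # right margin: many sd for the near-Gaussian bulk, plus enough of the
  # slowest exponential tail mode exp(-lambda_k tau) that the truncated
  # mass (~ e^-40) cannot bias the low moments
  hi <- mom$mean + max(upper_sd * mom$sd, 40 / (k * (k - 1) / 2))
  seq(lo, hi, length.out = grid_points)
}

hypoexp_tau_moments <- function(n, k) {
  lam <- lambda_rates(n, k)
  list(mean = sum(1 / lam), sd = sqrt(sum(1 / lam^2)),
       skew = 2 * sum(1 / lam^3) / sum(1 / lam^2)^1.5)
}

new_density_grid <- function(times, values, tau, values_c0, n, k, model,
                             method) {
  # the on-grid trapezoid integral limits the check as much as the density
  # evaluation does, so the closed-form partial-fraction path shares the
  # quadrature class
  tol <- switch(method, quadrature = 1e-5, fft = 1e-3,
                partial_fraction = 1e-5, limit = 1e-4)
  if (length(times) >= 50) {
    # by the change of variables pi(t) dt = pi_c0(tau) dtau the two grid
    # integrals are identical in exact arithmetic; the tau grid is uniform,
    # where Simpson weights avoid the trapezoid's boundary-term error
    norm <- if (is_uniform(tau)) sum(integ_weights(tau) * values_c0)
            else trapz_xy(times, values)
    if (abs(norm - 1) > tol)
      warning(sprintf(
        "%s density integrates to %.8f (tolerance %.0e); treat with care",
        method, norm, tol))
  } else {
    norm <- NA_real_  # sparse user grid: no normalization statement possible
  }
  values <- pmax(values, 0)   # clip tiny negative ringing on output
  structure(list(times = times, values = values, tau = tau,
                 values_c0 = values_c0, n = n, k = k, model = model,
                 method = method, norm = norm, norm_tol = tol),
            class = "coal_density")
}

#' @export
print.coal_density <- function(x, ...) {
  cat(sprintf(
    "<coal_density> T_%d, n = %d, method = %s, %d time points on [%.4g, %.4g]\n",
    x$k, x$n, x$method, length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  integral on grid = %.6f\n", x$norm))
  invisible(x)
}

trapz_xy <- function(x, y) {
  nx <- length(x)
  sum((y[-1] + y[-nx]) * diff(x)) / 2
}

#' Marginal density of a coalescence time by quadrature inversion
#'
#' Computes the density \eqn{\pi_{T_k}(t)} of the coalescence time
#' \eqn{T_k} for arbitrary sample size and population-size history by
#' numerically inverting the product transform
#' (\code{\link{upsilon_product}}) on the coalescent time scale:
#' \deqn{\pi_{T_k}(t) = \frac{1}{N(t)} \frac{1}{\pi} \int_0^\Omega
#'   \mathrm{Re}\left[P(i\omega) e^{i\omega g(t)}\right] d\omega,}
#' using the conjugate symmetry of \eqn{P} to fold the integral onto
#' \eqn{\omega \ge 0}. \eqn{\Omega} is chosen so that the neglected tail of
#' \eqn{|P|} is far below the target accuracy, and the frequency axis is
#' covered by adaptive Gauss-Kronrod panels (shared across all time
#' points) whose width also resolves the fastest oscillation
#' \eqn{e^{i\omega \tau_{max}}}. Relative accuracy is of order \eqn{10^{-5}}
#' or better over the bulk of the distribution.
#'
#' @inheritParams upsilon_product
#' @param model a \code{coal_history}.
#' @param times optional vector of evaluation times (generations); when
#'   omitted, a uniform grid on the coalescent scale spanning the mean
#'   \eqn{\pm} many standard deviations of \eqn{T_k} is used (recommended:
#'   the moments can then be read off the grid with near-spectral
#'   accuracy).
#' @param grid_points number of grid points for the automatic grid.
#' @return A \code{coal_density} (times, density values, method metadata).
#' @examples
#' d <- invert_density_quadrature(10, 2, const_pop(1), grid_points = 200)
#' density_moments(d)["mean"]  # ~ 2 * (1 - 1/10) = 1.8
#' @export
invert_density_quadrature <- function(n, k, model, times = NULL,
                                      grid_points = 400) {
  check_model(model)
  stopifnot(length(n) == 1L, n == as.integer(n),
            length(k) == 1L, k == as.integer(k), 2 <= k, k <= n)
  if (is.null(times)) {
    # with <= 4 exponential modes the density's low-order derivatives at
    # tau = 0 do not vanish and the trapezoid boundary term reappears;
    # densify (the density evaluations are cheap there)
    if (n - k + 1 <= 4) grid_points <- max(grid_points, 4001L)
    tau <- default_tau_grid(n, k, grid_points)
    times <- inverse_time_scale(model, tau)
  } else {
    stopifnot(all(times >= 0), !is.unsorted(times, strictly = TRUE))
    tau <- time_scale(model, times)
  }
  if (k == n) {  # single-factor transform: analytic first-coalescence law
    lam <- n * (n - 1) / 2
    vc0 <- lam * exp(-lam * tau)
    return(new_density_grid(times, vc0 / pop_size(model, times), tau, vc0,
                            n, k, model, "quadrature"))
  }
  vc0 <- invert_c0(n, k, tau)
  new_density_grid(times, vc0 / pop_size(model, times), tau, vc0,
                   n, k, model, "quadrature")
}

# density of T_k on the coalescent scale (constant size, N0 = 1) at taus
invert_c0 <- function(n, k, tau) {
  lam <- lambda_rates(n, k)
  s0 <- sqrt(sum(1 / lam^2))
  tau_max <- max(tau, s0)
  # truncation: |P| below thr makes the neglected tail irrelevant against
  # the density peak scale ~ 1/s0
  om1 <- find_omega_max(lam, log(1e-10))
  thr <- min(1e-10, 1e-9 / (om1 * s0))
  om_max <- find_omega_max(lam, log(thr))
  width <- min(2 * pi / tau_max, om_max / 16, min(lam))
  nodes <- gk_panel_nodes(function(w) exp(logmod_phase(w, lam)$logmod),
                          om_max, width)
  lmp <- logmod_phase(nodes$omega, lam)
  wmod <- nodes$weight * exp(lmp$logmod)
  vals <- vapply(tau, function(tt) {
    sum(wmod * cos(lmp$phase + nodes$omega * tt)) / pi
  }, numeric(1))
  vals
}

#' Marginal density of a coalescence time by FFT inversion
#'
#' Fast two-step inversion of the product transform: (i) inverse FFT of
#' \eqn{P(i\omega)} on a uniform grid of the coalescent time scale sized
#' from the first two moments of \eqn{T_k} under constant size plus a
#' skewness margin, yielding the constant-size (\eqn{N_0 = 1}) density;
#' (ii) deterministic change of time scale
#' \eqn{t = g^{-1}(\tau)}, \eqn{\pi(t) = \pi^{C0}(g(t))/N(t)}. Much faster
#' than the quadrature path, with relative moment accuracy of order
#' \eqn{10^{-4}} (constant) to \eqn{10^{-3}} (exponential) at the default
#' grid size. If visible probability mass sits at the end of the grid
#' (aliasing), the grid is enlarged automatically with a warning.
#'
#' @inheritParams invert_density_quadrature
#' @param grid_points number of equidistant coalescent-scale points
#'   (default 1024).
#' @return A \code{coal_density} with method tag \code{"fft"}.
#' @export
invert_density_fft <- function(n, k, model, grid_points = 1024) {
  check_model(model)
  stopifnot(length(n) == 1L, n == as.integer(n),
            length(k) == 1L, k == as.integer(k), 2 <= k, k <= n,
            grid_points >= 64)
  mom <- hypoexp_tau_moments(n, k)
  # same slow-tail-mode margin as the quadrature grid, so the aliasing
  # detector is not tripped by the exp(-lambda_k tau) tail itself
  tau_max <- mom$mean + max(12 * mom$sd, 30 / (k * (k - 1) / 2))
  for (attempt in 1:4) {
    m <- grid_points
    dtau <- tau_max / m
    lfreq <- c(0:(m / 2 - 1), -(m / 2):-1)
    omega <- 2 * pi * lfreq / (m * dtau)
    tau <- (0:(m - 1)) * dtau
    if (k == n) {  # one-factor transform: use the analytic law directly
      lam <- n * (n - 1) / 2
      vc0 <- lam * exp(-lam * tau)
    } else {
      p <- upsilon_product(n, k, omega)
      vc0 <- Re(stats::fft(p, inverse = TRUE)) / (m * dtau)
    }
    if (abs(vc0[m]) <= 1e-6 * max(vc0) || attempt == 4) {
      if (abs(vc0[m]) > 1e-6 * max(vc0))
        warning("FFT grid still shows mass at the boundary after enlarging")
      times <- inverse_time_scale(model, tau)
      return(new_density_grid(times, vc0 / pop_size(model, times), tau, vc0,
                              n, k, model, "fft"))
    }
    tau_max <- tau_max * 2
    grid_points <- grid_points * 2L
  }
}

#' Moments of a tabulated coalescence-time density
#'
#' Mean, standard deviation and skewness
#' \eqn{\gamma = E[((T - ET)/\mathrm{Std}\,T)^3]} by numerical integration
#' against a \code{coal_density}. Grids produced with a uniform coalescent
#' scale are integrated on that scale (trapezoid on a uniform grid of a
#' smooth decaying integrand, i.e. near-spectral accuracy); externally
#' supplied time grids fall back to trapezoid in \eqn{t}.
#'
#' @param grid a \code{coal_density} whose on-grid integral is within its
#'   method tolerance of 1 (this is checked).
#' @return named numeric vector \code{c(mean, sd, skewness)}.
#' @export
density_moments <- function(grid) {
  stopifnot(inherits(grid, "coal_density"))
  if (is.na(grid$norm))
    stop("grid too sparse for moment integration (supply >= 50 time points)")
  if (abs(grid$norm - 1) > grid$norm_tol)
    stop(sprintf("density grid integrates to %.6f, outside tolerance %.0e",
                 grid$norm, grid$norm_tol))
  if (!is.null(grid$tau) && is_uniform(grid$tau)) {
    x <- grid$tau
    y <- grid$values_c0
    tt <- grid$times
  } else {
    x <- grid$times
    y <- grid$values
    tt <- grid$times
  }
  w <- integ_weights(x)
  z <- sum(w * y)
  m1 <- sum(w * y * tt) / z
  m2 <- sum(w * y * (tt - m1)^2) / z
  m3 <- sum(w * y * (tt - m1)^3) / z
  c(mean = m1, sd = sqrt(m2), skewness = m3 / m2^1.5)
}

trapz_weights <- function(x) {
  nx <- length(x)
  w <- numeric(nx)
  d <- diff(x)
  w[1] <- d[1] / 2
  w[nx] <- d[nx - 1] / 2
  if (nx > 2) w[2:(nx - 1)] <- (d[-1] + d[-(nx - 1)]) / 2
  w
}

is_uniform <- function(x) {
  length(x) > 2 && diff(range(diff(x))) < 1e-8 * abs(mean(diff(x)))
}

# quadrature weights for a tabulated density on its grid. Trapezoid: by
# Euler-Maclaurin its error is driven by the boundary derivatives, and the
# coalescence-time densities handled here vanish to high order at both
# grid ends (tau = 0 like tau^(n-k), and exponentially small on the
# right), so on a uniform grid the rule is accurate far beyond its generic
# O(h^2). The automatic grids are densified where few exponential modes
# remain (k close to n) and the left-boundary derivatives do not vanish.
integ_weights <- function(x) trapz_weights(x)

#' Skewness along the coalescence tree
#'
#' Skewness coefficient \eqn{\gamma(T_k)} for a set of \eqn{k} values,
#' each obtained by transform inversion plus numerical moments. Under
#' growth (\eqn{\rho} large) the distributions of mid-tree times approach
#' normality (skewness near 0), while \eqn{\gamma} rises sharply for
#' \eqn{k} in the last quarter of its range.
#'
#' @inheritParams invert_density_quadrature
#' @param k_values integer vector of target lineage counts.
#' @param method \code{"fft"} (default, fast) or \code{"quadrature"}.
#' @param grid_points grid size passed to the inversion.
#' @return named numeric vector of skewness values.
#' @export
skewness_profile <- function(n, model, k_values, method = c("fft", "quadrature"),
                             grid_points = 2048) {
  method <- match.arg(method)
  out <- vapply(k_values, function(k) {
    g <- if (method == "fft") invert_density_fft(n, k, model, grid_points)
         else invert_density_quadrature(n, k, model, grid_points = grid_points)
    density_moments(g)[["skewness"]]
  }, numeric(1))
  names(out) <- paste0("k", k_values)
  out
}

#' Limit density of the time to the most recent common ancestor
#'
#' As the sample size grows, the distribution of TMRCA converges to a
#' proper limit whose transform is the infinite product
#' \eqn{\prod_{j \ge 2} \binom{j}{2}/(i\omega + \binom{j}{2})}, which has
#' the closed form \eqn{2\pi i\omega / \cos(\pi\sqrt{1/4 - 2i\omega})}
#' (a gamma-quotient identity). The limit density under any size history is
#' obtained by quadrature inversion of that kernel (principal branches of
#' the complex square root and cosine; the removable \eqn{\omega = 0}
#' singularity has value 1). An FFT path is deliberately not offered for
#' the limit kernel: its accuracy is hard to control.
#'
#' @inheritParams invert_density_quadrature
#' @return A \code{coal_density} with \code{k = Inf} conceptually
#'   (stored as \code{NA}) and method tag \code{"limit"}.
#' @examples
#' lim <- tmrca_limit_density(const_pop(1), grid_points = 200)
#' density_moments(lim)["mean"]  # ~ 2 (the limit of 2 * (1 - 1/n))
#' @export
tmrca_limit_density <- function(model, times = NULL, grid_points = 400) {
  check_model(model)
  # limit moments on the coalescent scale: mean 2, var = sum 4/(j(j-1))^2
  j <- 2:20000
  v0 <- sum(4 / (j * (j - 1))^2)
  s0 <- sqrt(v0)
  if (is.null(times)) {
    # slowest tail mode of the limit law is e^-tau (the j = 2 factor)
    tau <- seq(0, 2 + max(12 * s0, 40), length.out = grid_points)
    times <- inverse_time_scale(model, tau)
  } else {
    stopifnot(all(times >= 0), !is.unsorted(times, strictly = TRUE))
    tau <- time_scale(model, times)
  }
  kern <- function(w) {
    out <- 2 * pi * 1i * w /
      cos(pi * sqrt(complex(real = 0.25, imaginary = -2 * w)))
    out[w == 0] <- 1 + 0i
    out
  }
  # truncation where |kernel| is negligible (decays like w * exp(-pi sqrt(w)))
  om_max <- 2
  while (Mod(kern(om_max)) > 1e-12) om_max <- om_max * 2
  tau_max <- max(tau, 1)
  width <- min(2 * pi / tau_max, om_max / 16, 1)
  nodes <- gk_panel_nodes(function(w) Mod(kern(w)), om_max, width)
  kv <- kern(nodes$omega)
  wmod <- nodes$weight * Mod(kv)
  phase <- Arg(kv)
  vc0 <- vapply(tau, function(tt) {
    sum(wmod * cos(phase + nodes$omega * tt)) / pi
  }, numeric(1))
  new_density_grid(times, vc0 / pop_size(model, times), tau, vc0,
                   NA_integer_, NA_integer_, model, "limit")
}

#' Marginal density by explicit partial fractions (small samples)
#'
#' Classical representation
#' \eqn{\pi_{T_k}(t) = \sum_{j=k}^{n} A_{jkn} q_j(t)} with
#' \code{\link{partial_fraction_coef}} weights; exact up to floating-point
#' cancellation, which is why it is guarded to \eqn{n \le 50}. Retained as
#' the independent oracle for the inversion paths.
#'
#' @inheritParams invert_density_quadrature
#' @param times evaluation times (generations), strictly increasing.
#' @return A \code{coal_density} with method tag \code{"partial_fraction"}.
#' @export
marginal_density_partial_fraction <- function(n, k, model, times) {
  check_model(model)
  stopifnot(all(times >= 0), !is.unsorted(times, strictly = TRUE))
  if (n > 50)
    stop("partial-fraction densities are guarded to n <= 50; ",
         "use invert_density_quadrature or invert_density_fft")
  a <- partial_fraction_coef(n, k)
  lam <- lambda_rates(n, k)
  tau <- time_scale(model, times)
  vc0 <- as.vector((a * lam) %*% exp(-outer(lam, tau)))
  new_density_grid(times, vc0 / pop_size(model, times), tau, vc0,
                   n, k, model, "partial_fraction")
}
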