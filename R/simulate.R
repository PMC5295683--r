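#' Simulate a coalescent genealogy's times
#'
#' Draws one realization of the coalescence times \eqn{T_n < T_{n-1} <
#' \dots < T_2} under an arbitrary size history by the time-scale-change
#' construction: independent exponentials with rates \eqn{\binom{k}{2}}
#' on the coalescent scale, cumulated and mapped through
#' \code{\link{inverse_time_scale}} — exactly the joint law of the
#' variable-size coalescent.
#'
#' @param n sample size, \eqn{\ge 2}.
#' @param model a \code{coal_history}.
#' @param seed optional integer seed (recorded on the output).
#' @return An object of class \code{coal_genealogy}: list with \code{n},
#'   \code{model}, \code{t_k} (named, \eqn{k = n..2}, increasing toward
#'   the past), \code{s_k} (epoch durations), \code{tmrca}, \code{tlbt},
#'   \code{seed}.
#' @examples
#' g <- simulate_times(10, const_pop(1000), seed = 1)
#' g$tmrca == g$t_k[["k2"]]
#' @export
simulate_times <- function(n, model, seed = NULL) {
  check_model(model)
  stopifnot(length(n) == 1L, n == as.integer(n), n >= 2)
  if (!is.null(seed)) set.seed(seed)
  k <- n:2
  lam <- k * (k - 1) / 2
  s_tau <- stats::rexp(n - 1, rate = 1) / lam
  t_k <- inverse_time_scale(model, cumsum(s_tau))
  s_k <- diff(c(0, t_k))
  names(t_k) <- names(s_k) <- paste0("k", k)
  structure(list(n = n, model = model, t_k = t_k, s_k = s_k,
                 tmrca = t_k[[length(t_k)]],
                 tlbt = sum(k * s_k), seed = seed),
            class = "coal_genealogy")
}

#' @export
print.coal_genealogy <- function(x, ...) {
  cat(sprintf("<coal_genealogy> n = %d: TMRCA = %g, TLBT = %g\n",
              x$n, x$tmrca, x$tlbt))
  invisible(x)
}

#' Simulate many genealogies' coalescence times at once
#'
#' Vectorized companion of \code{\link{simulate_times}} for Monte-Carlo
#' validation: returns the matrix of realized times \eqn{t_k}.
#'
#' @inheritParams simulate_times
#' @param reps number of independent genealogies.
#' @return numeric matrix with \eqn{n - 1} rows (named \code{k<n>} down to
#'   \code{k2}) and \code{reps} columns.
#' @export
simulate_times_matrix <- function(n, model, reps) {
  check_model(model)
  stopifnot(n >= 2, reps >= 1)
  k <- n:2
  lam <- k * (k - 1) / 2
  s_tau <- matrix(stats::rexp((n - 1) * reps, rate = 1) / lam,
                  nrow = n - 1)
  taus <- apply(s_tau, 2, cumsum)
  if (n == 2) taus <- matrix(taus, nrow = 1)
  tm <- matrix(inverse_time_scale(model, as.vector(taus)), nrow = n - 1)
  rownames(tm) <- paste0("k", k)
  tm
}

#' Simulate a site-frequency spectrum
#'
#' Infinite-sites simulation: \code{n_sites} independent genealogies are
#' drawn under \code{model} and the \code{n_sites} segregating sites are
#' scattered over them with probability proportional to each genealogy's
#' total branch length — the exact conditional distribution of Poisson
#' mutation given the total number of sites, so class frequencies converge
#' to the theoretical \eqn{p_{nb} = f_{nb}/\sum f_{nb}}. Each site then
#' lands uniformly on its genealogy's branches and its allele class is the
#' number of leaves the mutated branch subtends. Constant and exponential
#' histories run in compiled code; general histories use an R fallback.
#'
#' @inheritParams simulate_times
#' @param n_sites number of segregating sites to place, \eqn{\ge 1}.
#' @param folded return minor-allele (folded) classes?
#' @return a \code{coal_sfs}.
#' @examples
#' simulate_sfs(20, exp_pop(1e4, rho = 100), 500, seed = 7)
#' @export
simulate_sfs <- function(n, model, n_sites, folded = FALSE, seed = NULL) {
  check_model(model)
  stopifnot(length(n) == 1L, n == as.integer(n), n >= 2, n_sites >= 1)
  if (!is.null(seed)) set.seed(seed)
  counts <- switch(model$kind,
    constant = cpp_sim_sfs(n, n_sites, 0L, model$N0, 0),
    exponential = cpp_sim_sfs(n, n_sites, 1L, model$N0, model$r),
    general = r_sim_sfs(n, n_sites, model))
  if (folded) {
    half <- floor(n / 2)
    fc <- integer(half)
    for (b in seq_len(half))
      fc[b] <- if (2 * b == n) counts[b] else counts[b] + counts[n - b]
    keep <- fc > 0
    as_sfs(n, which(keep), fc[keep], folded = TRUE)
  } else {
    keep <- counts > 0
    as_sfs(n, which(keep), counts[keep], folded = FALSE)
  }
}

# pure-R fallback for general N(t); same construction as the compiled
# path: sites scattered over n_sites independent genealogies with
# probability proportional to total branch length
r_sim_sfs <- function(n, n_sites, model) {
  counts <- integer(n - 1)
  k <- n:2
  lam <- k * (k - 1) / 2
  G <- n_sites
  epochs <- vector("list", G)
  L <- numeric(G)
  for (g in seq_len(G)) {
    taus <- cumsum(stats::rexp(n - 1, rate = 1) / lam)
    t_k <- inverse_time_scale(model, taus)
    s_k <- diff(c(0, t_k))
    epochs[[g]] <- s_k
    L[g] <- sum(k * s_k)
  }
  m_g <- as.vector(stats::rmultinom(1, n_sites, prob = L))
  for (g in which(m_g > 0)) {
    s_k <- epochs[[g]]
    w <- k * s_k
    # one fixed merge sequence per genealogy, shared by its sites
    merge_a <- integer(n - 2L)
    merge_b <- integer(n - 2L)
    for (m in n:3) {
      pair <- sample.int(m, 2L)
      merge_a[n - m + 1L] <- min(pair)
      merge_b[n - m + 1L] <- max(pair)
    }
    for (site in seq_len(m_g[g])) {
      jstar <- k[sample.int(n - 1, 1L, prob = w)]
      sizes <- rep(1L, n)
      m <- n
      while (m > jstar) {
        i1 <- merge_a[n - m + 1L]; i2 <- merge_b[n - m + 1L]
        sizes[i1] <- sizes[i1] + sizes[i2]
        sizes[i2] <- sizes[m]     # last active slot fills the vacancy
        m <- m - 1L
      }
      b <- sizes[sample.int(jstar, 1L)]
      counts[b] <- counts[b] + 1L
    }
  }
  counts
}
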