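#' Site-frequency spectra
#'
#' A site-frequency spectrum (SFS) records, for each allele count
#' \eqn{b}, the number of diallelic segregating sites at which \eqn{b} of
#' the \eqn{n} sampled sequences carry the mutant (unfolded) or minor /
#' "rare" (folded) allele. \code{as_sfs} builds one from vectors;
#' \code{read_sfs}/\code{write_sfs} handle the package's TSV format
#' (\code{#}-prefixed metadata lines carrying \code{n} and the folded
#' flag, then \code{b<TAB>count} rows).
#'
#' @param n sample size (number of sequences).
#' @param b integer allele counts, \eqn{1 \le b \le n-1} (folded:
#'   \eqn{b \le n/2}).
#' @param count non-negative integer site counts, same length as \code{b}.
#' @param folded logical: are counts minor-allele ("rare") counts?
#' @return An object of class \code{coal_sfs}: list with \code{n},
#'   \code{b}, \code{count}, \code{folded}, \code{total_sites}.
#' @examples
#' as_sfs(n = 4, b = c(1, 2, 3), count = c(6, 3, 2))
#' @export
as_sfs <- function(n, b, count, folded = FALSE) {
  stopifnot(length(n) == 1L, n == as.integer(n), n >= 2,
            length(b) == length(count))
  if (any(b != as.integer(b)) || any(count != as.integer(count)))
    stop("`b` and `count` must be integers")
  if (any(count < 0)) stop("site counts must be non-negative")
  if (any(b < 1 | b > n - 1))
    stop("allele counts must satisfy 1 <= b <= n - 1")
  if (folded && any(b > n / 2))
    stop("folded spectra cannot contain classes with b > n/2")
  ord <- order(b)
  if (anyDuplicated(b)) stop("duplicated allele-count classes")
  structure(list(n = as.integer(n), b = as.integer(b[ord]),
                 count = as.integer(count[ord]), folded = isTRUE(folded),
                 total_sites = sum(count)),
            class = "coal_sfs")
}

#' @export
print.coal_sfs <- function(x, ...) {
  cat(sprintf("<coal_sfs> n = %d, %s, %d classes, %d segregating sites\n",
              x$n, if (x$folded) "folded" else "unfolded",
              length(x$b), x$total_sites))
  invisible(x)
}

#' @rdname as_sfs
#' @param path file path of a spectrum TSV.
#' @export
read_sfs <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, invert = TRUE, value = TRUE)
  body <- body[nzchar(trimws(body))]
  get_meta <- function(key) {
    m <- regmatches(meta, regexpr(paste0(key, "\\s*=\\s*\\S+"), meta))
    m <- unlist(m)
    if (!length(m)) return(NULL)
    sub(paste0(key, "\\s*=\\s*"), "", m[1])
  }
  nval <- get_meta("n")
  if (is.null(nval))
    stop("format error: no '# n=<int>' metadata line found")
  folded <- isTRUE(as.logical(get_meta("folded")))
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 2L)
  if (length(bad))
    stop(sprintf("format error at data line %d: expected b<TAB>count", bad[1]))
  b <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  ct <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  bad <- which(!is.finite(b) | !is.finite(ct) | b != round(b) | ct != round(ct))
  if (length(bad))
    stop(sprintf("format error at data line %d: non-integer b or count",
                 bad[1]))
  as_sfs(as.integer(nval), as.integer(b), as.integer(ct), folded = folded)
}

#' @rdname as_sfs
#' @param sfs a \code{coal_sfs}.
#' @export
write_sfs <- function(sfs, path) {
  stopifnot(inherits(sfs, "coal_sfs"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# n=%d", sfs$n),
               sprintf("# folded=%s", sfs$folded)), con)
  utils::write.table(data.frame(sfs$b, sfs$count), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The packaged human mtDNA spectrum
#'
#' Folded site-frequency spectrum of the 3213 diallelic segregating sites
#' (typed in all 2704 individuals) of the human mitochondrial genome
#' database, with sites classed by the number of copies of the rare
#' allele.
#'
#' @return a \code{coal_sfs} with \eqn{n = 2704} and 3213 sites.
#' @export
mtdna_spectrum <- function() {
  read_sfs(system.file("extdata", "mtdb_table2.tsv", package = "coaltimes",
                       mustWork = TRUE))
}

# unfolded class probabilities p_nb, b = 1..n-1, as a function of
# (n, rho, backend); the product parameter rho is the only demographic
# quantity they depend on (N0 and mu cancel in the normalization), so a
# reference N0 is fixed internally. Results are memoized: spectrum
# evaluation is the dominant cost of likelihood fitting.
.p_cache <- new.env(parent = emptyenv())

p_unfolded <- function(n, rho, backend = c("exact", "approximate")) {
  backend <- match.arg(backend)
  stopifnot(length(rho) == 1L, is.finite(rho), rho >= 0)
  key <- sprintf("%d|%s|%.12g", n, backend, rho)
  hit <- .p_cache[[key]]
  if (!is.null(hit)) return(hit)
  N0ref <- 1e4
  r <- rho / N0ref
  if (backend == "exact") {
    model <- if (rho == 0) const_pop(N0ref) else exp_pop(N0ref, r = r)
    e <- expected_first_coal_time(model, 2:n)
    f <- cpp_spectrum_from_ej(e)
  } else {
    et <- approx_expected_time(n, 2:n, N0ref, r)
    es <- pmax(et - c(et[-1], 0), 0)
    f <- cpp_spectrum_from_esk(es)
  }
  p <- f / sum(f)
  .p_cache[[key]] <- p
  p
}

fold_p <- function(p) {
  n <- length(p) + 1L
  half <- floor(n / 2)
  out <- numeric(half)
  for (b in seq_len(half))
    out[b] <- if (2 * b == n) p[b] else p[b] + p[n - b]
  out
}

#' Site-class probabilities under exponential growth
#'
#' Probability that a randomly chosen segregating site has allele count
#' \eqn{b}, given sample size \code{n} and growth product parameter
#' \eqn{\rho = rN_0}: \eqn{p_{nb} = f_{nb}/\sum_b f_{nb}}. Depends on the
#' demography through \eqn{\rho} only (mutation intensity and \eqn{N_0}
#' cancel). Folded probabilities add the two complementary unfolded
#' classes, \eqn{p_{nb} + p_{n,n-b}} (\eqn{p_{n,n/2}} alone at
#' \eqn{b = n/2}).
#'
#' @param n sample size.
#' @param b allele count(s); \code{NULL} returns the full vector of valid
#'   classes.
#' @param rho growth product parameter, \eqn{\ge 0} (0 = constant size).
#' @param folded logical.
#' @param backend \code{"exact"} (stable recursion on exact expected
#'   times) or \code{"approximate"} (closed-form large-sample times).
#' @return probability vector, one element per requested class.
#' @export
site_class_probability <- function(n, b = NULL, rho, folded = FALSE,
                                   backend = c("exact", "approximate")) {
  backend <- match.arg(backend)
  p <- p_unfolded(n, rho, backend)
  if (folded) p <- fold_p(p)
  if (is.null(b)) return(p)
  bmax <- if (folded) floor(n / 2) else n - 1L
  if (any(b < 1 | b > bmax))
    stop(sprintf("allele count out of range for a %s spectrum (max %d)",
                 if (folded) "folded" else "unfolded", bmax))
  p[b]
}

#' Log-likelihood of a growth parameter given a site-frequency spectrum
#'
#' Treats each segregating site as an independent SNP, giving the
#' multinomial kernel \eqn{\ell(\rho) = \sum_b c_b \ln p(b \mid n, \rho)}
#' (class-count constants dropped). Folded spectra use folded class
#' probabilities.
#'
#' @param sfs a \code{coal_sfs}.
#' @param rho growth product parameter, \eqn{\ge 0}.
#' @inheritParams site_class_probability
#' @return the log-likelihood (\code{-Inf}, with a warning, if any
#'   observed class has zero probability).
#' @export
sfs_loglik <- function(sfs, rho, backend = c("exact", "approximate")) {
  stopifnot(inherits(sfs, "coal_sfs"))
  backend <- match.arg(backend)
  p <- site_class_probability(sfs$n, sfs$b, rho, folded = sfs$folded,
                              backend = backend)
  if (any(p <= 0 & sfs$count > 0)) {
    warning("observed class with zero probability; log-likelihood is -Inf")
    return(-Inf)
  }
  sum(sfs$count * log(p))
}

#' Maximum-likelihood fit of the exponential-growth product parameter
#'
#' Profiles \code{\link{sfs_loglik}} over a log-spaced grid of
#' \eqn{\rho} values, then refines the grid argmax by golden-section /
#' parabolic search to a tolerance of 0.05 in \eqn{\rho}.
#'
#' @inheritParams sfs_loglik
#' @param rho_min,rho_max search range, \eqn{0 \le \rho_{min} <
#'   \rho_{max}}.
#' @param grid_points number of coarse-grid points (\eqn{\ge 10}).
#' @return An object of class \code{coal_fit}: list with \code{rho_grid},
#'   \code{loglik}, \code{rho_hat}, \code{loglik_hat}, \code{backend}.
#'   A warning is issued when the argmax sits on the grid boundary.
#' @examples
#' \donttest{
#' fit <- fit_exponential_growth(mtdna_spectrum(), 50, 1000)
#' fit$rho_hat
#' }
#' @export
fit_exponential_growth <- function(sfs, rho_min = 50, rho_max = 1000,
                                   grid_points = 40,
                                   backend = c("exact", "approximate")) {
  stopifnot(inherits(sfs, "coal_sfs"), rho_min >= 0, rho_min < rho_max,
            grid_points >= 10)
  backend <- match.arg(backend)
  lo <- max(rho_min, 1e-4 * rho_max)
  grid <- exp(seq(log(lo), log(rho_max), length.out = grid_points))
  if (rho_min < lo) grid <- c(rho_min, grid)
  ll <- vapply(grid, function(r) sfs_loglik(sfs, r, backend), numeric(1))
  i <- which.max(ll)
  if (i == 1L || i == length(grid)) {
    warning("log-likelihood argmax on the grid boundary; ",
            "widen [rho_min, rho_max]")
    rho_hat <- grid[i]
    ll_hat <- ll[i]
  } else {
    opt <- stats::optimize(function(r) sfs_loglik(sfs, r, backend),
                           lower = grid[i - 1L], upper = grid[i + 1L],
                           maximum = TRUE, tol = 0.02)
    rho_hat <- opt$maximum
    ll_hat <- opt$objective
  }
  structure(list(rho_grid = grid, loglik = ll, rho_hat = rho_hat,
                 loglik_hat = ll_hat, backend = backend, n = sfs$n,
                 total_sites = sfs$total_sites),
            class = "coal_fit")
}

#' @export
print.coal_fit <- function(x, ...) {
  cat(sprintf(
    "<coal_fit> backend = %s: rho_hat = %.2f (loglik %.3f), grid [%g, %g]\n",
    x$backend, x$rho_hat, x$loglik_hat, min(x$rho_grid), max(x$rho_grid)))
  invisible(x)
}

#' Parametric-bootstrap confidence interval for the growth parameter
#'
#' Simulates \code{replicates} spectra at the fitted \eqn{\hat\rho} with
#' the observed number of segregating sites (each site on its own
#' genealogy, matching the independent-SNP likelihood), refits each, and
#' returns empirical quantiles of the refitted estimates.
#'
#' @inheritParams fit_exponential_growth
#' @param rho_hat the point estimate around which to bootstrap.
#' @param replicates number of bootstrap spectra, \eqn{\ge 100}.
#' @param seed integer RNG seed.
#' @param level confidence level (default 0.95).
#' @return list with \code{lower}, \code{upper}, \code{estimates} (the
#'   replicate estimates) and \code{failures}. Aborts if more than 5\% of
#'   refits fail.
#' @export
bootstrap_ci <- function(sfs, rho_hat, replicates = 200L, seed = 1L,
                         level = 0.95, rho_min = 50, rho_max = 1000,
                         backend = c("exact", "approximate")) {
  stopifnot(inherits(sfs, "coal_sfs"), replicates >= 100L, rho_hat > 0)
  backend <- match.arg(backend)
  N0ref <- 1e4
  model <- exp_pop(N0ref, rho = rho_hat)
  set.seed(seed)
  est <- rep(NA_real_, replicates)
  for (i in seq_len(replicates)) {
    sim <- simulate_sfs(sfs$n, model, sfs$total_sites, folded = sfs$folded)
    fit <- tryCatch(
      suppressWarnings(
        fit_exponential_growth(sim, rho_min, rho_max, grid_points = 25,
                               backend = backend)),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$loglik_hat)) est[i] <- fit$rho_hat
  }
  failures <- sum(is.na(est))
  if (failures > 0.05 * replicates)
    stop(sprintf("%d of %d bootstrap refits failed", failures, replicates))
  qs <- stats::quantile(est, c((1 - level) / 2, (1 + level) / 2),
                        na.rm = TRUE, names = FALSE)
  list(lower = qs[1], upper = qs[2], estimates = est[!is.na(est)],
       failures = failures)
}
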