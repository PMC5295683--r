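# coaltimes

Coalescence-time distributions and site-frequency spectra for large
samples under time-varying population size.

Classical coalescent formulas for a population of deterministic size
$N(t)$ — partial-fraction densities of the coalescence times $T_k$,
per-interval expectations, expected allele-frequency spectra — break down
numerically once the sample size $n$ exceeds a few dozen, because their
coefficients explode with alternating signs. `coaltimes` implements the
numerically stable alternatives that population geneticists need when
$n$ is in the thousands (biobank panels, mitochondrial databases) or
beyond:

* **Densities of $T_k$ for arbitrary $n$ and $N(t)$** by numerical
  inversion of the product transform
  $P(i\omega) = \prod_{j=k}^{n} \binom{j}{2}\big/\big(i\omega +
  \binom{j}{2}\big)$ on the coalescent time scale
  $\tau = \int_0^t d\sigma/N(\sigma)$ — a shared-panel adaptive
  Gauss–Kronrod quadrature path (`invert_density_quadrature()`) and a
  fast FFT path (`invert_density_fft()`), with moments and skewness from
  `density_moments()`.
* **The $n \to \infty$ limit law of the tree height** (TMRCA) from the
  closed-form kernel $2\pi i\omega / \cos(\pi\sqrt{1/4 - 2i\omega})$
  (`tmrca_limit_density()`).
* **Stable exact expectations** of tree height, total branch length and
  the expected spectrum $f_{nb}$, valid for $n$ up to the hundreds of
  thousands (`etmrca_stable()`, `etlbt_stable()`,
  `expected_spectrum()`), built on an overflow-safe scaled exponential
  integral (`e1_scaled()`).
* **Closed-form large-sample approximations** with exact-vs-approximate
  error reports (`approx_expected_time()`, `approx_etlbt()`,
  `relative_error_report()`, `roundoff_error_bound()`).
* **Maximum-likelihood fitting of the exponential-growth product
  parameter $\rho = rN_0$** to an observed site-frequency spectrum, with
  exact or approximate expected-spectrum backends and
  parametric-bootstrap confidence intervals (`fit_exponential_growth()`,
  `bootstrap_ci()`); the human mtDNA spectrum of 3213 diallelic
  segregating sites in 2704 individuals ships as a fixture
  (`mtdna_spectrum()`).
* **A matching coalescent simulator** for genealogy times and
  infinite-sites spectra under any size history (`simulate_times()`,
  `simulate_sfs()`).

## Worked example

Expected coalescence times for a sample of $n = 800$ sequences from an
exponentially growing population ($N_0 = 2\times10^6$, $r = 0.001$ per
generation), and the growth parameter of the human mtDNA polymorphism
data:

```r
library(coaltimes)

model <- exp_pop(2e6, r = 0.001)

# density of T_6 (time until 5 ancestral lineages remain), by transform
# inversion, and its moments
d <- invert_density_quadrature(800, 6, model, grid_points = 500)
density_moments(d)
#>         mean           sd     skewness
#> 6.647881e+03 2.505898e+02 4.406953e-02

# closed-form large-sample approximation of the same expectation
approx_expected_time(800, 6, 2e6, 0.001)
#> [1] 6679.599

# fit the exponential-growth product parameter to the mtDNA spectrum
sfs <- mtdna_spectrum()
sfs
#> <coal_sfs> n = 2704, folded, 134 classes, 3213 segregating sites
fit <- fit_exponential_growth(sfs, 50, 1000, backend = "exact")
fit$rho_hat
#> [1] 339.2019
```

The mean of $T_6$ is about 6648 generations with standard deviation 251
and skewness 0.04 — growth makes mid-tree times nearly Gaussian. The
closed-form approximation overshoots the mean by about 0.5%. The fitted
$\hat\rho \approx 339$ says the mtDNA data are best explained by a
product of present-day size and growth rate around 339 — population
growth strong enough to skew the spectrum heavily toward singletons
(1231 of 3213 sites).

The methods vignette (`vignettes/coalescence-computations.Rmd`) documents
the model, every numerical choice and the package's limitations.

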