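# dfemap

Estimate the distribution of fitness effects (DFE) of segregating
single-nucleotide polymorphisms by mapping per-variant deleteriousness
scores (CADD-style C-scores, conservation scores, or any PHRED-like
annotation) to selection coefficients.

**Who it is for.** Population geneticists who have (a) a table of biallelic
SNPs with derived-allele counts in a sample of *n* haploid genomes and a
deleteriousness score per site, and (b) want a quantitative picture of how
much of each functional category (nonsynonymous, UTR, regulatory,
intergenic, ...) is neutral versus weakly or strongly deleterious — without
assuming synonymous sites are neutral and without forcing the whole DFE into
a single parametric family.

## The method

Sites are binned by score; each bin's unfolded site frequency spectrum
(SFS) is fitted by maximum likelihood under a Poisson random field model.
Expected spectra come from the Wright–Fisher forward diffusion with genic
negative selection and an arbitrary population-size history
$\rho(\tau)$:

$$
\partial_\tau f = \tfrac12\, \partial_x^2\!\left[\frac{x(1-x)}{\rho(\tau)} f\right]
                - \partial_x\!\left[S\,x(1-x)\,f\right],
\qquad \lim_{x\to 0} x f = \theta\rho(\tau),
$$

with $\tau$ in units of $2N_0$ generations and $S = 2N_0 s$.  Sampling
$e_{n,i} = \int_0^1 \binom{n}{i} x^i (1-x)^{n-i} f\,dx$ and normalizing
gives shape-only multinomial likelihoods; an EM algorithm jointly
re-estimates the ancestral-state misidentification rate $\varepsilon$
(flips $i \to n-i$) with either the demographic model (on the lowest,
presumed-neutral score bin) or the per-bin selection model (a point mass on
a log-spaced grid of $s$, or a gamma DFE over $|s|$, with likelihood-ratio
and chi-squared diagnostics).  Non-neutral per-bin coefficients are
smoothed by a cubic spline (20 df) on $\log_{10}(-\hat s)$ into a
continuous score-to-$s$ mapping with bootstrap confidence intervals and a
label-randomization control; mapped coefficients are then summarized per
functional category (range proportions, log-mean/SD, kernel densities).

See `vignettes/score-to-selection.Rmd` for the full model, conventions and
numerical choices.

## Worked example

Simulate four score bins with known coefficients under exponential growth
(scaled rate 1 for 13,000 generations, $N_0 = 10^4$, $n = 18$ haploids,
$\varepsilon = 0.02$), then refit them:

```r
library(dfemap)
library(tibble)

model <- demog_exponential(r = 1, t_gen = 13000)
ctl   <- solver_control(grid_points = 401, dt = 2e-3)
cache <- precompute_spectra(model, n = 18, s_grid_default(step = 0.05),
                            control = ctl)

bins <- tibble(bin = c(0, 10, 20, 30),
               s_true = c(0, -1e-5, -1e-4, -1e-3), n_sites = 2e4)
bins$s_true <- vapply(bins$s_true,
                      function(s) cache$s[which.min(abs(cache$s - s))],
                      numeric(1))
sites <- simulate_scored_sites(simulation_spec(bins, cache, epsilon = 0.02),
                               seed = 1)
fits <- fit_score_bins(bin_sites_by_score(sites), cache)
fits
#> # A tibble: 4 × 10
#>     bin n_sites       s_hat epsilon loglik_point neutral low_data chisq_stat
#>   <dbl>   <int>       <dbl>   <dbl>        <dbl> <lgl>   <lgl>         <dbl>
#> 1     0   20081  0           0.0219      -45790. TRUE    FALSE          9.59
#> 2    10   20094 -0.00000891  0.0210      -44773. FALSE   FALSE         14.9
#> 3    20   20027 -0.0001      0.0211      -33382. FALSE   FALSE         13.4
#> 4    30   20111 -0.001       0.0188       -9140. FALSE   FALSE         2.35
```

Reading the output: bin 0 (simulated neutral) is called neutral
(`s_hat = 0`); the selected bins recover their generating coefficients
($-10^{-5}$, $-10^{-4}$, $-10^{-3}$) on the fitting grid; the per-bin EM
estimates of the misidentification rate cluster around the simulated 0.02;
and no bin's chi-squared diagnostic rejects the fit.  With 41 bins one
would continue `build_mapping(fits, df = 20)`,
`bootstrap_mapping(...)`, `map_sites_to_s(sites, mapping)` and
`category_summary(...)`; `autoplot()` methods draw the mapping and DFE
densities.

A thin command-line interface over the same functions ships in
`inst/cli/dfemap.R` (subcommands `simulate`, `fit-demography`, `fit-bins`,
`build-mapping`, `map-sites`, `report`, `bias-check`).

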