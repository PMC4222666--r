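---
title: "From deleteriousness scores to selection coefficients: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From deleteriousness scores to selection coefficients: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfemap)
library(tibble)
```

dfemap estimates how strongly negative selection acts on segregating
single-nucleotide polymorphisms, stratified by a per-variant deleteriousness
score (a CADD-style C-score, a conservation score, or any PHRED-like
annotation).  The idea: sites with similar scores should experience similar
selection pressure, so the site frequency spectrum (SFS) of each score bin
carries information about the typical selection coefficient of that bin.
Fitting a coefficient to every bin and smoothing across bins yields a
continuous score-to-$s$ map, which in turn converts a genome's worth of
scored polymorphisms into an approximate distribution of fitness effects
(DFE) for any functional category.

This vignette documents the model, the conventions, the numerical choices,
and the limits of what the validation suite shows.

## The population-genetic model

We model derived-allele frequencies under the Wright–Fisher diffusion with
genic (additive) negative selection, mutation influx, and a deterministic
population-size history.  Let $f(x, \tau)$ be the expected density of
segregating sites per unit frequency at derived frequency $x \in (0, 1)$ and
diffusion time $\tau$.  With time measured in units of $2 N_0$ generations
($N_0$ the diploid reference size at the most ancient modeled time, default
10,000) the forward equation is

$$
\frac{\partial f}{\partial \tau}
  = \frac{1}{2} \frac{\partial^2}{\partial x^2}
      \left[ \frac{x (1 - x)}{\rho(\tau)} f \right]
  - \frac{\partial}{\partial x} \left[ S\, x (1 - x)\, f \right],
$$

where $\rho(\tau)$ is the population size relative to $N_0$ (with
$\rho(0) = 1$ by convention; $\tau$ runs forward from the most ancient time
to the present) and $S = 2 N_0 s$ is the population-scaled selection
coefficient of the per-generation coefficient $s \le 0$.  Mutations enter at
low frequency in proportion to the current population size, which we impose
as the boundary behavior $\lim_{x \to 0} x f(x, \tau) = \theta \rho(\tau)$,
with $\theta$ the population-scaled mutation rate; fixation at $x = 1$ is
absorbing.  The constant in the influx condition is calibrated so that the
constant-size neutral model reproduces the classical stationary spectrum
$f(x) = \theta / x$, and this calibration is pinned by tests.

The expected sample spectrum for $n$ haploid genomes follows by binomial
sampling,

$$
e_{n,i} = \int_0^1 \binom{n}{i} x^i (1 - x)^{n-i} f(x)\, dx,
\qquad i = 1, \dots, n - 1,
$$

and because only the *shape* of the SFS is fitted, the working quantity is
$p_i = e_{n,i} / \sum_j e_{n,j}$, with $\theta$ profiled out.  Under the
Poisson random field assumption the observed class counts are independent
Poisson variables around $e_{n,i}$, so the shape-only likelihood of counts
$c_i$ is multinomial: $\ell = \sum_i c_i \log \tilde p_i$.

Per-bin DFEs come in two families: a point mass at $s_0 \le 0$, and a gamma
distribution over $|s|$ with shape $\alpha$ and rate $\beta$ (mean
$\alpha/\beta$, and mean/SD $= \sqrt{\alpha}$, a convenient shape summary).
Gamma-mixed spectra are trapezoid-rule mixtures of per-coefficient spectra
over the selection grid.

Assumptions worth keeping in mind: no dominance, no epistasis, no positive
selection (scores cannot distinguish adaptive from deleterious disruption,
and polymorphism data carry little signal of strong positive selection), and
free recombination (sites independent).

## Numerical solution of the diffusion

The substitution $g = x (1 - x) f$ converts the equation into a plain
advection–diffusion problem,
$\partial_\tau g = x(1-x) \left[ g'' / (2\rho) - S g' \right]$, with simple
Dirichlet boundaries $g(0, \tau) = \theta \rho(\tau)$ and $g(1, \tau) = 0$.
For a constant-size epoch the stationary solution is closed-form,
$g(x) = \theta\rho\, (e^{2 S \rho x} - e^{2 S \rho}) / (1 - e^{2 S \rho})$,
reducing to $\theta \rho (1 - x)$ at neutrality.  This closed form serves
two roles: it initializes histories that begin in equilibrium (no burn-in),
and — integrated against the binomial kernel by adaptive quadrature
(`equilibrium_sample_spectrum()`, relative tolerance `1e-10`) — it is the
independent oracle against which the finite-difference solver is validated.

Numerical choices:

* **Grid.** Cosine-clustered nodes $x_j = (1 - \cos \pi u_j)/2$ including
  both boundaries (default 2,001 points), refining resolution near $x = 0$
  and $x = 1$ where the spectrum is steep.  Sampling integrals use the
  trapezoid rule on the same grid in the $g$ variable, whose integrand is
  finite at both endpoints.
* **Time stepping.** Crank–Nicolson with a target step of $10^{-3}$
  diffusion time units (each epoch subdivided evenly), preceded by four
  fully implicit start-up steps that damp oscillations from rough initial
  data.  The tridiagonal solves run in compiled code.
* **Stability and positivity.** Negative densities beyond `neg_tol`
  (default $10^{-6}$ relative to the maximum) raise a solver-instability
  error; smaller undershoots are clamped to zero.  When an equilibrium
  answer is requested, an optional stationarity check evolves a further 0.5
  time units and errors if the solution still moves by more than $10^{-4}$.
* **Scaled selection.** The stable evaluation of the stationary form
  branches on the sign of $S$ (direct for $S < 0$, `expm1`-based otherwise)
  and guards $|S| > 10^4$.  Positive $S$ is rejected at the API.
* **Accuracy at defaults.** At 1,001 grid points the solved neutral
  constant-model sample spectrum matches $p_i \propto 1/i$ to a few
  $10^{-6}$ absolute, and selected spectra match the quadrature oracle
  within 0.2% relative for $S$ down to $-10$; the test suite uses 401-point
  grids, whose accuracy is itself verified against the oracle.

## Ancestral misidentification EM

Polarizing alleles by an inferred ancestral state occasionally flips a
site's class from $i$ to $n - i$, inflating high-frequency classes.  With
flip rate $\varepsilon$ the observed-class probabilities are
$\tilde p_i = (1 - \varepsilon) p_i + \varepsilon p_{n-i}$.  The EM
algorithm alternates:

* **E step:** posterior flip probability
  $q_i = \varepsilon p_{n-i} / \tilde p_i$;
* **$\varepsilon$ M step:** $\varepsilon' = \sum_i c_i q_i / \sum_i c_i$;
* **model M step:** re-maximize $\ell$ over the model family (demography
  candidates, the selection grid, or gamma parameters) at the current
  $\varepsilon$.

Both halves increase the observed-data log-likelihood, so the trace is
non-decreasing; the implementation errors if it ever drops beyond round-off
slack.  Defaults: $\varepsilon_0 = 0.02$, relative tolerance $10^{-8}$,
at most 1,000 iterations.  A symmetric spectrum makes $\varepsilon$
unidentifiable ($\tilde p = p$ for all $\varepsilon$); realistic spectra are
strongly asymmetric, and at $10^5$–$10^6$ sites the rate is recovered within
$\pm 0.01$ across $\varepsilon \in [0, 0.1]$.

## Fitting demography and selection

**Demography.** The presumed-neutral bin (lowest score) is fitted by a grid
search over candidate histories — the constant model plus exponential growth
over scaled rates $r \in \{0.25, 0.5, 1, 2, 4\}$ and durations 1,000–20,000
generations (configurable), with published-style piecewise histories read
from YAML configs — as the model M step of the EM.  Candidate spectra are
computed once at $S = 0$ and reused.

**Per-bin selection.** The selection grid is $s = 0$ plus $\log_{10}|s|$
from $-6$ to $-2$ in steps of 0.005 (801 points, configurable); spectra are
precomputed once per (demography, $n$) into a cache and reused across bins,
EM iterations, bootstrap replicates and label randomizations — this caching
is the package's central performance device.  Grid ties break toward the
weaker coefficient so identical inputs give identical fits.

**The neutral call.**  At exactly neutral truth the bare grid argmax falls
on the weakest negative coefficient about half the time (the usual boundary
behavior of a likelihood ratio), which would make "bins that best fit the
neutral model" a coin flip.  We therefore call a bin selected only when its
best negative coefficient improves the EM-converged log-likelihood over the
neutral fit by more than $\chi^2_{1,0.95}/2 \approx 1.92$ units — a 5%
likelihood-ratio threshold for the one extra parameter.  `neutral_margin = 0`
restores the bare argmax.

**Gamma fits, LRT and goodness of fit.**  Gamma parameters are maximized
over $(\log \alpha, \log \beta)$ with `L-BFGS-B` inside the EM's model M
step, warm-started between iterations; proposals whose gamma mass is not at
least 99.9% covered by the cached grid are rejected (mass below the smallest
cached $|s|$ is effectively neutral and assigned to the $s = 0$ spectrum).
The gamma-vs-point likelihood-ratio statistic is floored at zero and
referred to $\chi^2_1$ — a conservative convention given the boundary
non-regularity — with Bonferroni correction across bins.  The Pearson
chi-squared diagnostic pools classes from the high-frequency end until every
expected count reaches 5 and uses `df = classes - n_params - 1`; whether
$\varepsilon$ is charged as a parameter is the caller's choice (the bin
pipeline charges 2: the coefficient and $\varepsilon$).

## Building the score-to-s mapping

Scores are binned to the nearest integer (ties rounded half away from zero)
up to a cutoff of 40 for natively PHRED-scaled scores, or to 0.25-unit bins
up to 5 for rank-rescaled scores.  The rank rescaling converts any score to
$-\log_{10}$ of the within-dataset probability of an as-or-more-extreme
value (self-inclusive), making different annotations comparable; it is
invariant to strictly increasing transforms of the input.

After removing neutral-called bins, a cubic smoothing spline with 20
effective degrees of freedom (reduced with a warning when fewer than 21
non-neutral bins remain) is fitted to $\log_{10}(-\hat s)$ against the bin
center.  The log scale keeps the spline well-behaved across three orders of
magnitude of $|s|$; mapping the neutral mass through the log would be
ill-defined, which is why neutral bins form an explicit zero set instead.
Evaluation clamps scores outside the fitted domain to its edges and returns
$s = 0$ for scores falling in neutral bins.

Per-bin uncertainty comes from resampling sites within each bin with
replacement (default 100 replicates) and refitting against the cached
spectra; intervals are percentile-based.  As a negative control, score
labels can be permuted across sites — preserving both the score histogram
and the pooled SFS — and the mapping refitted; a real signal disappears
(the regression of fitted $s$ on bin center flattens), while artifacts of
bin occupancy would survive.

## DFE summaries

Mapped coefficients are summarized per functional category by the
proportion of sites in a partition of the $s$-axis — the neutral mass
$\{s = 0\}$ plus magnitude ranges with default cut points $10^{-4}$ and
$10^{-3}$, fully configurable — together with $\log_{10}$ of the mean and
SD of $|s|$ over the selected ($s < 0$) sites only; with large neutral
fractions, including zeros would make the log statistics meaningless.
Densities use a Gaussian kernel with the bandwidth given directly as the
kernel SD on the $s$ scale (default $5 \times 10^{-6}$; $2.5 \times 10^{-6}$
and $10^{-6}$ resolve finer structure), evaluated on a grid extended six
bandwidths beyond the data so the density integrates to 1 within $10^{-3}$.

The reference/alternative bias diagnostic compares mean scores at sites
where the reference allele is ancestral versus derived, standardized by the
pooled SD, per derived-count class — a check that a score does not encode
the reference allele itself.

## The synthetic-data generator

`simulate_observed_sfs()` and `simulate_scored_sites()` draw independent
Poisson class counts around the model's expected spectrum after the
misidentification mixture, then emit per-site records with scores jittered
uniformly within their bin (so binning round-trips exactly) and optional
category labels.  All randomness flows from a single recorded seed.

This emulates exactly the statistical structure the estimator assumes:
independent sites, Poisson class counts, a single coefficient (or gamma DFE)
per bin, and a polarization flip rate constant across bins.  It does *not*
emulate linkage and background selection, sequence-context effects (e.g.
CpG hypermutability), score measurement error correlated with frequency, or
positive selection — so passing the recovery tests demonstrates internal
consistency of the estimator, not robustness to those real-data violations.
The stratum column (e.g. background-selection deciles, exome flags) exists
precisely so users can re-run the whole pipeline within subsets where such
violations are more homogeneous.

Validation problem sizes (the package's own choices, balancing Monte-Carlo
error against runtime): $n = 18$ haploids throughout; $10^6$ sites for
misidentification and demography recovery; $10^5$ sites per bin for
coefficient recovery with 50 bootstrap replicates; 40-bin mapping recovery
at $2 \times 10^4$ sites per bin with 50 label randomizations; 200
replicates for chi-squared calibration; 50 bins for LRT calibration.  Tests
use a 401-point solver grid and a 0.05-step selection grid, both of whose
accuracy is verified against the analytic oracle and grid-refinement checks.

## A worked miniature

```{r mini, eval = FALSE}
model <- demog_exponential(r = 1, t_gen = 13000)
ctl <- solver_control(grid_points = 401, dt = 2e-3)
cache <- precompute_spectra(model, n = 18,
                            s_grid_default(step = 0.05), control = ctl)

bins <- tibble(bin = 0:40,
               s_true = c(0, -10^seq(-5.5, -2.5, length.out = 40)),
               n_sites = 2e4)
bins$s_true <- vapply(bins$s_true,
                      function(s) cache$s[which.min(abs(cache$s - s))],
                      numeric(1))
sites <- simulate_scored_sites(simulation_spec(bins, cache, epsilon = 0.02),
                               seed = 1)
fits <- fit_score_bins(bin_sites_by_score(sites), cache)
mapping <- build_mapping(fits, df = 20)
summary_tab <- sites |>
  map_sites_to_s(mapping) |>
  category_summary()
autoplot(fits, mapping = mapping)
```

## Known limitations

* Selection coefficients come from a discrete grid; uncertainty within a
  grid step (0.005 in $\log_{10}|s|$ at defaults) is not propagated.
* Free recombination understates bootstrap interval widths on real data,
  where linked sites covary.
* The neutral anchor is the lowest-score bin; if that bin is not actually
  neutral, the demographic fit absorbs the difference and the whole mapping
  shifts.
* The method reads the DFE of *segregating* variants; the DFE of new
  mutations would require additionally modeling the sites already removed
  by selection.
* Only negative selection and neutrality are modeled; bins dominated by
  positive selection would be mis-read as weakly deleterious (their SFS
  signatures are similar to misidentification, which the EM partially
  absorbs).
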