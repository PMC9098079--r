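---
title: "Growth laws with ribosome maintenance and protein turnover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth laws with ribosome maintenance and protein turnover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribomaint)
```

## The problem

The first growth law states that the ribosomal proteome mass fraction
$\phi_R$ rises linearly with the steady-state growth rate $\lambda$ across
nutrient conditions. Empirically the law extrapolates to a nonzero offset
$\phi_R^{min} = \phi_R(\lambda = 0)$, conventionally explained by a pool of
inactive ribosomes: in the standard model only a fraction $f_a$ of ribosomes
translates, and mass balance gives

$$\lambda = \gamma\,\phi_R\,f_a,$$

where $\gamma = k / L_R$ (codon elongation rate over the amino-acid content
of a ribosome) is the inverse of the time a ribosome needs to make one
ribosome's worth of protein. Taken literally, this model says $f_a \to 0$ as
$\lambda \to 0$: no protein synthesis at all in non-growing cells. That
conflicts with the observation of finite elongation rates at vanishing
growth, and with the fact that protein degradation — with time scales of
hours, comparable to slow doubling times — must be balanced by ongoing
synthesis.

This package implements three nested models of the law and the estimators
needed to confront them with data:

1. **Standard (active-ribosome) model**: no turnover,
   $f_a = \lambda/(\gamma\phi_R)$ (`fa_standard()`).
2. **Degradation-only model**: every ribosome bound, proteins degraded at a
   first-order rate $\eta$, so $\lambda = \gamma\phi_R - \eta$ and the offset
   is $\phi_R^{min} = \eta/\gamma$ (`phi_r_degradation()`). This model is
   mathematically equivalent to the standard one under the identification
   $\eta = \gamma\,\phi_{Ri}$; the two differ only in interpretation.
3. **Combined model**: both inactive ribosomes and turnover,
   $\lambda = \gamma\phi_R f_b - \eta$, so the bound/active fraction is
   $f_b = (\lambda+\eta)/(\gamma\phi_R)$ (`fb_combined()`), constrained to
   $\lambda/(\gamma\phi_R) \le f_b \le 1$.

In the combined model, bound ribosomes split into a *growth* share and a
*maintenance* share whose synthesis exactly replaces degraded protein:

$$f_{bg} = \frac{1}{1 + \eta/\lambda}, \qquad
  f_{bm} = \frac{\eta/\lambda}{1 + \eta/\lambda}.$$

The split depends on $\eta/\lambda$ only (curves at different growth rates
collapse when plotted against that ratio), and $f_{bm} \to 1$ as
$\lambda \to 0$ with $\eta > 0$: at vanishing growth *all* active ribosomes
do maintenance. `maintenance_split()` returns the analytic limit at
$\lambda = 0$ rather than evaluating $\eta/\lambda$.

```{r}
maintenance_split(lambda = c(1, 0.15, 1e-9), eta = 0.04)
```

## The constant-ratio ansatz

The combined law has two unknowns per condition ($f_b$ and $\eta$), so an
additional assumption is needed to close it against allocation data. The
*constant-ratio ansatz* is the one-parameter family

$$f_b(\lambda) = f_{b0} + (1 - f_{b0})\,\frac{\lambda}{\gamma\phi_R},$$

where $f_{b0}$ is the bound fraction at null growth. Algebraically this is
equivalent to the ratio of inactive to maintenance ribosomal mass fractions
being constant across conditions, $\phi_{Ri}/\phi_{Rbm} = 1/f_{b0} - 1$,
hence the name. Substituting the ansatz into the growth law yields, per
condition,

$$\frac{\eta}{\gamma\phi_R} = f_{b0}\left(1 -
  \frac{\lambda}{\gamma\phi_R}\right),$$

so the ratio on the left divided by the bracket on the right is a direct
per-condition estimator of $f_{b0}$. `estimate_fb0()` computes it for the
slow-growth subset (default $\lambda \le 0.2\,h^{-1}$, the regime where
degradation and growth rates are comparable) and aggregates by an unweighted
mean; a regression-through-the-origin aggregation is available via
`method = "regression"`. On data generated under the ansatz the estimator
is exact, with zero dispersion — the package's central parameter-recovery
property:

```{r}
gen <- generate_growth_law_dataset(n = 10, fb0 = 0.2, seed = 1)
estimate_fb0(gen$conditions, lambda_max = Inf)[c("fb0", "sd", "n_used")]
```

Setting $f_{b0} = 1$ (no inactive ribosomes) recovers the degradation-only
prediction $\eta(\lambda) = \gamma\phi_R - \lambda$
(`eta_constant_ratio()` with `fb0 = 1`).

Finally, the dimensionless demand variable $\Lambda = (\lambda+\eta)/\gamma$
restores the linearity of the law: $\phi_R = \Lambda/f_b$.
`lambda_linearity_check()` regresses $\phi_R$ on $\Lambda$ and reports
slope, intercept, residuals and a curvature statistic (the $t$-value of a
quadratic term). Two caveats discovered while validating it on generated
data, worth stating precisely: with a *constant* $f_b$ the relation is an
exact line through the origin with slope $1/f_b$; ansatz data with a linear
allocation profile are still exactly linear in $\Lambda$ but miss the origin
(the intercept, not curvature, carries the signal); curvature proper appears
when $f_b$ varies with growth rate in a way not absorbed by the ansatz.

## Microscopic underpinning

`ribosome_density()`, `free_ribosomes()` and `translation_flux()` implement
the initiation-limited kinetics behind the laws: ribosome density on a
transcript $\rho = (\alpha/k)/(1 + (\ell-1)\alpha/k)$ (footprint $\ell
\approx 10$ codons), the free/bound partition $R_f = k(R - R_i)/(k + L c_m
\alpha_0)$, and the biosynthesis flux $J_{tl} = m_{aa} k R$ valid when the
elongation time far exceeds the initiation waiting time ($\tau_e/\tau_i \ge
10$; a warning is emitted below that). Since only the combination $L c_m
\alpha_0 / k$ matters for the partition, the interface also accepts that
dimensionless `binding_ratio` directly. Both the full density expression and
its low-density approximation $\rho \approx \alpha/k$ are exposed; at the
physiological separation of scales (initiation ~0.1/s versus elongation
~10/s) they differ by under 10%.

Two numerical oracles close the loop. `simulate_mass_balance()` integrates
$\dot M = (\gamma f_b \phi_R - \eta) M$ with a fixed-step classical
Runge-Kutta scheme (default step $10^{-3}/(|\text{net rate}|+1)$ h — the
problem is linear and non-stiff; a fixed step keeps trajectories
deterministic for testing) and must reproduce the closed-form growth rate to
within $10^{-6}$ relative. `self_consistent_growth()` root-solves $\lambda =
\gamma(\lambda)\phi_R f_b(\lambda) - \eta(\lambda)$ to a residual below
$10^{-10}$, accepting constants or functions for $\gamma$ and $\eta$.

## Pulse-chase degradation inference

Mean degradation rates come from pulse-chase experiments: the proteome is
labelled during a pulse and the labelled fraction $P_L(t)/P_L(0)$ decays
during the chase. For a heterogeneous proteome the decay is the Laplace
transform of the rate distribution, $\langle e^{-\eta t}\rangle$
(`mean_decay_curve()`, discrete mixtures and lognormal supported).

The classic estimator inverts a single-exponential decay,
$\hat\eta = -\log(P_L(t)/P_L(0))/t$. With several timepoints,
`single_exp_eta()` pools them as the zero-intercept least-squares slope of
$-\log$ fraction on time, a deterministic generalisation of the one-point
formula. By Jensen's inequality $\langle e^{-\eta t}\rangle \ge
e^{-\langle\eta\rangle t}$, so this estimator *underestimates* the true mean
rate for any non-degenerate distribution; `jensen_gap()` quantifies the
bias, which grows with chase time:

```{r}
mix <- decay_mixture(c(0.5, 0.5), c(0, 0.2))
jensen_gap(mix, t = 5)
```

Class fits decompose the proteome into fast, slow and stable classes,
$P_L(t)/P_L(0) = f_{fast}e^{-\eta_{fast}t} + f_{slow}e^{-\eta_{slow}t} +
f_{stable}$, with mean rate $\langle\eta\rangle = f_{fast}\eta_{fast} +
f_{slow}\eta_{slow}$. `fit_two_class()` drops the slow class;
`fit_three_class()` offers three routes:

* `"mixture"` (default) fits the full three-class curve by bounded
  Levenberg–Marquardt least squares. It nests the generating model, so
  noiseless round-trips recover the parameters to $10^{-6}$.
* `"integrated"` linearises the slow class ($e^{-\eta_{slow}t} \approx 1 -
  \eta_{slow}t$), fitting only the product $f_{slow}\eta_{slow}$. The
  linearisation is a genuine approximation: on a curve with
  $\eta_{slow} t \le 0.2$ it biases the mean rate at the $10^{-3}$/h level,
  which is why it is not the default even though it is the more traditional
  parameterisation.
* `"derivative"` fits the negative numerical derivative (central differences
  inside, one-sided at the ends) to $f_{fast}\eta_{fast}e^{-\eta_{fast}t} +
  f_{slow}\eta_{slow}$. Differentiation amplifies noise; the route exists
  for comparison.

Initialisation takes $\eta_{fast}$ from the earliest log-slope and
$f_{fast}$ from the late-time deficit below 1; fractions are box-constrained
to $[0,1]$ and rates to non-negative values, with the label convention
$\eta_{fast} > \eta_{slow}$ enforced after fitting. If every sampled time
satisfies $\eta_{fast}t < 0.2$ or $> 5$ the fit warns that the fast class is
poorly constrained. Standard errors come from the nonlinear fit; no attempt
is made to model source-specific systematics beyond that.

```{r}
pc <- generate_pulse_chase(times = seq(0, 10, by = 0.25),
                           fractions = c(0.07, 0.23, 0.70),
                           rates = c(1.2, 0.02, 0), noise_sd = 0, seed = 1)
tidy(fit_three_class(pc$curve))
```

## Interpolation and regression choices

Degradation rates and allocation measurements almost never come from the
same study, so combining them requires interpolation. The package mirrors
the field's practice:

* `saturated_linear_fit()` fits $y = a + b\min(x, x_0)$ — linear at slow
  growth, constant beyond the breakpoint, continuous by construction. For a
  fixed $x_0$ the model is linear in $(a, b)$, so the breakpoint is profiled
  over a grid of observed $x$ values plus midpoints and refined locally;
  ties break deterministically to the smallest breakpoint. The fit nests the
  pure line and the pure constant, so it can never do worse than either.
* `polynomial_interpolate()` smooths allocation and elongation data
  (default degree 2 — the lowest degree able to express the curvature seen
  in allocation data; configurable). Its evaluator warns on extrapolation
  outside the observed range.
* `growth_law_fit()` is the ordinary least-squares line of $\phi_R$ on
  $\lambda$, reporting $\hat\gamma = 1/\text{slope}$ and $\hat\eta =
  \text{intercept}\cdot\hat\gamma$ — the degradation rate that would fully
  account for the offset. For organisms without per-condition elongation
  measurements (the yeast situation), a constant $\gamma$ taken from the
  inverse slope of this fit is the supported workflow; where per-condition
  rates exist, $\gamma$ is carried per condition (`gamma_per_h` column) and
  never assumed global.

Per-condition relative differences between the models are reported under
both conventions found in the literature, $(f_b-f_a)/f_a$ (`rel_diff_fa`)
and $(f_b-f_a)/f_b$ (`rel_diff_fb`); only the latter equals $f_{bm}$, and
the partition table labels them distinctly.

## Synthetic data: what it emulates and what it does not

The generators produce every input the estimators consume, with the
generating truth attached:

* `generate_growth_law_dataset()` — condition tables on an even growth-rate
  grid (default $0.05$–$1\,h^{-1}$, $n = 10$), a linear allocation profile
  ($\phi_R = 0.05 + 0.15\lambda$, matching the observed offset and range for
  *E. coli*), constant $\gamma = 7.2\,h^{-1}$ (mid-range of measured
  elongation rates) and the ansatz-implied $\eta(\lambda)$, so the dataset
  satisfies the combined law exactly. Noise defaults are 0 (recovery tests)
  with conventional magnitudes of $\sigma_{\phi} = 0.003$ additive and 10%
  multiplicative lognormal on $\eta$ when enabled — the order of scatter
  visible in published compilations, which report no formal noise model.
* `generate_pulse_chase()` — mixture decay curves; default truth 7% fast at
  $1.2/h$, 23% slow at $0.02/h$, 70% stable, sampled every 30 min over 10 h,
  additive noise $\sigma = 0.01$ when enabled, noisy fractions clipped to
  $(0, 1]$.
* `generate_deg_vs_growth()` — the empirical decreasing-then-flat trend of
  mean degradation rate versus growth rate (default slope $-0.2$, intercept
  $0.06/h$, breakpoint $0.25/h$, hence plateau $0.01/h$); the breakpoint is
  included in the grid so the noiseless table lies exactly on the model.

`write_dataset()` writes the table plus a `key=value` ground-truth sidecar;
every estimator has a recovery test that reads only the files.

These generators reproduce the *structure* of the real datasets, not their
messiness: real compilations mix organisms, strains, labelling chemistries
and growth-rate ranges, have heteroscedastic and sometimes irreconcilable
errors across studies, and the constant-ratio ansatz is an approximation to
data rather than their generating process. Passing recovery tests therefore
demonstrates correctness of the estimators under the stated models, not that
the models are true of any particular organism. Analyses of the published
compilations (which live in an external repository) are supported by
`read_conditions()` plus `run_pipeline()` on a downloaded CSV, but are not
bundled or tested here.

## Numerical and design notes

* Units: all rates in $h^{-1}$ internally; elongation rates in aa/s are
  converted on entry ($\times 3600 / L_R$, with $L_R = 7300$ aa for
  *E. coli* and $12500$ aa for *S. cerevisiae* by default).
* Feasibility: $f_b$ may exceed 1 by at most $10^{-9}$ (float slack) before
  an infeasible-condition error; $\phi_R \in \{0, 1\}$ is rejected.
* Degenerate inputs: `maintenance_split()` errors when $\lambda = \eta = 0$
  (the split is undefined); `fa_to_fb()` refuses $\lambda = 0$ and points to
  `fb_combined()`; flat pulse-chase curves short-circuit to the zero fit.
* Problem sizes in the test suite (grids of 10–30 conditions, curves of
  20–40 timepoints, sweeps of 100–1000 random parameter sets) were chosen as
  the smallest sizes at which every identity and tolerance in the suite is
  informative; all tests complete in seconds.
* Known limitations: no regulatory feedback, no ribosome drop-off or
  traffic, no per-protein half-life catalogues, no cross-species scaling,
  and no modelling of biomass recycling from dead cells. The sector-weighted
  mean `eta_sector_weighted()` is provided for sensitivity analyses, but no
  published data currently constrain sector-specific rates.
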