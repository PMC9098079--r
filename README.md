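# ribomaint

Growth laws with ribosome maintenance and protein turnover.

## What this package is for

The first growth law relates the ribosomal proteome mass fraction φ_R to the
steady-state growth rate λ. The standard formulation, λ = γ φ_R f_a (with
γ = k/L_R the inverse time for a ribosome to synthesise its own protein
content), attributes the empirical zero-growth offset of the law entirely to
inactive ribosomes and predicts that active ribosomes vanish at λ = 0. That
prediction breaks down once protein degradation — with time scales
comparable to slow doubling times — enters the mass balance. `ribomaint`
implements the growth-law algebra with turnover for people analysing
ribosome-allocation and protein-degradation data (quantitative microbial
physiology, systems biology):

- the combined law **λ = γ φ_R f_b − η**, the bound-fraction bounds
  λ/(γφ_R) ≤ f_b ≤ 1, and the split of bound ribosomes into growth and
  maintenance shares, f_bg = 1/(1 + η/λ) and f_bm = (η/λ)/(1 + η/λ), which
  reaches 100% maintenance as λ → 0;
- the **constant-ratio ansatz** f_b(λ) = f_b0 + (1 − f_b0)·λ/(γφ_R) and the
  per-condition estimator of f_b0 from the identity
  η/(γφ_R) = f_b0·(1 − λ/(γφ_R));
- **pulse-chase degradation inference**: the single-exponential estimator
  η̂ = −log(P_L(t)/P_L(0))/t, its Jensen underestimation bias for
  heterogeneous proteomes, and two-/three-class exponential-mixture fits with
  mean rate ⟨η⟩ = f_fast η_fast + f_slow η_slow;
- the supporting toolbox: saturated (linear-then-constant) breakpoint
  regression, polynomial interpolation, first-growth-law OLS, a linearity
  diagnostic in Λ = (λ+η)/γ, an ODE mass-balance oracle, and synthetic-data
  generators with known ground truth for every estimator.

Everything is data-frame-first: functions take tibbles in the standard
condition/curve schemas and return tibbles, fitted objects support
`tidy()`, `glance()` and `autoplot()`.

## Worked example

Generate a self-consistent condition table under the constant-ratio ansatz
(f_b0 = 0.2, γ = 7.2/h, 5% multiplicative noise on the degradation rates),
then run the full pipeline:

```r
library(ribomaint)

gen <- generate_growth_law_dataset(n = 8, fb0 = 0.2, noise_eta = 0.05, seed = 7)
report <- run_pipeline(gen$conditions, smooth_eta = FALSE, lambda_max = Inf)
report
#> <ribomaint_report>
#>   conditions: 8
#>   f_b0 estimate: 0.1984 (sd 0.012 , n = 8 )
#>   growth law: gamma_hat = 6.667 /h, phi_R_min = 0.05
#>   linearity in Lambda: slope = 1.066 (implied f_b = 0.9382 )
```

The f_b0 estimate recovers the generating 0.2 within the noise. The
per-condition partition table shows degradation inflating the active pool at
slow growth — at λ = 0.05/h, 62% of the bound ribosomes are doing
maintenance rather than producing net growth:

```r
dplyr::select(report$partitions, growth_rate_per_h, f_a, f_b, f_bm)
#> # A tibble: 8 × 4
#>   growth_rate_per_h   f_a   f_b  f_bm
#> 1             0.05  0.121 0.318 0.620
#> 2             0.186 0.331 0.457 0.275
#> 3             0.321 0.455 0.560 0.188
#> # …
```

Fit a noiseless three-class pulse-chase curve (7% fast at 1.2/h, 23% slow at
0.02/h, 70% stable) and read off the mean degradation rate:

```r
pc <- generate_pulse_chase(seq(0, 10, 0.5), noise_sd = 0, seed = 1)
glance(fit_three_class(pc$curve))
#> # A tibble: 1 × 5
#>   mean_eta      rss     n classes method
#> 1   0.0886 2.47e-32    21       3 mixture
```

`mean_eta` equals the generating 0.07·1.2 + 0.23·0.02 = 0.0886/h.

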