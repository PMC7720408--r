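# overlapMR

Bayesian Mendelian randomization for one-sample, two-sample and
**overlapping-sample** designs with multiple exposures.

## The problem

Mendelian randomization (MR) estimates the causal effect of an exposure on
an outcome using genetic variants as instrumental variables. Classic
estimators assume the instrument–exposure and instrument–outcome
associations come either from the *same* individuals (one-sample 2SLS) or
from *disjoint* studies (two-sample IVW). In practice the two studies often
share a subset of participants — a complete-data study combined with
cheaper exposure-only and outcome-only arms — and applying a two-sample
method then requires discarding the shared individuals, while applying a
one-sample method is impossible.

`overlapMR` treats any overlap pattern as a *one-sample analysis with
missing data*. Individuals fall into three groups:

* **A** — instruments Z, exposures X and outcome Y all observed,
* **B** — Z and X observed, Y missing,
* **C** — Z and Y observed, X missing.

The structural model is linear with a latent scalar confounder U:

```
U      ~  N(0, 0.1)
X_1    ~  N(omega_1 + alpha_1 Z_1,               sigma_1^2)   + delta_1 U
X_2    ~  N(omega_2 + alpha_2 Z_2,               sigma_2^2)   + delta_2 U
X_3    ~  N(omega_3 + alpha_3 Z_2 + alpha_4 Z_3, sigma_3^2)   + delta_3 U
Y      ~  N(omega_Y + beta' X,                   sigma_Y^2)   + delta_4 U
```

`Z_2` loads on both `X_2` and `X_3` (horizontal pleiotropy), so the causal
effects `beta = (beta_1, beta_2, beta_3)` must be estimated jointly. Priors:
`beta ~ N(0, 10^2)`, `alpha ~ N(1, 0.3^2)`, `sigma ~ Inv-Gamma(3, 2)`.
Missing outcomes (group B) and exposures (group C) are imputed inside the
Markov chain alongside the parameters — Bayesian data augmentation — so the
posterior uses every observed cell and no individual is discarded. Classic
2SLS and multivariable IVW comparators and a full simulation harness
(replicate generation, mean / sd / coverage / power summaries) are included.

## Worked example

An 80%-overlap design: two association studies of 400 individuals sharing
320, i.e. groups of 320 / 80 / 80:

```r
library(overlapMR)
cfg <- simConfig(overlapRate = 0.8, alphaTrue = 0.5, betaTrue = 0.3,
                 deltaTrue = 1)
d <- simulateDesign(cfg, seed = 42)
d
#> MRData with 480 individuals, 3 instruments, 3 exposures
#>   groups: A (complete) 320 | B (Y missing) 80 | C (X missing) 80

fit <- runChain(d, seed = 42)
posteriorSummary(fit)[1:3, ]
#>   parameter      mean         sd     lower     upper     rhat      ess
#> 1     beta1 0.3199494 0.01736600 0.2865078 0.3535534 0.999984 562.3145
#> 2     beta2 0.2660490 0.02312117 0.2222423 0.3109861 1.000700 659.9679
#> 3     beta3 0.3103045 0.01699079 0.2778870 0.3430395 1.002157 759.2971
```

All three true effects (0.3) are inside their 95% credible intervals; the
pleiotropy-affected `beta2` carries visibly more posterior uncertainty. The
design-appropriate classic comparator must drop the 320 shared individuals
and run two-sample IVW on the 80 + 80 remainder, with much wider intervals:

```r
classicForDesign(d)
#> ClassicEstimate (IVW)
#>  exposure estimate     se   lower  upper
#>         1   0.3168 0.0946  0.1314 0.5022
#>         2   0.1558 0.1396 -0.1178 0.4294
#>         3   0.3691 0.0931  0.1865 0.5516
```

Simulation studies over a grid of overlap rates, instrument strengths,
confounding levels and effect sizes run through `gridSpec()` / `runGrid()`,
which emit per-condition mean, sd, coverage and power tables. A command-line
interface (`inst/scripts/overlapmr`) exposes `simulate`, `fit`, `classic`
and `replicate` subcommands over TSV datasets with YAML configuration and a
JSON run manifest.

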