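# dpmlpa

Latent profile analysis (LPA) groups people into discrete latent
profiles from continuous indicator variables — for example,
standardized neurocognitive task scores in a developmental cohort.
Conventional LPA must fix the number of profiles in advance and pick
it by comparing many fitted models, and the standard criteria (AIC,
BIC, bootstrap likelihood ratio test, classification entropy)
routinely disagree. `dpmlpa` implements **DPM-LPA**: a non-parametric
Bayesian LPA built on a Dirichlet process mixture, fit by mean-field
variational inference, in which the number of profiles is inferred
from the data while unneeded profiles are left empty.

The package is aimed at researchers running person-centered analyses
(psychology, epidemiology, biostatistics) who want profile solutions
that balance fit against interpretability, plus the machinery to
compare methods and to validate profiles against outcome variables.

## The model

All participants share the mixture likelihood

x_{j,i} | z_i = t  ~  N(mu_{j,t}, 1/xi_j),

a Gaussian finite mixture with profile-specific means and a shared
diagonal covariance (precisions `xi_j` common to all profiles).
DPM-LPA places a Dirichlet process prior on the profile assignments
(Pólya-urn form)

p(z_{1:n}) = alpha^T * prod_t (n_t - 1)! / [alpha (alpha+1) ... (n-1+alpha)],

with conjugate priors `xi_j ~ Gamma(5, 5)`,
`mu_{j,t} | xi_j ~ N(0, 2/xi_j)`, and a `Gamma(1, 1)` hyperprior on the
concentration parameter `alpha`. The posterior is approximated with a
truncated stick-breaking variational family by coordinate ascent on
the ELBO; a fitted component is retained only if it is the most
probable profile for at least one participant.

Alongside DPM-LPA the package provides:

* `fit_em()`, `information_criteria()`, `blrt()`, `select_profiles()`
  — conventional maximum-likelihood LPA (EM, compiled inner loop),
  AIC/BIC, and the parametric-bootstrap likelihood ratio test;
* `fit_finite_bayes()` — finite Bayesian LPA (symmetric Dirichlet
  prior on the mixing proportions), selected by ELBO;
* `classification_entropy()`, `entropy_reduction()`,
  `mahalanobis_distance()`, `distance_summary()` — classification
  certainty and profile distinctiveness metrics;
* `validate_outcome()` and friends — a conjugate Bayes-factor ANOVA
  with exhaustive partition post-hoc search, per-profile posterior
  outcome means with 95% credible intervals, and an r² effect size;
* `simulation_scenario()`, `generate_dataset()`, `run_benchmark()` —
  a class-enumeration simulation benchmark;
* `lpa_cli()` and the `inst/cli/dpm-lpa` script — `fit`, `select`,
  `outcomes`, `simulate`, `compare` commands for reproducible,
  seeded runs.

## Worked example

Three latent profiles, 600 participants, four indicators; one profile
carries an elevated outcome:

```r
library(dpmlpa)
set.seed(1)
sc  <- simulation_scenario(600, m = 4, T_true = 3, separation = 3, base_seed = 11)
gen <- generate_dataset(sc, 1)
fit <- fit_dpm(indicator_matrix(gen$values), seed = 2)
fit
#> DPM-LPA fit: truncation 20 -> 3 retained profile(s); ELBO -1888.9982 (converged)
round(fit$profiles$means, 2)
#>       [,1]  [,2]  [,3]  [,4]
#> [1,]  0.00  0.00 -0.02 -0.01
#> [2,]  1.14  1.12  1.14  1.13
#> [3,] -1.14 -1.12 -1.13 -1.12
entropy_reduction(fit$profiles$resp)
#> 0.995
distance_summary(fit$profiles)
#> profile distances: min 5.582 | mean 7.519 over 3 pairs
```

The fit retains exactly the three generating profiles (labeled in
decreasing size order; means are on the z-scored indicator scale, so
profile 2 sits about 1.1 SD above average on every indicator). The
entropy reduction near 1 says participants are classified with almost
total certainty, and the smallest pairwise precision-weighted
(Mahalanobis) distance of 5.6 says no two profiles are redundant.

Validating against an outcome that is elevated in one profile only:

```r
y   <- outcome_vector(c(0, 0, 1)[gen$true_labels] + rnorm(600))
res <- validate_outcome(y, fit$profiles$resp)
res
#> Bayes-factor ANOVA: log10(BF10) = 13.94 -> supports_H1
#> r^2 = 0.1162 | best partition: {1,3},{2}
round(res$profile_posteriors, 3)
#>   profile   n   mean ci_lower ci_upper
#> 1       1 201 -0.192   -0.321   -0.062
#> 2       2 200  0.476    0.346    0.606
#> 3       3 199 -0.285   -0.416   -0.155
```

`log10(BF10) = 13.9` is decisive evidence that profile outcome means
differ (values in (-0.5, 0.5) would be inconclusive). The post-hoc
search over all set partitions of the profiles concludes that
profiles 1 and 3 share a mean while profile 2 differs — exactly the
planted structure — and the credible intervals show profile 2 about
0.5 SD above the others on the standardized outcome.

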