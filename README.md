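# EFDMreg

Distribution theory and Bayesian regression for overdispersed multivariate
count data — taxa-by-sample tables from 16S/metagenomic sequencing — built
on the **extended flexible Dirichlet-multinomial (EFDM)** family.

## Who this is for, and what it does

Microbiome count vectors $Y_i \in \{0,\dots,n_i\}^D$, $\sum_r Y_{ir} = n_i$,
are overdispersed relative to the multinomial and show both co-absence and
co-occurrence between taxa. The classical Dirichlet-multinomial (DM) fixes
only the first problem: its intraclass correlation $1/(\alpha^+ + 1)$ is the
same for every taxon and all its interclass correlations are negative.

The EFDM is a *structured* mixture of DM components: component $r$ has mean
$\lambda_r = (\alpha + \tau_r e_r)/(\alpha^+ + \tau_r)$ — a common
barycenter pulled toward the $r$-th simplex vertex — precision
$\alpha^+ + \tau_r$, and weight $p_r$:

$$f_{\mathrm{EFDM}}(y;\alpha,\tau,p) \;=\; \sum_{r=1}^{D} p_r\,
  f_{\mathrm{DM}}\!\bigl(y;\ \lambda_r,\ \alpha^+{+}\,\tau_r\bigr).$$

The structure keeps the parameter count linear in $D$, makes the mixture
identifiable, and yields closed-form moments, taxonwise intraclass
correlations, and interclass correlations that may be positive
(co-occurrence). Setting $\tau \equiv \tau$ gives the flexible DM (FDM);
$\tau \equiv 1,\ p = \alpha/\alpha^+$ recovers the DM.

The regression model **EFDMReg** links the marginal mean
$\mu_i = E[Y_i/n_i]$ to covariates through the multinomial logit
$\log(\mu_{ir}/\mu_{iD}) = x_i^\top\beta_r$ (configurable baseline taxon),
with global $(\alpha^+, p, \tilde w)$ in the variation-independent
mean-level parameterization. Estimation is Bayesian, via blocked adaptive
Metropolis in C++ with weakly informative priors; model comparison uses
WAIC; covariate-level spike-and-slab selection with marginalized inclusion
indicators provides posterior inclusion probabilities and a two-stage
select-then-refit workflow. Posterior-predictive zero-handling metrics,
Kullback–Leibler divergence, class-correlation tables and correlation
networks support downstream interpretation.

## Worked example

Simulate the packaged five-taxon recovery scenario (one standard-normal
covariate, $\alpha^+ = 50$, $p_1 = 0.25$) and fit the EFDM regression:

```r
library(EFDMreg)
sim <- simulateScenario(caseIVScenario(), seed = 7)
fit <- fitEFDMReg(sim$data, family = "efdm",
                  mcmc = mcmcConfig(chains = 2, warmup = 6000, iter = 6000,
                                    thin = 5, seed = 7))
fit
#> EFDMFit: family = efdm
#>   draws: 2400 ( 2 chains x 1200 )
#>   acceptance: 0.241, 0.236
#>   max split R-hat: 1.028  min ESS: 61
posteriorSummary(fit, truth = sim$truth)[c(9, 10, 15), ]
#>    parameter   mean     sd  lower  upper truth    sqErr covered
#> 9  alphaPlus 50.154 3.6921 43.363 58.021 50.00 0.023837    TRUE
#> 10      p[1]  0.229 0.0169  0.198  0.263  0.25 0.000454    TRUE
#> 15 wtilde[1]  0.553 0.0222  0.510  0.596  0.60 0.002221   FALSE
waic(fit)$waic
#> [1] 9103.8
```

The posterior recovers the generating precision ($\alpha^+$: mean 50.2,
95% credible set 43.4–58.0) and first mixing weight (0.229 vs truth 0.25);
`waic()` values are comparable across `family = "dm"`, `"fdm"`, `"efdm"`
fits of the same data and order them by fit quality (lower is better).
Posterior-averaged dependence summaries expose what the DM cannot:

```r
mom <- fittedMoments(fit, size = 100)
round(mom@intraclass, 3)
#> taxon1 taxon2 taxon3 taxon4 taxon5
#>  0.039  0.077  0.680  0.314  0.042     # taxonwise, not constant
correlationNetwork(mom)                  # positive = co-occurrence edges
#>    source target  weight     sign
#> 3  taxon1 taxon4  0.0322 positive
#> 6  taxon2 taxon4  0.0718 positive
#> 8  taxon3 taxon4 -0.4470 negative
#> ...
```

A thin command-line wrapper (`inst/scripts/efdmreg`) exposes `simulate`,
`fit`, `select`, `network`, `evaluate` and `waic` subcommands over
TSV/CSV tables.

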