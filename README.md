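# deerforecast

Overabundant white-tailed deer degrade forest understories, spread
tick-borne disease and collide with cars, but parks and residential areas
often cannot use regulated hunting to control them. Managers therefore
ask whether fertility control — sterilization or contraception — can do
what culling does. `deerforecast` is for quantitative ecologists and
wildlife managers who want that question answered with honest
uncertainty: it fits a Bayesian hierarchical state-space model to
park-by-year density estimates and age/sex classification counts, checks
the fit, and forecasts the probability that each management regime meets
a density objective.

## The model

Latent abundances of juveniles, does and bucks follow a Lefkovitch stage
projection with density-dependent fecundity and lognormal process error:

    A = [ 0        s2*f   0  ]        f(D) = exp(r_f - (r_f/K_f) * D)
        [ s1*m     s2     0  ]
        [ s1*(1-m) 0      s3 ]        log n_t ~ MVN(log(A n_{t-1}), sigma_p^2 I)

Park survivals get hierarchical beta priors with gamma hyperpriors
centred on literature meta-analysis values; the sex ratio has a
Beta(312, 312) prior (mean 0.5, SD 0.02); maximum fecundity has an
allometric normal prior (mean 1.56 at 65 kg body mass, SD 0.1304).
Classification counts are multinomial in the latent stage proportions and
density estimates are normal with known survey SEs. An adaptive
Metropolis-within-Gibbs sampler (C++ core) draws the joint posterior of
all parameters and latent states. Management experiments add a
sterile/contracepted doe class and evaluate culling, sterilization, and
one- and three-year contraceptives at 20/40/60/90% of does per year via
posterior distributions of the asymptotic growth rate λ, five-year
posterior predictive forecasts, probabilities of meeting a 5–15 deer/km²
objective, treatment numbers and program costs.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on a
synthetic survey with known truth (no external data needed). From the
repository root:

```sh
Rscript analysis/01_simulate.R   # 8 parks x 13 years, truth recorded
Rscript analysis/02_fit.R        # MCMC fit, posterior summaries
Rscript analysis/03_check.R      # posterior predictive check
Rscript analysis/04_eigenanalysis.R
Rscript analysis/05_forecast.R
Rscript analysis/06_experiments.R
```

`02_fit.R` prints the regional posterior (generating values in
parentheses): female survival 0.62 (0.67), juvenile survival 0.78
(0.75), male survival 0.41 (0.45), sex ratio 0.510 (0.53), process
variance 0.54 (0.50), carrying capacity 34.5 (27.1) and maximum
fecundity 1.33 (0.86) — the last two sit above truth because the
informative allometric prior dominates the weakly identified fecundity
intercept; the methods vignette explains why that is expected and not a
sampler defect. `03_check.R` reports a Bayesian P-value of 0.26
(no lack of fit). `04_eigenanalysis.R` tabulates λ by treatment:
culling 90% of does drops the median growth rate from 1.31 (no action)
to 0.41, while sterilization floors near adult female survival (0.62 at
90%). `06_experiments.R` shows the decision layer: culling 60% has the
highest probability of landing inside the 5–15 deer/km² objective five
years out (p_in ≈ 0.68 at ~5,200 does), contraceptives alone need far
larger treatment numbers, and culling 90% once then maintaining with 20%
contraception handles ~65% fewer does than a 90% contraception-only
program.

All outputs land in `results/` as CSV tables.

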