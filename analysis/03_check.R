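#!/usr/bin/env Rscript
# Posterior predictive check: the Bayesian P-value on the squared-error
# discrepancy between observed and model-predicted densities.

library(deerforecast)

fit <- readRDS("results/fit.rds")
data <- load_survey_data("data/synthetic/density.csv",
                         "data/synthetic/classification.csv",
                         "data/synthetic/parks.csv")
set.seed(3)
ppc <- posterior_predictive_pvalue(fit, data)
print(ppc)
write_ppc(ppc, "results/ppc.csv")
cat("Values near 0.5 indicate the replicated data resemble the real data;\n")
cat("values near 0 or 1 would flag structural lack of fit.\n")
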