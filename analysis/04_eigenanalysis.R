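#!/usr/bin/env Rscript
# Posterior distributions of the asymptotic growth rate lambda for every
# treatment type and intensity, from linearized projection matrices
# (fecundity at its maximum, density term zero) built draw by draw.

library(deerforecast)

fit <- readRDS("results/fit.rds")
tab <- lambda_table(fit, max_draws = 3000)
write.csv(tab, "results/lambda_table.csv", row.names = FALSE)
cat("Growth-rate posteriors by treatment (medians and 95% BCI):\n")
print(tab, digits = 3)

no_action <- tab$median[tab$treatment == "none"]
cat(sprintf("\nNo-action lambda median: %.3f\n", no_action))
cat(sprintf("Cull 90%%: %.3f; sterilize 90%%: %.3f (floors near adult female survival)\n",
            tab$median[tab$treatment == "cull" & tab$p == 0.9],
            tab$median[tab$treatment == "sterilize" & tab$p == 0.9]))

# where is lambda most sensitive? evaluate at the posterior-median matrix
sm <- summary(fit, pars = c("mu[1]", "mu[2]", "mu[3]", "m", "r_f", "K_f"))
v <- vital_rates(sm$median[1], sm$median[2], sm$median[3], sm$median[4],
                 sm$median[5], sm$median[6])
S <- sensitivities(annual_treated_matrix(v, treatment_spec("none")))
write.csv(S, "results/sensitivities.csv")
cat("\nSensitivities of lambda at the posterior-median matrix:\n")
print(round(S, 3))
ij <- which(S == max(S), arr.ind = TRUE)[1, ]
entry <- c("n1.n2" = "recruitment (s2*f)", "n2.n1" = "maturation to does (s1*m)",
           "n2.n2" = "adult female survival (s2)",
           "n3.n1" = "maturation to bucks", "n3.n3" = "male survival (s3)")
key <- paste(rownames(S)[ij[1]], colnames(S)[ij[2]], sep = ".")
cat("Largest sensitivity:", rownames(S)[ij[1]], "<-", colnames(S)[ij[2]],
    "=", unname(entry[key]), "\n")
cat("(For a declining population at the reference medians, adult female\n",
    "survival carries the largest sensitivity; in this growing synthetic\n",
    "fit the maturation flow into the doe stage can dominate.)\n")
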