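#!/usr/bin/env Rscript
# Management experiments: the four treatment types at four intensities,
# evaluated by probability of meeting the 5-15 deer/km2 objective five
# years out, treatment numbers (does handled), program cost, and the net
# effect relative to no action; plus the cull-then-maintain combination.

library(deerforecast)

fit <- readRDS("results/fit.rds")
obj <- management_objective(5, 15, horizon = 5)

set.seed(6)
grid <- experiment_grid(fit, obj, max_draws = 500)
write.csv(grid, "results/experiment_grid.csv", row.names = FALSE)
cat("Treatment grid (p_in = probability within objective at year 5):\n")
print(grid, digits = 3, row.names = FALSE)

best <- grid[which.max(grid$p_in * (grid$treatment != "none")), ]
cat(sprintf("\nHighest p_in: %s at %.0f%% (p_in = %.2f, ~%d does, $%s)\n",
            best$treatment, 100 * best$p, best$p_in, round(best$effort_median),
            format(round(best$cost), big.mark = ",")))

# culling first, then maintaining with fertility control
set.seed(7)
rows <- list()
for (ty in c("sterilize", "contracept1", "contracept3")) {
  for (p in c(0.2, 0.4, 0.6, 0.9)) {
    plan <- list(treatment_spec("cull", 0.9, years = 1),
                 treatment_spec(ty, p, years = 2:5))
    ens <- forecast(fit, 5, plan, max_draws = 500)
    pr <- objective_probabilities(ens, obj)
    eff <- treatment_effort(ens)
    cull_n <- eff$per_year[[1]]
    fert_n <- eff$total_median - cull_n
    rows[[length(rows) + 1L]] <- data.frame(
      maintain = ty, p = p, p_below = pr[[1]], p_in = pr[[2]],
      p_above = pr[[3]], culled_yr1 = cull_n, treated_after = fert_n,
      cost = program_cost(setNames(c(cull_n, fert_n), c("cull", ty))))
  }
}
comb <- do.call(rbind, rows)
write.csv(comb, "results/combined_plans.csv", row.names = FALSE)
cat("\nCull 90% in year 1, then maintain with fertility control:\n")
print(comb, digits = 3, row.names = FALSE)

alone <- grid[grid$treatment == "contracept1" & grid$p == 0.9, ]
pick <- comb[comb$maintain == "contracept1" & comb$p == 0.2, ]
cat(sprintf("\nRelative effort: cull-then-contracept-20%% handles %d does vs %d for contracept-90%% alone (%.0f%% less).\n",
            round(pick$culled_yr1 + pick$treated_after),
            round(alone$effort_median),
            100 * (1 - (pick$culled_yr1 + pick$treated_after) / alone$effort_median)))
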