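#!/usr/bin/env Rscript
# Effective dose for one year of full-time exposure on the dried-out pond,
# by age group (newborn, 1, 5, 10, 15, adult), from the conservative profile.
# Doses decline monotonically from newborn to adult because the coefficient
# table's age factors do.

library(sedidose)

samples <- read_core_samples("results/inputs/cores.csv")
profile <- build_conservative_profile(samples)
table <- read_coefficient_table("results/inputs/coefficients.csv")
weights <- read_tissue_weights("results/inputs/tissue_weights.csv")

tab <- dose_table_by_age(profile, table, weights, ages = c(0, 1, 5, 10, 15, 20))
tab$E_mSv <- 1e3 * tab$E_Sv
write.csv(tab, "results/dose_by_age.csv", row.names = FALSE)

cat("Effective dose, 1-year full-time exposure (mSv):\n")
print(data.frame(age = tab$age, E_mSv = round(tab$E_mSv, 2)), row.names = FALSE)
cat(sprintf("Newborn/adult ratio: %.2f\n", tab$E_mSv[1] / tab$E_mSv[6]))
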