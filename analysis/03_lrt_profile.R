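#!/usr/bin/env Rscript
# Stage 3: is there kinetic proofreading, and how long is it?
#
# Likelihood-ratio test of the KPR model against the occupancy null
# (boundary-corrected mixture null, since tau_KPR = 0 sits on the parameter
# boundary), then the profile-likelihood 95% confidence interval for the KPR
# time. Writes the profile curve and a combined report.

suppressMessages(library(optoKPR))
seed <- 1L

data <- read_dataset_bundle("results/synthetic_data")
lrt <- likelihood_ratio_test(data, n_starts = 20, seed = seed)
print(lrt)

prof <- profile_likelihood_tau(data, fit = lrt$fit_kpr, seed = seed)
print(prof)

write.csv(prof$profile, "results/profile_tau.csv", row.names = FALSE)
write_fit_report(lrt$fit_kpr, "results/report.json", lrt = lrt,
                 profile = prof)
cat("Wrote results/profile_tau.csv and results/report.json\n")
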