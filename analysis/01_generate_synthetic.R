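#!/usr/bin/env Rscript
# Generate the synthetic tensile data set used by the downstream analyses:
# one monotonic test and one incremental cyclic test drawn from the
# tissue-calibrated generator profile (soft plateau ~12 N/m, stiff plateau
# ~70 N/m, recovery schedule 85% -> 40%), with seeded measurement noise.

library(wallmech)

dir.create("results", showWarnings = FALSE)

prof <- generator_profile(seed = 101)
mono <- generate_monotonic(prof)
write_curve_csv(mono$curve, "results/synthetic_monotonic.csv")
jsonlite::write_json(mono$expected_summary,
                     "results/synthetic_monotonic_truth.json",
                     auto_unbox = TRUE, digits = 9)

peaks <- c(1.08, 1.14, 1.20, 1.26, 1.32, 1.40)
cyc <- generate_cyclic(generator_profile(seed = 202), peaks)
write_curve_csv(cyc$curve, "results/synthetic_cyclic.csv")
jsonlite::write_json(cyc$truth_cycles, "results/synthetic_cyclic_truth.json",
                     digits = 9)

cat("Monotonic curve:", nrow(mono$curve), "samples to stretch",
    max(mono$curve$lambda_ax), "\n")
cat("Cyclic curve:", nrow(cyc$curve), "samples,", length(peaks), "cycles\n")
cat("Ground truth written alongside both curves under results/.\n")
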