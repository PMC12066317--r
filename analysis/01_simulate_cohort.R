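#!/usr/bin/env Rscript
# Step 1: simulate the study cohort.
#
# Generates a 56-patient synthetic cohort in the ventral_effect scenario
# (planted sweet sphere in the ventrocentral left STN, positive
# PFC-bundle and negative SMC-bundle tract effects) and writes it, with
# its ground truth, under results/cohort/.

suppressPackageStartupMessages(library(dbsmap))

cohort <- generate_cohort(n_patients = 56, scenario = "ventral_effect",
                          seed = 7)
cfg <- write_cohort(cohort, "results/cohort")

cat("Simulated cohort written to", cfg, "\n")
print(cohort)
gt <- cohort$ground_truth
cat(sprintf("Planted sweet spot: center (%.2f, %.2f, %.2f) mm, radius %.1f mm\n",
            gt$sweet_center[1], gt$sweet_center[2], gt$sweet_center[3],
            gt$sweet_radius))
cat(sprintf("Effect weights: voxel %+.1f, PFC bundle %+.1f, SMC bundle %+.1f, noise SD %.1f\n",
            gt$voxel_effect_weight, gt$tract_effect_weights$PFC,
            gt$tract_effect_weights$SMC, gt$noise_sd))
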