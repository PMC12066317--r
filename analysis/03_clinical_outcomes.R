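#!/usr/bin/env Rscript
# Step 3: clinical outcome statistics.
#
# Baseline vs 6-month summary per scale (normality-gated paired tests,
# improvement rate of the medians), Spearman correlations of
# active-contact coordinates and of STN-subregion overlaps with
# HAMA/HAMD improvement rates.

suppressPackageStartupMessages(library(dbsmap))

cohort <- read_cohort("results/cohort/cohort.yaml")

summary_tab <- summarize_cohort(cohort)
write.csv(summary_tab, "results/cohort_summary.csv", row.names = FALSE)
cat("Cohort summary (results/cohort_summary.csv):\n")
print(summary_tab, digits = 3)

coords <- active_contact_coordinates(cohort)
coord_cor <- coordinate_outcome_correlations(coords, cohort$clinical)
write.csv(coord_cor, "results/coordinate_correlations.csv", row.names = FALSE)
zrows <- coord_cor[coord_cor$axis == "z" & coord_cor$scale == "HAMA", ]
cat("\nActive-contact Z vs HAMA improvement (Spearman):\n")
for (i in seq_len(nrow(zrows)))
  cat(sprintf("  %-5s rho = %+.3f, p = %.4f\n", zrows$hemisphere[i],
              zrows$rho[i], zrows$p_value[i]))

overlaps <- cohort_overlap_table(cohort)
ov_cor <- overlap_outcome_correlations(overlaps, cohort$clinical)
write.csv(ov_cor, "results/overlap_correlations.csv", row.names = FALSE)
limb <- ov_cor[grepl("limbic", ov_cor$region_label) & ov_cor$scale == "HAMA" &
                 mapply(grepl, ov_cor$hemisphere, ov_cor$region_label), ]
cat("\nLimbic-overlap vs HAMA improvement (Spearman):\n")
for (i in seq_len(nrow(limb)))
  cat(sprintf("  %-22s (%s electrodes) rho = %+.3f, p = %.4f\n",
              limb$region_label[i], limb$hemisphere[i], limb$rho[i],
              limb$p_value[i]))
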