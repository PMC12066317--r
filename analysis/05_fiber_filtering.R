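#!/usr/bin/env Rscript
# Step 5: fiber filtering by fiber T-scores with cross-validation.
#
# Streamline-VTA connectivity, 20% prevalence filter, pooled-variance
# fiber T-scores for HAMA change, top-30% selection (positive and
# negative sets written as TCK), LOOCV and 10-fold validation.

suppressPackageStartupMessages(library(dbsmap))

cohort <- read_cohort("results/cohort/cohort.yaml")
vtas <- patient_vta_voxels(cohort)
conn <- streamline_vta_connectivity(cohort$tractogram, vtas,
                                    cohort$atlas$volume)
changes <- clinical_outcome(cohort$clinical, "HAMA")

kept <- prevalence_filter(conn)
scores <- fiber_t_scores(conn, changes, kept)
selected <- select_top_fraction(scores)
cat(sprintf("%d/%d fibers pass the 20%% prevalence filter; %d selected (top 30%% by |T|)\n",
            length(kept), nrow(conn), length(selected)))

sel <- scores[scores$fiber_id %in% selected, ]
dir.create("results/fibers", showWarnings = FALSE, recursive = TRUE)
write.csv(scores, "results/fibers/fiber_t_scores.csv", row.names = FALSE)
pos <- sel$fiber_id[sel$t_score > 0]
neg <- sel$fiber_id[sel$t_score < 0]
write_tractogram(tractogram(cohort$tractogram$streamlines[pos]),
                 "results/fibers/selected_positive.tck")
write_tractogram(tractogram(cohort$tractogram$streamlines[neg]),
                 "results/fibers/selected_negative.tck")

bundle <- cohort$ground_truth$fiber_bundle
if (!is.null(bundle)) {
  cat(sprintf("Selected positive-T fibers in PFC bundle: %d/%d; negative-T in SMC bundle: %d/%d\n",
              sum(bundle[pos] == "PFC"), length(pos),
              sum(bundle[neg] == "SMC"), length(neg)))
}

cv_loo <- crossvalidate_fibers(cohort, "HAMA", "loocv", conn = conn)
cv_k10 <- crossvalidate_fibers(cohort, "HAMA", "kfold", k = 10, seed = 7,
                               conn = conn)
print(cv_loo)
print(cv_k10)
jsonlite::write_json(
  list(outcome = "HAMA", n_fibers = nrow(conn), n_kept = length(kept),
       n_selected = length(selected),
       loocv = list(R = cv_loo$R, p = cv_loo$p_value),
       kfold10 = list(R = cv_k10$R, p = cv_k10$p_value)),
  "results/fibers/summary.json", auto_unbox = TRUE, digits = NA)
cat("Fiber tables and TCKs written under results/fibers/\n")
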