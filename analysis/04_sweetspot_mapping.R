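#!/usr/bin/env Rscript
# Step 4: voxel-wise sweet-spot mapping with LOOCV validation.
#
# N-image, 20% coverage filter, mean-effect map, voxel-wise signed-rank
# p-map, BH q-map, sweet/sour labels; leave-one-out and 10-fold
# cross-validated prediction of HAMA change.

suppressPackageStartupMessages(library(dbsmap))

cohort <- read_cohort("results/cohort/cohort.yaml")
vtas <- patient_vta_voxels(cohort)

maps <- build_sweetspot_maps(cohort, outcome = "HAMA", vtas = vtas)
print(maps)
dir.create("results/sweetspot", showWarnings = FALSE, recursive = TRUE)
write_image(maps$n_image, "results/sweetspot/n_image.nii.gz", datatype = "int16")
for (nm in c("mean_effect", "p_map", "q_map", "label_map"))
  write_image(maps[[nm]], file.path("results/sweetspot",
                                    paste0(nm, ".nii.gz")))

cv_loo <- crossvalidate_sweetspot(cohort, "HAMA", "loocv", vtas = vtas)
cv_k10 <- crossvalidate_sweetspot(cohort, "HAMA", "kfold", k = 10, seed = 7,
                                  vtas = vtas)
print(cv_loo)
print(cv_k10)
write.csv(data.frame(patient_id = names(vtas), fold = cv_loo$fold,
                     predicted = cv_loo$predicted, observed = cv_loo$observed),
          "results/sweetspot/cv_loocv.csv", row.names = FALSE)
jsonlite::write_json(
  list(outcome = "HAMA", n_kept = maps$n_kept, n_sweet = maps$n_sweet,
       n_sour = maps$n_sour, alpha = maps$alpha,
       loocv = list(R = cv_loo$R, p = cv_loo$p_value),
       kfold10 = list(R = cv_k10$R, p = cv_k10$p_value)),
  "results/sweetspot/summary.json", auto_unbox = TRUE, digits = NA)
cat("Maps and CV results written under results/sweetspot/\n")
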