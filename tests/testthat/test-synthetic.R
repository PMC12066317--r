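test_that("toy atlas has mirrored tripartite STNs and cortical targets", {
  atlas <- make_toy_atlas()
  expect_setequal(names(atlas$legend),
                  c(paste0("STN_left_", c("sensorimotor", "associative", "limbic")),
                    paste0("STN_right_", c("sensorimotor", "associative", "limbic")),
                    "PFC_box", "SMC_box"))
  counts <- table(atlas$volume$data[atlas$volume$data > 0])
  expect_true(all(atlas$legend %in% as.integer(names(counts))))
  # mirror symmetry: left/right sublabel voxel counts coincide
  for (part in c("sensorimotor", "associative", "limbic"))
    expect_identical(length(region_voxels(atlas, paste0("STN_left_", part))),
                     length(region_voxels(atlas, paste0("STN_right_", part))))
  # ventral-dorsal ordering: limbic centroid below sensorimotor centroid
  w <- grid_world_coords(atlas$volume)
  zc <- function(reg) mean(w[region_voxels(atlas, reg), 3])
  expect_lt(zc("STN_left_limbic"), zc("STN_left_associative"))
  expect_lt(zc("STN_left_associative"), zc("STN_left_sensorimotor"))
  # PFC box anterior (larger y) of SMC box
  expect_gt(mean(w[region_voxels(atlas, "PFC_box"), 2]),
            mean(w[region_voxels(atlas, "SMC_box"), 2]))
})

test_that("atlas construction rejects unresolvable grids", {
  expect_error(make_toy_atlas(grid_shape = c(30, 64, 64)), "40 voxels")
  expect_error(make_toy_atlas(voxel_size_mm = 2), "coarse")
  expect_error(make_toy_atlas(voxel_size_mm = 1, stn_half_length_mm = 2),
               "sublabels")
})

test_that("electrode placement follows the offset and jitter contract", {
  atlas <- make_toy_atlas()
  set.seed(3)
  e0 <- make_electrode(atlas, "left", 0, jitter_mm = 0)
  # contact 0 sits at the ventral STN border, within one voxel of the
  # ventral-most limbic voxel
  w <- grid_world_coords(atlas$volume)
  limb <- w[region_voxels(atlas, "STN_left_limbic"), ]
  zmin <- min(limb[, 3])
  c0 <- electrode_contacts(e0)[1, ]
  expect_lt(abs(c0["z"] - zmin), 1)
  # dorsoventral offset is a pure z translation
  e4 <- make_electrode(atlas, "left", 4, jitter_mm = 0)
  expect_equal(electrode_contacts(e4)[, "z"],
               electrode_contacts(e0)[, "z"] + 4)
  expect_equal(electrode_contacts(e4)[, c("x", "y")],
               electrode_contacts(e0)[, c("x", "y")])
  # collinear, spaced 2 mm
  cc <- electrode_contacts(e0)
  expect_equal(unname(sqrt(rowSums(diff(cc)^2))), rep(2, 3))
  # jitter is reproducible from the seed and bounded
  set.seed(9); a <- make_electrode(atlas, "right", 1)
  set.seed(9); b <- make_electrode(atlas, "right", 1)
  expect_identical(a, b)
  expect_lte(max(abs(electrode_contacts(a)[, "x"] -
                       electrode_contacts(make_electrode(atlas, "right", 1,
                                                         jitter_mm = 0))[, "x"])),
             0.5)
})

test_that("synthetic tractogram bundles start in their seed subregions", {
  atlas <- make_toy_atlas()
  set.seed(4)
  tr <- make_tractogram(atlas, n_fibers_per_bundle = 20)
  expect_identical(tr$count, 40L)
  expect_true(all(vapply(tr$streamlines, nrow, 1L) >= 10))
  bundle <- attr(tr, "bundle")
  expect_identical(sum(bundle == "PFC"), 20L)
  limbic <- c(region_voxels(atlas, "STN_left_limbic"),
              region_voxels(atlas, "STN_right_limbic"))
  sm <- c(region_voxels(atlas, "STN_left_sensorimotor"),
          region_voxels(atlas, "STN_right_sensorimotor"))
  starts <- t(vapply(tr$streamlines, function(s) s[1, ], numeric(3)))
  idx <- world_to_linear_index(atlas$volume, starts)
  expect_true(all(idx[bundle == "PFC"] %in% limbic))
  expect_true(all(idx[bundle == "SMC"] %in% sm))
  set.seed(4)
  tr2 <- make_tractogram(atlas, n_fibers_per_bundle = 20)
  expect_identical(tr$streamlines, tr2$streamlines)
})

test_that("planted outcome model obeys its formula in degenerate cases", {
  atlas <- make_toy_atlas()
  # electrode placed dorsally enough that its VTA misses the sweet sphere
  el <- rbind(make_electrode(atlas, "left", 12, jitter_mm = 0, patient_id = "A"),
              make_electrode(atlas, "right", 12, jitter_mm = 0, patient_id = "A"))
  gt <- list(sweet_center = unlist(atlas$geometry$stn_center$left) -
               2 * unlist(atlas$geometry$stn_axis$left),
             sweet_radius = 2.5, voxel_effect_weight = 3,
             tract_effect_weights = list(PFC = 0, SMC = 0), noise_sd = 0)
  set.seed(5)
  tr <- make_tractogram(atlas, 10)
  cl <- simulate_outcomes(list(atlas = atlas, electrodes = el, tractogram = tr), gt)
  expect_equal(cl$hama_pre - cl$hama_post, 0)
  # with w_b = 0 and no noise, change increases with sphere overlap
  el2 <- do.call(rbind, lapply(seq(0, 6, by = 1.5), function(off)
    rbind(make_electrode(atlas, "left", off, active_contact = 0L,
                         jitter_mm = 0, patient_id = sprintf("O%02d", off * 10)),
          make_electrode(atlas, "right", 12, active_contact = 0L,
                         jitter_mm = 0, patient_id = sprintf("O%02d", off * 10)))))
  cl2 <- simulate_outcomes(list(atlas = atlas, electrodes = el2, tractogram = tr), gt)
  vtas <- patient_vta_voxels(list(atlas = atlas, electrodes = el2,
                                  clinical = cl2))
  w <- grid_world_coords(atlas$volume)
  ctr <- gt$sweet_center
  sphere <- which((w[, 1] - ctr[1])^2 + (w[, 2] - ctr[2])^2 +
                    (w[, 3] - ctr[3])^2 <= gt$sweet_radius^2)
  of <- vapply(vtas, function(v) length(intersect(v, sphere)), numeric(1))
  ch <- (cl2$hama_pre - cl2$hama_post)[match(names(vtas), cl2$patient_id)]
  expect_true(all(diff(ch[order(of)]) >= -1e-12))
  expect_gt(cor(of, ch), 0.99)
})

test_that("cohort generation is deterministic with correct cardinalities", {
  co <- cached_cohort(12, "ventral_effect", seed = 7, n_fibers_per_bundle = 20)
  expect_identical(nrow(co$electrodes), 24L)
  expect_identical(nrow(co$clinical), 12L)
  expect_identical(co$tractogram$count, 40L)
  co2 <- generate_cohort(12, "ventral_effect", seed = 7,
                         n_fibers_per_bundle = 20)
  expect_identical(co$clinical, co2$clinical)
  expect_identical(co$electrodes, co2$electrodes)
  co3 <- generate_cohort(12, "ventral_effect", seed = 8,
                         n_fibers_per_bundle = 20)
  expect_false(identical(co$electrodes, co3$electrodes))
  expect_error(generate_cohort(4, "null", 1), "at least 8")
})

test_that("null scenario decouples outcomes from sweet-spot overlap", {
  co <- generate_cohort(400, "null", seed = 31, n_fibers_per_bundle = 20)
  gt <- co$ground_truth
  vtas <- patient_vta_voxels(co)
  w <- grid_world_coords(co$atlas$volume)
  ctr <- unlist(gt$sweet_center)
  sphere <- which((w[, 1] - ctr[1])^2 + (w[, 2] - ctr[2])^2 +
                    (w[, 3] - ctr[3])^2 <= gt$sweet_radius^2)
  of <- vapply(vtas, function(v) length(intersect(v, sphere)), numeric(1))
  ch <- clinical_outcome(co$clinical, "HAMA")
  expect_lt(abs(cor(ch, of)), 0.1)
})

test_that("ventral stimulation yields larger improvement than dorsal", {
  atlas <- make_toy_atlas()
  set.seed(11)
  tr <- make_tractogram(atlas, 60)
  gt <- list(sweet_center = unlist(atlas$geometry$stn_center$left) -
               2 * unlist(atlas$geometry$stn_axis$left),
             sweet_radius = 2.5, voxel_effect_weight = 8,
             tract_effect_weights = list(PFC = 0.5, SMC = -5), noise_sd = 0,
             fiber_bundle = attr(tr, "bundle"))
  mk <- function(off, tag) do.call(rbind, lapply(seq_len(10), function(i)
    rbind(make_electrode(atlas, "left", off, active_contact = 0L,
                         patient_id = paste0(tag, i)),
          make_electrode(atlas, "right", off, active_contact = 0L,
                         patient_id = paste0(tag, i)))))
  el <- rbind(mk(0.5, "V"), mk(5.5, "D"))
  cl <- simulate_outcomes(list(atlas = atlas, electrodes = el, tractogram = tr), gt)
  ch <- clinical_outcome(cl, "HAMA")
  expect_gt(mean(ch[grep("^V", names(ch))]), mean(ch[grep("^D", names(ch))]))
})
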