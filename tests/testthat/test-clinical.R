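test_that("improvement rate follows [(pre - post) / pre] * 100", {
  expect_equal(round(improvement_rate(7.50, 5.50), 2), 26.67)
  expect_equal(round(improvement_rate(10.00, 6.00), 2), 40.00)
  expect_equal(round(improvement_rate(725.85, 225.00), 2), 69.00)
  expect_equal(improvement_rate(12, 12), 0)
  expect_warning(out <- improvement_rate(c(0, 10), c(1, 5)), "pre == 0")
  expect_true(is.na(out[1]))
  expect_equal(out[2], 50)
  # algebraic reversal identity: rate(pre, post) = -rate(post, pre) * post/pre
  set.seed(2)
  pre <- runif(20, 1, 50); post <- runif(20, 1, 50)
  expect_equal(improvement_rate(pre, post),
               -improvement_rate(post, pre) * post / pre)
})

test_that("normality gate selects the right branch at realistic rates", {
  sel <- vapply(1:100, function(s) {
    set.seed(s)
    normality_gate(rnorm(56))$test_used
  }, character(1))
  expect_gte(mean(sel == "paired_t"), 0.9)
  sel2 <- vapply(1:100, function(s) {
    set.seed(s)
    normality_gate(rexp(56))$test_used
  }, character(1))
  expect_gte(mean(sel2 == "wilcoxon_signed_rank"), 0.9)
  expect_error(normality_gate(c(1, 2)), "at least 3")
  g <- normality_gate(rep(2, 10))
  expect_identical(g$test_used, "wilcoxon_signed_rank")
  expect_identical(g$flag, "constant_differences")
})

test_that("paired change test gates, tests and formats correctly", {
  # no change at all: statistic 0, p = 1
  r0 <- paired_change_test(c(5, 7, 9, 11), c(5, 7, 9, 11))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # constant non-zero differences fall to the Wilcoxon branch with the
  # exact enumeration p = 2/2^3
  r1 <- paired_change_test(c(10, 12, 14), c(6, 8, 10))
  expect_identical(r1$test_used, "wilcoxon_signed_rank")
  expect_equal(r1$p_value, 0.25)
  expect_match(r1$summary_pre, "12.00")
  # flipping pre and post flips the statistic sign
  set.seed(6)
  pre <- rnorm(30, 10); post <- pre - rnorm(30, 1)
  a <- paired_change_test(pre, post)
  b <- paired_change_test(post, pre)
  expect_equal(a$statistic, -b$statistic)
  expect_equal(a$p_value, b$p_value)
  expect_error(paired_change_test(1:4, 1:5), "mismatch")
})

test_that("signed-rank branch of the paired test matches enumeration", {
  set.seed(61)
  for (i in 1:10) {
    n <- sample(4:11, 1)
    pre <- rnorm(n, 10, 4); post <- rnorm(n, 9, 4)
    d <- pre - post
    r <- paired_change_test(pre, post)
    if (r$test_used == "wilcoxon_signed_rank")
      expect_equal(r$p_value, enum_signed_rank_p(d))
    else
      expect_equal(r$p_value, t.test(pre, post, paired = TRUE)$p.value)
  }
})

test_that("Spearman helper matches the rank-then-Pearson oracle", {
  set.seed(33)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    s <- spearman_cor(x, y)
    expect_equal(s$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
  }
  # perfect monotone decrease
  expect_equal(spearman_cor(1:10, 10:1)$rho, -1)
  # invariance under monotone transform
  x <- runif(25); y <- runif(25)
  expect_equal(spearman_cor(exp(3 * x), y)$rho, spearman_cor(x, y)$rho)
  # degenerate input flagged
  expect_identical(spearman_cor(rep(1, 8), rnorm(8))$flag, "zero_variance")
})

test_that("coordinate correlations recover the planted ventral gradient", {
  co <- cached_cohort(40, "ventral_effect", seed = 7, noise_sd = 0.5,
                      n_fibers_per_bundle = 60)
  coords <- active_contact_coordinates(co)
  tab <- coordinate_outcome_correlations(coords, co$clinical,
                                         scales = "HAMA")
  zrows <- tab[tab$axis == "z", ]
  expect_identical(nrow(zrows), 2L)
  expect_true(all(zrows$rho < 0)) # more ventral contact, more improvement
  # patient order must not matter
  perm <- sample(nrow(coords))
  tab2 <- coordinate_outcome_correlations(coords[perm, ], co$clinical,
                                          scales = "HAMA")
  z2 <- tab2[tab2$axis == "z", ]
  expect_equal(z2$rho[order(z2$hemisphere)], zrows$rho[order(zrows$hemisphere)])
})

test_that("overlap correlations link limbic overlap to improvement", {
  co <- cached_cohort(40, "ventral_effect", seed = 7, noise_sd = 0.5,
                      n_fibers_per_bundle = 60)
  ov <- cohort_overlap_table(co)
  tab <- overlap_outcome_correlations(ov, co$clinical, scales = "HAMA")
  left_limb <- tab[tab$hemisphere == "left" &
                     tab$region_label == "STN_left_limbic", ]
  expect_gt(left_limb$rho, 0)
  # rank statistic: invariant under monotone transform of the overlaps
  ov2 <- ov; ov2$overlap_mm3 <- sqrt(ov2$overlap_mm3)
  tab2 <- overlap_outcome_correlations(ov2, co$clinical, scales = "HAMA")
  expect_equal(tab2$rho, tab$rho)
  # zero-variance overlap column flagged
  ov3 <- ov; ov3$overlap_mm3 <- 1
  tab3 <- overlap_outcome_correlations(ov3, co$clinical, scales = "HAMA")
  expect_true(all(tab3$flag == "zero_variance"))
})

test_that("cohort summary table covers scales and parameters", {
  co <- cached_cohort(20, "tract_only", seed = 7, noise_sd = 0.3,
                      n_fibers_per_bundle = 60)
  tab <- summarize_cohort(co)
  expect_identical(nrow(tab), 8L) # 5 scales + 3 stimulation parameters
  expect_setequal(tab$type, c("scale", "parameter"))
  expect_true(all(is.finite(tab$p_value[tab$type == "scale"])))
  expect_identical(tab, summarize_cohort(co))
})
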