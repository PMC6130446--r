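test_that("rank-inverse-normal transform matches normal quantiles of ranks", {
  expect_equal(rank_inverse_normal(c(1, 2, 3)),
               qnorm(c(1 / 6, 3 / 6, 5 / 6)), tolerance = 1e-12)
  # rank invariance under monotone transforms; antisymmetry under reversal
  x <- c(0.3, 1.7, 0.9, 2.4, 0.1)
  expect_equal(rank_inverse_normal(x), rank_inverse_normal(exp(x)))
  expect_equal(rank_inverse_normal(-x), -rank_inverse_normal(x))
  expect_warning(z <- rank_inverse_normal(rep(2, 5)), "all values equal")
  expect_equal(z, rep(0, 5))
})

test_that("sequential SS decomposition matches a projection-based oracle", {
  # explicit design-matrix computation of sequential sums of squares
  set.seed(3)
  n <- 30; m <- 4
  po <- simulate_pair_outcomes(n_mz = n, n_dzsib = n, n_unrelated = n,
                               M = m, h2 = 0.25, c2 = 0.15, seed = 8)
  res <- rm_anova_ss(po, transform = FALSE)
  # oracle: incremental RSS reduction over nested QR fits
  y <- as.vector(po$outcomes)
  roi <- factor(rep(seq_len(m), each = 3 * n))
  env <- rep(po$environment, m); gen <- rep(po$genetics, m)
  rss <- function(X) sum(qr.resid(qr(X), y)^2)
  x0 <- matrix(1, length(y), 1)
  x1 <- model.matrix(~roi)
  x2 <- model.matrix(~roi + env)
  x3 <- model.matrix(~roi + env + gen)
  ss_roi <- rss(x0) - rss(x1)
  ss_env <- rss(x1) - rss(x2)
  ss_gen <- rss(x2) - rss(x3)
  ss_tot <- sum((y - mean(y))^2)
  expect_equal(res$h2, ss_gen / ss_tot, tolerance = 1e-10)
  expect_equal(res$c2, ss_env / ss_tot, tolerance = 1e-10)
  # SS conservation
  expect_equal(sum(res$ss$ss), res$ss_total, tolerance = 1e-8)
})

test_that("identical outcomes give zero factor SS and aliasing is honest", {
  po <- simulate_pair_outcomes(10, 10, 10, M = 3, h2 = 0.2, c2 = 0.1,
                               seed = 4)
  po0 <- po
  po0$outcomes[] <- 0.5
  suppressWarnings(res <- rm_anova_ss(po0))
  expect_equal(res$h2, 0)
  expect_equal(res$c2, 0)
  # without MZ pairs, genetics adds nothing beyond environment: SS exactly 0
  keep <- po$genetics != "MZ"
  po_nomz <- structure(list(outcomes = po$outcomes[keep, , drop = FALSE],
                            genetics = droplevels(po$genetics[keep]),
                            environment = po$environment[keep],
                            pair = po$pair[keep]),
                       class = "pair_outcomes")
  res2 <- rm_anova_ss(po_nomz)
  expect_true(res2$aliased)
  expect_equal(res2$h2, 0)
  expect_gt(res2$c2, 0)
})

test_that("permuted genetics labels give null-level genetics SS", {
  set.seed(12)
  hits <- 0
  for (i in 1:20) {
    po <- simulate_pair_outcomes(20, 20, 20, M = 5, h2 = 0, c2 = 0.2,
                                 seed = 100 + i)
    po$genetics[po$environment == "related"] <-
      sample(po$genetics[po$environment == "related"])
    res <- rm_anova_ss(po)
    hits <- hits + (is.na(res$p_genetics) || res$p_genetics > 0.05)
  }
  expect_gte(hits / 20, 0.9)
})

test_that("planted variance fractions are recovered with resampled matching", {
  est <- experiment_heritability(h2 = 0.2, c2 = 0.2, seed = 1,
                                 n_anovas = 60)
  expect_gt(est$h2, 0.1)
  expect_lt(est$h2, 0.3)
  expect_gt(est$c2, 0.1)
  expect_lt(est$c2, 0.3)
  expect_true(est$h2_ci[1] <= est$h2 && est$h2 <= est$h2_ci[2])
})

test_that("fractions are bounded and sum below one", {
  for (s in 1:5) {
    po <- simulate_pair_outcomes(15, 15, 60, M = 6,
                                 h2 = runif(1, 0, 0.4),
                                 c2 = runif(1, 0, 0.3), seed = s)
    est <- estimate_heritability(po, n_unrelated_match = 15, n_anovas = 10,
                                 seed = s)
    expect_gte(est$h2, 0); expect_lte(est$h2, 1)
    expect_gte(est$c2, 0); expect_lte(est$c2, 1)
    expect_lte(est$h2 + est$c2, 1)
    expect_lte(est$h2_ci[1], est$h2_ci[2])
  }
})

test_that("network-level estimates localize planted signal", {
  # plant genetics only in the first half of the ROIs: estimates on the
  # carrier subset exceed estimates on the null subset
  set.seed(9)
  po_sig <- simulate_pair_outcomes(30, 30, 80, M = 6, h2 = 0.3, c2 = 0.1,
                                   seed = 21)
  po_nul <- simulate_pair_outcomes(30, 30, 80, M = 6, h2 = 0, c2 = 0.1,
                                   seed = 21)
  po <- po_sig
  po$outcomes <- cbind(po_sig$outcomes[, 1:3], po_nul$outcomes[, 4:6])
  est_sig <- estimate_heritability(po, level = "network", roi_subset = 1:3,
                                   n_unrelated_match = 30, n_anovas = 20,
                                   seed = 2)
  est_nul <- estimate_heritability(po, level = "network", roi_subset = 4:6,
                                   n_unrelated_match = 30, n_anovas = 20,
                                   seed = 2)
  expect_gt(est_sig$h2, est_nul$h2)
  expect_lt(est_nul$h2, 0.05)
})

test_that("roiwise estimates correct p-values across ROIs", {
  po <- simulate_pair_outcomes(25, 25, 60, M = 4, h2 = 0.3, c2 = 0.1,
                               seed = 33)
  tab <- estimate_heritability_roiwise(po, n_unrelated_match = 25,
                                       n_anovas = 5, seed = 1)
  expect_equal(nrow(tab), 4L)
  expect_true(all(tab$p_adjusted >= tab$p, na.rm = TRUE))
  expect_true(all(tab$p_adjusted <= 1, na.rm = TRUE))
})

test_that("pipeline pair outcomes average ordered directions per pair", {
  bundle <- small_bundle(seed = 71, templates = c(mz = 2, sib = 3,
                                                  singleton = 3))
  scans <- lapply(bundle$scans, remove_autocorrelation, order = 1)
  pc <- run_all_comparisons(bundle$cohort, scans, rank = 8)
  po <- pair_outcomes(pc, bundle$cohort)
  # one row per unordered pair: 5 related + choose(11,2)-5 unrelated... the
  # related count is what matters here
  expect_equal(sum(po$environment == "related"), 5L)
  expect_equal(sum(po$genetics == "MZ"), 2L)
  # outcome equals the mean of the two directions for a related pair
  z <- bundle$cohort$zygosity[1, ]
  cmp <- pc$comparisons
  subj_of <- setNames(bundle$cohort$scans$subject_id,
                      bundle$cohort$scans$scan_id)
  dir_rows <- which(subj_of[cmp$model_scan] %in% c(z$subject_a, z$subject_b) &
                    subj_of[cmp$target_scan] %in% c(z$subject_a, z$subject_b) &
                    subj_of[cmp$model_scan] != subj_of[cmp$target_scan])
  i <- which(po$pair == connectokin:::pair_key(z$subject_a, z$subject_b))
  expect_equal(po$outcomes[i, ], colMeans(pc$r_mat[dir_rows, ]),
               ignore_attr = TRUE)
})
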