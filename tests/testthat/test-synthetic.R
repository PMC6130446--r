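test_that("pedigree instantiates templates with valid kinship bookkeeping", {
  # adult-sample shape: 70 one-descendant, 49 two-descendant and 10
  # three-descendant families give 198 subjects in 129 families, whose
  # within-family pairs count 10 MZ + 11 DZ + 58 non-twin sibling pairs
  spec <- synthetic_spec(templates = c(mz = 10, dz = 11, sib = 28,
                                       trio = 10, singleton = 70),
                         M = 6, frames = 40, seed = 1)
  ped <- make_pedigree(spec)
  expect_equal(nrow(ped$subjects), 198L)
  expect_equal(length(unique(ped$subjects$family_id)), 129L)
  expect_equal(table(ped$zygosity$class)[["MZ"]], 10L)
  expect_equal(table(ped$zygosity$class)[["DZ"]], 11L)
  expect_equal(table(ped$zygosity$class)[["sibling"]], 58L)  # 28 + 10*3
  fam <- setNames(ped$subjects$family_id, ped$subjects$subject_id)
  expect_true(all(fam[ped$zygosity$subject_a] == fam[ped$zygosity$subject_b]))
  # single singleton
  ped1 <- make_pedigree(synthetic_spec(templates = c(singleton = 1),
                                       M = 6, frames = 40))
  expect_equal(nrow(ped1$subjects), 1L)
  expect_equal(nrow(ped1$zygosity), 0L)
  expect_error(make_pedigree(synthetic_spec(templates = c(singleton = 0),
                                            M = 6, frames = 40)),
               "zero families|length")
})

test_that("planted precision structure follows the kinship coefficients", {
  # pure genetics: MZ twins receive identical precision matrices
  spec <- synthetic_spec(templates = c(mz = 2, dz = 2, singleton = 1),
                         M = 10, frames = 40, g2 = 1, c2 = 0, e2 = 0,
                         seed = 5)
  ped <- make_pedigree(spec)
  tr <- make_precisions(spec, ped)
  mz <- ped$zygosity[ped$zygosity$class == "MZ", ][1, ]
  expect_equal(tr$Theta[[mz$subject_a]], tr$Theta[[mz$subject_b]])
  # DZ pair under pure genetics: correlation of the genetic edge fields
  # (weights minus the shared base) ~ 0.5
  cors <- sapply(1:12, function(s) {
    spec_i <- synthetic_spec(templates = c(dz = 1, singleton = 1), M = 30,
                             frames = 40, g2 = 1, c2 = 0, e2 = 0, seed = s)
    ped_i <- make_pedigree(spec_i)
    tr_i <- make_precisions(spec_i, ped_i)
    dz <- ped_i$zygosity[1, ]
    sup <- tr_i$support
    cor(tr_i$Theta[[dz$subject_a]][sup] - tr_i$base,
        tr_i$Theta[[dz$subject_b]][sup] - tr_i$base)
  })
  expect_lt(abs(mean(cors) - 0.5), 0.05)
  # pure unique variance: cross-subject deviation correlation ~ 0, even for
  # siblings (they share nothing when g2 = c2 = 0)
  spec_e <- synthetic_spec(templates = c(sib = 15), M = 30, frames = 40,
                           g2 = 0, c2 = 0, e2 = 1, seed = 50)
  ped_e <- make_pedigree(spec_e)
  tr_e <- make_precisions(spec_e, ped_e)
  sup <- tr_e$support
  dev <- sapply(tr_e$Theta, function(th) th[sup])
  dev <- dev - rowMeans(dev)  # remove the shared base pattern
  prs <- combn(ncol(dev), 2)
  cors0 <- sapply(seq_len(min(100, ncol(prs))), function(j)
    cor(dev[, prs[1, j]], dev[, prs[2, j]]))
  expect_lt(abs(mean(cors0)), 0.05)
  # SPD by construction
  spec2 <- synthetic_spec(templates = c(sib = 2), M = 12, frames = 40,
                          seed = 9)
  ped2 <- make_pedigree(spec2)
  tr2 <- make_precisions(spec2, ped2)
  for (th in tr2$Theta) {
    ev <- eigen(th, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), 0.1 - 1e-8)
  }
})

test_that("sampled time series realize the planted covariance", {
  spec <- synthetic_spec(templates = c(singleton = 1), M = 20, frames = 5000,
                         ar_phi = 0, seed = 13)
  b <- simulate_cohort(spec)
  S <- cov(b$scans[[1]]$data)
  Sig <- solve(b$truth$Theta[[1]])
  expect_lt(norm(S - Sig, "F") / norm(Sig, "F"), 0.1)
  # ar_phi = 0: fitted AR(1) coefficient near zero
  ar1 <- mean(apply(b$scans[[1]]$data[, 1:5], 2, function(v)
    ar.yw(v, aic = FALSE, order.max = 1)$ar))
  expect_lt(abs(ar1), 0.05)
  # with smoothing on, prewhitening recovers the planted coefficient
  spec2 <- synthetic_spec(templates = c(singleton = 1), M = 5, frames = 2000,
                          ar_phi = 0.3, seed = 14)
  b2 <- simulate_cohort(spec2)
  ar2 <- mean(apply(b2$scans[[1]]$data, 2, function(v)
    ar.yw(v, aic = FALSE, order.max = 1)$ar))
  expect_lt(abs(ar2 - 0.3), 0.07)
})

test_that("end-to-end: fitting long scans recovers the true coefficients", {
  spec <- synthetic_spec(templates = c(singleton = 1), M = 30, frames = 5000,
                         seed = 7)
  b <- simulate_cohort(spec)
  tsw <- remove_autocorrelation(b$scans[[1]], 1)
  ct <- fit_connectotype(tsw)
  expect_lt(max(abs(coef(ct) - b$truth$B[[1]])), 0.05)
})

test_that("generation is deterministic in the spec seed", {
  spec <- synthetic_spec(templates = c(mz = 1, sib = 2, singleton = 2),
                         M = 8, frames = 50, seed = 77)
  b1 <- simulate_cohort(spec)
  b2 <- simulate_cohort(spec)
  expect_identical(b1$cohort$subjects, b2$cohort$subjects)
  expect_identical(b1$truth$Theta, b2$truth$Theta)
  expect_identical(lapply(b1$scans, `[[`, "data"),
                   lapply(b2$scans, `[[`, "data"))
  b3 <- simulate_cohort(synthetic_spec(templates = c(mz = 1, sib = 2,
                                                     singleton = 2),
                                       M = 8, frames = 50, seed = 78))
  expect_false(identical(b1$scans[[1]]$data, b3$scans[[1]]$data))
})

test_that("FD generator plants familial motion only when asked", {
  spec <- synthetic_spec(templates = c(sib = 8, singleton = 8), M = 6,
                         frames = 400, fd_median = 0.1, seed = 15)
  ped <- make_pedigree(spec)
  med_dist <- function(fd_list) {
    med <- sapply(fd_list, median)
    sib <- ped$zygosity
    fam_d <- abs(med[paste0(sib$subject_a, "_v1")] -
                 med[paste0(sib$subject_b, "_v1")])
    ids <- ped$subjects$subject_id
    set.seed(1)
    unrel_d <- replicate(200, {
      p <- sample(ids, 2)
      abs(med[paste0(p[1], "_v1")] - med[paste0(p[2], "_v1")])
    })
    c(fam = mean(fam_d), unrel = mean(unrel_d))
  }
  d0 <- med_dist(make_fd(spec, ped, family_shift = 0))
  d1 <- med_dist(make_fd(spec, ped, family_shift = 1))
  expect_lt(abs(d0["fam"] - d0["unrel"]), 0.035)   # null: no familial motion
  expect_lt(d1["fam"], d1["unrel"])                # planted familial motion
  # median 0.1 vs threshold 0.2: most frames survive
  fd <- make_fd(spec, ped)[[1]]
  expect_gt(mean(fd <= 0.2), 0.5)
})

test_that("synthetic bundle round-trips through the on-disk layout", {
  spec <- synthetic_spec(templates = c(sib = 2, singleton = 1), M = 6,
                         frames = 40, seed = 19)
  b <- simulate_cohort(spec, fd = TRUE, anatomy = TRUE)
  dir <- file.path(tempdir(), "synth_rt")
  write_synthetic_cohort(b, dir)
  co <- load_cohort(file.path(dir, "roster.tsv"),
                    file.path(dir, "zygosity.tsv"))
  expect_equal(sort(co$scans$scan_id), sort(b$cohort$scans$scan_id))
  parc <- load_parcellation(file.path(dir, "parcellation.tsv"))
  expect_equal(nrow(parc), 6L)
  id <- co$scans$scan_id[1]
  ts <- load_timeseries(file.path(dir, paste0(id, ".tsv")), parc, tr = spec$tr)
  expect_equal(ts$data, signif(b$scans[[id]]$data, 8), tolerance = 1e-7)
  fd <- load_fd(file.path(dir, paste0(id, "_fd.txt")))
  expect_equal(fd, b$fd[[id]], tolerance = 1e-7)
  unlink(dir, recursive = TRUE)
})
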