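#' Default desk-scale study design for synthetic experiments
#'
#' A scaled-down family mix in the style of the adult twin sample: MZ and DZ
#' twin-pair families, non-twin sibling pairs and trios, and singleton
#' families. Sixty families / 120 subjects at M = 30 ROIs and 150 frames —
#' large enough for planted kinship structure to be recoverable, small
#' enough for routine desk-scale reruns.
#'
#' @param seed master seed.
#' @param g2,c2 planted genetic / shared-environment edge-variance
#'   fractions (unique variance is the remainder).
#' @param M,frames problem size overrides.
#' @param templates family-template mix override.
#' @return a [synthetic_spec].
#' @export
study_spec <- function(seed = 1L, g2 = 0.4, c2 = 0.2, M = 30L,
                       frames = 150L,
                       templates = c(mz = 6, dz = 6, sib = 12, trio = 6,
                                     singleton = 30)) {
  synthetic_spec(templates = templates,
                 M = M, frames = frames, g2 = g2, c2 = c2,
                 e2 = 1 - g2 - c2, seed = seed)
}

# prewhiten every scan of a bundle (AR order matching what the generator
# planted: order 1 when ar_phi > 0)
prewhiten_scans <- function(bundle, order = NULL) {
  order <- order %||% (if (bundle$spec$ar_phi > 0) 1L else 0L)
  lapply(bundle$scans, remove_autocorrelation, order = order)
}

#' Fingerprinting experiment: is the self split-half always on top?
#'
#' Generates a cohort of unrelated subjects, fits one connectotype per scan
#' (split-half for the self comparison), predicts every scan from every
#' model, and asks for what fraction of scans the same-scan split-half
#' similarity exceeds every cross-subject similarity onto that scan.
#'
#' @param seed master seed.
#' @param n_subjects number of (singleton) subjects.
#' @param M,frames problem size.
#' @return list: `self_top_rate`, per-relationship mean similarities, and
#'   the underlying `pair_comparisons`.
#' @export
experiment_fingerprint <- function(seed = 1L, n_subjects = 50L, M = 30L,
                                   frames = 150L) {
  spec <- synthetic_spec(templates = c(singleton = n_subjects), M = M,
                         frames = frames, seed = seed)
  bundle <- simulate_cohort(spec)
  scans <- prewhiten_scans(bundle)
  pc <- run_all_comparisons(bundle$cohort, scans)
  cmp <- pc$comparisons
  self <- cmp[cmp$relationship == "self_same_scan", ]
  self_r <- stats::setNames(self$mean_r, self$target_scan)
  cross <- cmp[cmp$relationship == "unrelated", ]
  top <- vapply(names(self_r), function(sc)
    self_r[[sc]] > max(cmp$mean_r[cmp$target_scan == sc &
                                    cmp$model_scan != sc]),
    logical(1))
  group_means <- tapply(cmp$mean_r, cmp$relationship, mean)
  list(self_top_rate = mean(top), group_means = group_means,
       comparisons = pc)
}

#' Build classifier feature rows from a synthetic bundle
#'
#' Fits connectotypes (after prewhitening), computes all sibling-class
#' comparisons plus a seeded subsample of unrelated comparisons, and
#' returns the feature rows.
#'
#' @param bundle a [simulate_cohort()] bundle.
#' @param max_unrelated unrelated ordered comparisons kept in the pool.
#' @param seed seed for the unrelated subsample.
#' @param ... passed to [fit_connectotype()].
#' @return a `feature_rows` object.
#' @export
bundle_feature_rows <- function(bundle, max_unrelated = 2000L, seed = 1L,
                                ...) {
  scans <- prewhiten_scans(bundle)
  cmp <- enumerate_comparisons(bundle$cohort)
  keep_pos <- cmp$relationship %in% c("MZ", "DZ", "sibling")
  unrel_idx <- which(cmp$relationship == "unrelated")
  if (length(unrel_idx) > max_unrelated)
    unrel_idx <- local_seed(derive_seed(seed, "unrel_pool"),
                            sample(unrel_idx, max_unrelated))
  sub <- cmp[sort(c(which(keep_pos), unrel_idx)), ]
  pc <- run_all_comparisons(bundle$cohort, scans, comparisons = sub, ...)
  build_features(pc, bundle$cohort)
}

#' Sibling-classification experiment on a planted synthetic cohort
#'
#' End-to-end: simulate a family-structured cohort, fit connectotypes,
#' assemble features, and run the family-holdout SVM experiment with its
#' permutation null.
#'
#' @param seed master seed.
#' @param runs runs per condition (study scale 1,000; desk scale 200).
#' @param g2,c2 planted variance fractions.
#' @param top_p features kept after KS ranking (default ~M/3, mirroring the
#'   100-of-333 ratio used at full scale).
#' @param null include the permutation null.
#' @param M,frames problem size (the classification study default, M = 60 /
#'   400 frames, is the package's scaled-down analogue of a 333-ROI,
#'   hour-long acquisition; smaller settings are fine for quick work).
#' @param templates family-template mix (default: 60 families, trio-rich so
#'   held-out partitions carry a useful number of test pairs).
#' @return list: `result` (an `experiment_result`), the `bundle`, `rows`.
#' @export
experiment_classification <- function(seed = 1L, runs = 200L, g2 = 0.4,
                                      c2 = 0.2, top_p = NULL, null = TRUE,
                                      M = 60L, frames = 400L,
                                      templates = c(mz = 6, dz = 6, sib = 10,
                                                    trio = 10,
                                                    singleton = 28)) {
  spec <- study_spec(seed = derive_seed(seed, "cohort"), g2 = g2, c2 = c2,
                     M = M, frames = frames, templates = templates)
  bundle <- simulate_cohort(spec)
  rows <- bundle_feature_rows(bundle, seed = derive_seed(seed, "pool"))
  top_p <- top_p %||% max(10L, ceiling(ncol(rows$features) / 3))
  res <- run_experiment(rows, scheme = "family_holdout", runs = runs,
                        holdout_families = 3L, top_p = top_p,
                        seed = derive_seed(seed, "exp"), null = null)
  list(result = res, bundle = bundle, rows = rows)
}

#' Zygosity-ordering experiment across seeds
#'
#' Repeats the classification experiment over independent cohort seeds and
#' records, per seed, whether the MZ-stratum held-out accuracy is at least
#' the DZ-stratum accuracy — the qualitative signature of a genetic (not
#' merely environmental) contribution.
#'
#' @param seed master seed.
#' @param n_seeds independent cohorts.
#' @param runs runs per cohort (no null needed).
#' @param g2,c2 planted fractions.
#' @param M,frames problem size; the default (M = 40, 400 frames, twin-rich
#'   40-family cohorts) puts the MZ stratum near its accuracy ceiling, where
#'   the ordinal contrast is stable.
#' @return list: `mz_ge_dz_rate`, per-seed stratum accuracies.
#' @export
experiment_zygosity <- function(seed = 1L, n_seeds = 10L, runs = 40L,
                                g2 = 0.4, c2 = 0.2, M = 40L,
                                frames = 400L) {
  per_seed <- lapply(seq_len(n_seeds), function(i) {
    ex <- experiment_classification(seed = derive_seed(seed, paste0("zyg", i)),
                                    runs = runs, g2 = g2, c2 = c2,
                                    null = FALSE, M = M, frames = frames,
                                    templates = c(mz = 10, dz = 10, sib = 10,
                                                  singleton = 10))
    stratify_by_zygosity(ex$result)$accuracy
  })
  acc <- do.call(rbind, per_seed)
  ok <- !is.na(acc[, "MZ"]) & !is.na(acc[, "DZ"])
  list(mz_ge_dz_rate = mean(acc[ok, "MZ"] >= acc[ok, "DZ"]),
       accuracy = acc, n_informative = sum(ok))
}

#' Heritability parameter recovery on planted pair outcomes
#'
#' Plants known genetics / environment variance fractions in simulated pair
#' outcomes ([simulate_pair_outcomes()]) and estimates them back with the
#' resampled-matching ANOVA.
#'
#' @param h2,c2 planted fractions.
#' @param seed master seed.
#' @param n_anovas resampled ANOVAs (study scale 1,000; desk scale 200).
#' @param M outcome variables (ROIs).
#' @param n_pairs pairs per related group (and matched unrelated draw).
#' @return a `heritability_estimate`.
#' @export
experiment_heritability <- function(h2 = 0.2, c2 = 0.2, seed = 1L,
                                    n_anovas = 200L, M = 30L,
                                    n_pairs = 58L) {
  po <- simulate_pair_outcomes(n_mz = n_pairs, n_dzsib = n_pairs,
                               n_unrelated = 300L, M = M, h2 = h2, c2 = c2,
                               seed = derive_seed(seed, "po"))
  estimate_heritability(po, level = "whole_brain",
                        n_unrelated_match = n_pairs, n_anovas = n_anovas,
                        seed = derive_seed(seed, "est"))
}
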