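#' Build classifier feature rows from pair comparisons
#'
#' One row per retained ordered comparison; the features are the per-ROI
#' prediction-observation correlations. Self comparisons are excluded; MZ,
#' DZ and non-twin sibling comparisons form the positive class
#' (`sibling_class`), unrelated comparisons the negative class. Rows with
#' more than `max_invalid` invalid ROIs are dropped (logged); remaining
#' invalid entries are imputed with 0 (the null correlation).
#'
#' @param pc a `pair_comparisons` object from [run_all_comparisons()].
#' @param cohort the [cohort] the comparisons came from.
#' @param max_invalid maximum tolerated fraction of invalid ROIs per row.
#' @return object of class `feature_rows`: feature matrix plus per-row
#'   label, family ids, zygosity and scan ids.
#' @export
build_features <- function(pc, cohort, max_invalid = 0.2) {
  stopifnot(inherits(pc, "pair_comparisons"), inherits(cohort, "cohort"))
  cmp <- pc$comparisons
  keep <- cmp$relationship %in% c("MZ", "DZ", "sibling", "unrelated")
  cmp <- cmp[keep, , drop = FALSE]
  feats <- pc$r_mat[keep, , drop = FALSE]
  if (!any(cmp$relationship %in% c("MZ", "DZ", "sibling")))
    stop("no positive class: no sibling-class comparisons present")
  frac_bad <- rowMeans(is.na(feats))
  if (any(frac_bad > max_invalid)) {
    message("dropping ", sum(frac_bad > max_invalid),
            " comparison(s) with >", round(100 * max_invalid),
            "% invalid ROIs")
    cmp <- cmp[frac_bad <= max_invalid, , drop = FALSE]
    feats <- feats[frac_bad <= max_invalid, , drop = FALSE]
  }
  feats[is.na(feats)] <- 0
  subj_of <- stats::setNames(cohort$scans$subject_id, cohort$scans$scan_id)
  fam_of <- stats::setNames(cohort$subjects$family_id,
                            cohort$subjects$subject_id)
  sa <- unname(subj_of[cmp$model_scan]); sb <- unname(subj_of[cmp$target_scan])
  label <- factor(ifelse(cmp$relationship == "unrelated", "unrelated",
                         "sibling_class"),
                  levels = c("sibling_class", "unrelated"))
  structure(list(
    features = feats,
    label = label,
    zygosity = ifelse(cmp$relationship %in% c("MZ", "DZ"),
                      cmp$relationship,
                      ifelse(cmp$relationship == "sibling", "nontwin",
                             NA_character_)),
    family_a = unname(fam_of[sa]), family_b = unname(fam_of[sb]),
    subject_a = sa, subject_b = sb,
    model_scan = cmp$model_scan, target_scan = cmp$target_scan,
    scanpair_key = pair_key(cmp$model_scan, cmp$target_scan)),
    class = "feature_rows")
}

#' @export
print.feature_rows <- function(x, ...) {
  cat(sprintf("feature_rows: %d rows x %d features (%d sibling-class, %d unrelated)\n",
              nrow(x$features), ncol(x$features),
              sum(x$label == "sibling_class"), sum(x$label == "unrelated")))
  invisible(x)
}

subset_rows <- function(x, idx) {
  structure(list(features = x$features[idx, , drop = FALSE],
                 label = factor(x$label[idx],
                                levels = c("sibling_class", "unrelated")),
                 zygosity = x$zygosity[idx],
                 family_a = x$family_a[idx], family_b = x$family_b[idx],
                 subject_a = x$subject_a[idx], subject_b = x$subject_b[idx],
                 model_scan = x$model_scan[idx],
                 target_scan = x$target_scan[idx],
                 scanpair_key = x$scanpair_key[idx]),
            class = "feature_rows")
}

#' Build anatomy-derived classifier feature rows
#'
#' Per ordered pair and ROI, the signed difference of the (optionally
#' brain-size-adjusted) anatomical measure between the two subjects
#' (model-subject minus target-subject; the sign of the difference is kept).
#' `adjust = "normalize"` divides each subject's raw measures by head size
#' before differencing; `adjust = "regress"` removes head size from each
#' ROI's measure by least squares across subjects.
#'
#' @param cohort a [cohort] with an `anatomical` table.
#' @param comparisons rows from [enumerate_comparisons()] (defaults to all
#'   non-self comparisons).
#' @param measure `"thickness"` or `"sulcal_depth"`.
#' @param adjust `"none"`, `"normalize"` or `"regress"`.
#' @return a `feature_rows` object.
#' @export
anatomical_features <- function(cohort, comparisons = NULL,
                                measure = c("thickness", "sulcal_depth"),
                                adjust = c("none", "normalize", "regress")) {
  measure <- match.arg(measure); adjust <- match.arg(adjust)
  anat <- cohort$anatomical
  if (is.null(anat)) stop("cohort has no anatomical table")
  cmp <- comparisons %||% {
    e <- enumerate_comparisons(cohort)
    e[!(e$relationship %in% c("self_same_scan", "self_other_scan")), ]
  }
  cmp <- cmp[cmp$relationship %in% c("MZ", "DZ", "sibling", "unrelated"), ,
             drop = FALSE]
  rois <- sort(unique(anat$roi_id))
  wide <- matrix(NA_real_, length(unique(anat$subject_id)), length(rois),
                 dimnames = list(unique(anat$subject_id), NULL))
  wide[cbind(match(anat$subject_id, rownames(wide)),
             match(anat$roi_id, rois))] <- anat[[measure]]
  head_size <- as.vector(tapply(anat$head_size, anat$subject_id,
                                `[`, 1)[rownames(wide)])
  if (adjust == "normalize") {
    wide <- wide / head_size
  } else if (adjust == "regress") {
    for (j in seq_len(ncol(wide))) {
      fit <- stats::lm.fit(cbind(1, head_size), wide[, j])
      wide[, j] <- fit$residuals
    }
  }
  subj_of <- stats::setNames(cohort$scans$subject_id, cohort$scans$scan_id)
  sa <- unname(subj_of[cmp$model_scan]); sb <- unname(subj_of[cmp$target_scan])
  known <- sa %in% rownames(wide) & sb %in% rownames(wide)
  if (!all(known)) {
    message("dropping ", sum(!known), " pair(s) without anatomical measures")
    cmp <- cmp[known, , drop = FALSE]; sa <- sa[known]; sb <- sb[known]
  }
  feats <- wide[sa, , drop = FALSE] - wide[sb, , drop = FALSE]
  bad <- rowSums(is.na(feats)) > 0
  if (any(bad)) {
    message("dropping ", sum(bad), " pair(s) with missing ROI measures")
    cmp <- cmp[!bad, , drop = FALSE]; feats <- feats[!bad, , drop = FALSE]
    sa <- sa[!bad]; sb <- sb[!bad]
  }
  rownames(feats) <- NULL
  fam_of <- stats::setNames(cohort$subjects$family_id,
                            cohort$subjects$subject_id)
  structure(list(
    features = feats,
    label = factor(ifelse(cmp$relationship == "unrelated", "unrelated",
                          "sibling_class"),
                   levels = c("sibling_class", "unrelated")),
    zygosity = ifelse(cmp$relationship %in% c("MZ", "DZ"), cmp$relationship,
                      ifelse(cmp$relationship == "sibling", "nontwin",
                             NA_character_)),
    family_a = unname(fam_of[sa]), family_b = unname(fam_of[sb]),
    subject_a = sa, subject_b = sb,
    model_scan = cmp$model_scan, target_scan = cmp$target_scan,
    scanpair_key = pair_key(cmp$model_scan, cmp$target_scan)),
    class = "feature_rows")
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Maximum absolute difference between the two empirical CDFs (ties
#' handled exactly). Distribution-free, hence suitable for ranking features
#' without assumptions about their distributions.
#'
#' @param a,b numeric samples.
#' @return the KS statistic D in `[0, 1]`.
#' @export
ks_statistic <- function(a, b) {
  na <- length(a); nb <- length(b)
  stopifnot(na > 0, nb > 0)
  w <- c(a, b)
  ord <- order(w)
  steps <- cumsum(ifelse(ord <= na, 1 / na, -1 / nb))
  ws <- w[ord]
  at_jump <- c(ws[-length(ws)] != ws[-1], TRUE)
  max(abs(steps[at_jump]))
}

#' Rank features by between-class KS statistic
#'
#' Features (ROIs) are sorted by how different their sibling-class and
#' unrelated distributions are, measured by the two-sample KS statistic.
#' Only training rows may be supplied: ranking is part of the training
#' pipeline and must never see held-out rows. Features constant in both
#' classes get D = 0 and rank last.
#'
#' @param rows a `feature_rows` object (training rows only).
#' @return data.frame with `feature` (column index) and `ks`, sorted by
#'   decreasing D.
#' @export
rank_features_ks <- function(rows) {
  stopifnot(inherits(rows, "feature_rows"))
  y <- rows$label
  if (min(table(y)) < 2) stop("need at least 2 rows per class to rank")
  pos <- rows$features[y == "sibling_class", , drop = FALSE]
  neg <- rows$features[y == "unrelated", , drop = FALSE]
  d <- vapply(seq_len(ncol(pos)),
              function(j) ks_statistic(pos[, j], neg[, j]), numeric(1))
  out <- data.frame(feature = order(d, decreasing = TRUE),
                    ks = sort(d, decreasing = TRUE))
  out
}

#' Train a linear SVM tuned by leave-one-out cross-validation
#'
#' Features are standardized with parameters learned on the training rows
#' only; the regularization constant is chosen from a log-spaced grid by
#' leave-one-out CV accuracy (libsvm's internal cross-validation), with ties
#' broken toward the smallest constant, i.e. the strongest regularization.
#' The grid tops out at cost = 1 because, for standardized features at these
#' sample sizes, larger costs only approach the hard-margin solution while
#' the quadratic program becomes ill-conditioned.
#'
#' @param x numeric training matrix (rows x selected features).
#' @param y two-level factor of labels.
#' @param cost_grid candidate regularization constants.
#' @param loocv logical; tune by loocv (TRUE) or fix `cost_grid[1]`.
#' @return object of class `tuned_svm` with the fitted model, the scaling
#'   parameters, the chosen cost and its loocv accuracy.
#' @export
train_tuned_svm <- function(x, y, cost_grid = 10^seq(-3, 0), loocv = TRUE) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("training set contains a single class")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale(x, ctr, scl)
  cost_grid <- sort(cost_grid)
  acc <- rep(NA_real_, length(cost_grid))
  if (loocv && length(cost_grid) > 1) {
    for (i in seq_along(cost_grid)) {
      fit <- e1071::svm(xs, y, kernel = "linear", cost = cost_grid[i],
                        scale = FALSE, cross = nrow(xs))
      acc[i] <- fit$tot.accuracy / 100
    }
    best <- which.max(acc)  # ascending grid: first max = smallest cost
  } else best <- 1L
  model <- e1071::svm(xs, y, kernel = "linear", cost = cost_grid[best],
                      scale = FALSE)
  structure(list(model = model, center = ctr, scale = scl,
                 cost = cost_grid[best], loocv_accuracy = acc[best],
                 grid_accuracy = stats::setNames(acc, cost_grid)),
            class = "tuned_svm")
}

#' @export
predict.tuned_svm <- function(object, newdata, ...) {
  xs <- scale(as.matrix(newdata), object$center, object$scale)
  predict(object$model, xs)
}

#' @export
print.tuned_svm <- function(x, ...) {
  cat(sprintf("tuned_svm: linear kernel, cost %.3g (loocv accuracy %.3f)\n",
              x$cost, x$loocv_accuracy))
  invisible(x)
}

# one train/evaluate pass; returns metrics, selected features and per-test-row
# correctness (for zygosity stratification)
svm_run_once <- function(train, test, top_p, cost_grid, permute_labels = FALSE) {
  y_tr <- train$label
  if (permute_labels) y_tr <- sample(y_tr)
  ranking <- rank_features_ks(subset_rows_with_labels(train, y_tr))
  sel <- ranking$feature[seq_len(min(top_p, nrow(ranking)))]
  clf <- train_tuned_svm(train$features[, sel, drop = FALSE], y_tr, cost_grid)
  pred <- predict(clf, test$features[, sel, drop = FALSE])
  truth <- test$label
  correct <- pred == truth
  pos <- truth == "sibling_class"
  list(accuracy = mean(correct),
       sensitivity = if (any(pos)) mean(correct[pos]) else NA_real_,
       specificity = if (any(!pos)) mean(correct[!pos]) else NA_real_,
       cost = clf$cost, selected = sel,
       test_zygosity = test$zygosity, test_correct = correct,
       test_positive = pos)
}

subset_rows_with_labels <- function(rows, labels) {
  rows$label <- labels
  rows
}

#' Run a sibling-classification experiment with permutation nulls
#'
#' On each run a family-aware partition is drawn, features are ranked by KS
#' statistic on the training rows only, unrelated training rows are
#' undersampled to match the positive count, a loocv-tuned linear SVM is
#' trained, and held-out accuracy / sensitivity / specificity are recorded.
#' The permutation null repeats the identical machinery with class labels
#' randomized within the training partition.
#'
#' Schemes: `"family_holdout"` reserves whole families (both directions of
#' any held-out pair leave together, and families containing twins never
#' enter training); `"scanpair_holdout"` reserves individual sibling
#' scan-pairs (longitudinal-style: the same siblings at another timepoint
#' may remain in training).
#'
#' @param rows a `feature_rows` object.
#' @param scheme partitioning scheme (see Details).
#' @param runs number of runs (the study-scale figure is 1,000; scale down
#'   for quick work).
#' @param holdout_families families (or scan-pairs) reserved per run.
#' @param top_p number of top-ranked features kept (clipped to M with a
#'   warning when larger).
#' @param cost_grid SVM regularization grid.
#' @param seed master seed.
#' @param null logical; also run the permutation null.
#' @return object of class `experiment_result`: per-run metric data.frames
#'   (`runs`, `null_runs`), percentile summaries, a per-feature selection
#'   tally, and per-run stratification bookkeeping.
#' @export
run_experiment <- function(rows, scheme = c("family_holdout",
                                            "scanpair_holdout"),
                           runs = 200L, holdout_families = 3L, top_p = 100L,
                           cost_grid = 10^seq(-3, 0), seed = 1L,
                           null = TRUE) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(rows, "feature_rows"))
  m <- ncol(rows$features)
  if (top_p > m) {
    warning(sprintf("top_p (%d) exceeds feature count (%d); clipped", top_p, m))
    top_p <- m
  }
  pos_idx <- which(rows$label == "sibling_class")
  neg_idx <- which(rows$label == "unrelated")
  if (!length(pos_idx)) stop("no positive class rows")
  twin_fams <- unique(rows$family_a[pos_idx][rows$zygosity[pos_idx] %in%
                                               c("MZ", "DZ")])
  sib_fams <- unique(rows$family_a[pos_idx])
  if (scheme == "family_holdout" && length(sib_fams) <= holdout_families)
    stop("fewer sibling families than holdout_families")
  one_run <- function(run_seed, permute) {
    set.seed(run_seed)
    if (scheme == "family_holdout") {
      hold <- sample(sib_fams, holdout_families)
      te_pos <- pos_idx[rows$family_a[pos_idx] %in% hold]
      tr_pos <- pos_idx[!(rows$family_a[pos_idx] %in% hold) &
                          !(rows$family_a[pos_idx] %in% twin_fams)]
      neg_ok_train <- neg_idx[!(rows$family_a[neg_idx] %in% c(hold, twin_fams)) &
                                !(rows$family_b[neg_idx] %in% c(hold, twin_fams))]
      tr_neg <- sample(neg_ok_train, min(length(tr_pos), length(neg_ok_train)))
      te_neg_pool <- neg_idx[rows$family_a[neg_idx] %in% hold &
                               rows$family_b[neg_idx] %in% hold]
      if (length(te_neg_pool) < length(te_pos))
        te_neg_pool <- setdiff(neg_idx[rows$family_a[neg_idx] %in% hold |
                                         rows$family_b[neg_idx] %in% hold],
                               tr_neg)
      te_neg <- sample(te_neg_pool, min(length(te_pos), length(te_neg_pool)))
    } else {
      units <- unique(rows$scanpair_key[pos_idx])
      if (length(units) <= holdout_families)
        stop("fewer sibling scan-pairs than holdout units")
      hold <- sample(units, holdout_families)
      te_pos <- pos_idx[rows$scanpair_key[pos_idx] %in% hold]
      tr_pos <- pos_idx[!(rows$scanpair_key[pos_idx] %in% hold)]
      tr_neg <- sample(neg_idx, min(length(tr_pos), length(neg_idx)))
      te_neg <- sample(setdiff(neg_idx, tr_neg),
                       min(length(te_pos), length(neg_idx) - length(tr_neg)))
    }
    train_idx <- c(tr_pos, tr_neg); test_idx <- c(te_pos, te_neg)
    stopifnot(length(intersect(train_idx, test_idx)) == 0)
    if (scheme == "family_holdout")
      stopifnot(!any(rows$family_a[train_idx] %in% hold),
                !any(rows$family_b[train_idx] %in% hold))
    svm_run_once(subset_rows(rows, train_idx), subset_rows(rows, test_idx),
                 top_p, cost_grid, permute_labels = permute)
  }
  collect <- function(permute, tag) {
    res <- lapply(seq_len(runs), function(r)
      one_run(derive_seed(seed, paste0(tag, r)), permute))
    df <- data.frame(run = seq_len(runs),
                     accuracy = vapply(res, `[[`, 0, "accuracy"),
                     sensitivity = vapply(res, `[[`, 0, "sensitivity"),
                     specificity = vapply(res, `[[`, 0, "specificity"),
                     cost = vapply(res, `[[`, 0, "cost"))
    list(df = df, detail = res)
  }
  obs <- collect(FALSE, "run")
  nul <- if (null) collect(TRUE, "null") else NULL
  tally <- tabulate(unlist(lapply(obs$detail, `[[`, "selected")), nbins = m)
  structure(list(runs = obs$df, null_runs = nul$df,
                 detail = obs$detail, null_detail = nul$detail,
                 feature_tally = tally, scheme = scheme, top_p = top_p,
                 n_runs = runs, seed = seed,
                 summary = metric_percentiles(obs$df$accuracy),
                 null_summary = if (null) metric_percentiles(nul$df$accuracy)),
            class = "experiment_result")
}

metric_percentiles <- function(x) {
  c(mean = mean(x),
    stats::quantile(x, c(0.025, 0.25, 0.75, 0.975), names = TRUE),
    sd = stats::sd(x))
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("experiment_result (%s, %d runs, top %d features)\n",
              x$scheme, x$n_runs, x$top_p))
  cat(sprintf("  accuracy: mean %.3f [2.5%%: %.3f, 97.5%%: %.3f]\n",
              x$summary["mean"], x$summary["2.5%"], x$summary["97.5%"]))
  cat(sprintf("  sensitivity %.3f, specificity %.3f\n",
              mean(x$runs$sensitivity, na.rm = TRUE),
              mean(x$runs$specificity, na.rm = TRUE)))
  if (!is.null(x$null_runs))
    cat(sprintf("  null accuracy: mean %.3f (sd %.3f)\n",
                x$null_summary["mean"], x$null_summary["sd"]))
  invisible(x)
}

#' Stratify held-out positive-class accuracy by zygosity
#'
#' Per run, the held-out sibling-class rows are split by pair zygosity (MZ,
#' DZ, non-twin) and per-stratum accuracy recorded where the stratum is
#' non-empty; strata that never appear are reported as missing rather than
#' zero. A rank-sum test and Cohen's d compare the MZ and DZ run-wise
#' accuracy distributions.
#'
#' @param result an `experiment_result` from [run_experiment()].
#' @return list with per-stratum mean accuracies (`MZ`, `DZ`, `nontwin`),
#'   run-wise accuracy vectors, and the MZ-vs-DZ `wilcox_p` and `cohens_d`.
#' @export
stratify_by_zygosity <- function(result) {
  stopifnot(inherits(result, "experiment_result"))
  strata <- c("MZ", "DZ", "nontwin")
  per_run <- lapply(strata, function(s) {
    v <- vapply(result$detail, function(d) {
      sel <- d$test_positive & !is.na(d$test_zygosity) & d$test_zygosity == s
      if (any(sel)) mean(d$test_correct[sel]) else NA_real_
    }, numeric(1))
    v[!is.na(v)]
  })
  names(per_run) <- strata
  means <- vapply(per_run, function(v) if (length(v)) mean(v) else NA_real_,
                  numeric(1))
  wp <- dd <- NA_real_
  if (length(per_run$MZ) > 1 && length(per_run$DZ) > 1) {
    wp <- suppressWarnings(stats::wilcox.test(per_run$MZ, per_run$DZ)$p.value)
    dd <- cohen_d(per_run$MZ, per_run$DZ)
  }
  list(accuracy = means, per_run = per_run, wilcox_p = wp, cohens_d = dd)
}

#' Train in one dataset, predict siblings in another
#'
#' Feature ranking, scaling and loocv tuning use the training dataset only;
#' per run, all training sibling rows plus an equal number of resampled
#' unrelated rows form the training set, and all test-dataset sibling rows
#' plus an equal number of resampled unrelated test rows are evaluated. The
#' two datasets must share a parcellation (features align by ROI id).
#'
#' @param train_rows,test_rows `feature_rows` from the two cohorts.
#' @param runs number of resampling runs.
#' @param top_p features kept after KS ranking.
#' @param cost_grid SVM regularization grid.
#' @param seed master seed.
#' @param null logical; include the permuted-label null.
#' @return an `experiment_result`.
#' @export
cross_dataset_experiment <- function(train_rows, test_rows, runs = 200L,
                                     top_p = 100L,
                                     cost_grid = 10^seq(-3, 0), seed = 1L,
                                     null = TRUE) {
  stopifnot(inherits(train_rows, "feature_rows"),
            inherits(test_rows, "feature_rows"))
  if (ncol(train_rows$features) != ncol(test_rows$features))
    stop(sprintf("parcellation mismatch: %d vs %d features",
                 ncol(train_rows$features), ncol(test_rows$features)))
  m <- ncol(train_rows$features)
  if (top_p > m) {
    warning("top_p clipped to feature count")
    top_p <- m
  }
  tr_pos <- which(train_rows$label == "sibling_class")
  tr_neg <- which(train_rows$label == "unrelated")
  te_pos <- which(test_rows$label == "sibling_class")
  te_neg <- which(test_rows$label == "unrelated")
  one <- function(run_seed, permute) {
    set.seed(run_seed)
    tr <- c(tr_pos, sample(tr_neg, min(length(tr_pos), length(tr_neg))))
    te <- c(te_pos, sample(te_neg, min(length(te_pos), length(te_neg))))
    svm_run_once(subset_rows(train_rows, tr), subset_rows(test_rows, te),
                 top_p, cost_grid, permute_labels = permute)
  }
  collect <- function(permute, tag) {
    res <- lapply(seq_len(runs), function(r)
      one(derive_seed(seed, paste0(tag, r)), permute))
    list(df = data.frame(run = seq_len(runs),
                         accuracy = vapply(res, `[[`, 0, "accuracy"),
                         sensitivity = vapply(res, `[[`, 0, "sensitivity"),
                         specificity = vapply(res, `[[`, 0, "specificity"),
                         cost = vapply(res, `[[`, 0, "cost")),
         detail = res)
  }
  obs <- collect(FALSE, "xrun")
  nul <- if (null) collect(TRUE, "xnull") else NULL
  structure(list(runs = obs$df, null_runs = nul$df, detail = obs$detail,
                 null_detail = nul$detail,
                 feature_tally = tabulate(unlist(lapply(obs$detail, `[[`,
                                                        "selected")),
                                          nbins = m),
                 scheme = "cross_dataset", top_p = top_p, n_runs = runs,
                 seed = seed, summary = metric_percentiles(obs$df$accuracy),
                 null_summary = if (null) metric_percentiles(nul$df$accuracy)),
            class = "experiment_result")
}

#' Check whether selected features are confounded with ROI size
#'
#' Compares the sizes (vertex counts) of the ROIs selected by a classifier
#' experiment against the sizes of the excluded ROIs with a two-sample
#' Kolmogorov-Smirnov test. A small statistic / large p-value indicates the
#' classifier is not simply picking large (or small) parcels.
#'
#' @param result an `experiment_result`.
#' @param parcellation a [parcellation] aligned with the feature columns.
#' @param top_n how many most-frequently-selected ROIs count as "selected"
#'   (default: the experiment's `top_p`).
#' @return list with `ks` (the D statistic), `p`, and the two size vectors.
#' @export
roi_size_confound_check <- function(result, parcellation, top_n = NULL) {
  stopifnot(inherits(result, "experiment_result"),
            inherits(parcellation, "parcellation"),
            nrow(parcellation) == length(result$feature_tally))
  top_n <- top_n %||% result$top_p
  sel <- order(result$feature_tally, decreasing = TRUE)[seq_len(top_n)]
  sizes_sel <- parcellation$n_vertices[sel]
  sizes_exc <- parcellation$n_vertices[-sel]
  kt <- suppressWarnings(stats::ks.test(sizes_sel, sizes_exc))
  list(ks = unname(kt$statistic), p = kt$p.value,
       selected_sizes = sizes_sel, excluded_sizes = sizes_exc)
}

#' Run one classification experiment per functional network
#'
#' Each network's classifier uses all (and only) that network's ROIs as
#' features, with no KS pre-selection within the network. Networks with
#' fewer than 2 ROIs are skipped with a message.
#'
#' @param rows a `feature_rows` object.
#' @param parcellation a [parcellation] table aligned with the feature
#'   columns.
#' @param runs,holdout_families,cost_grid,seed,scheme,null passed to
#'   [run_experiment()].
#' @return named list of `experiment_result`, one per usable network.
#' @export
per_network_experiment <- function(rows, parcellation, runs = 100L,
                                   scheme = "family_holdout",
                                   holdout_families = 3L,
                                   cost_grid = 10^seq(-3, 0), seed = 1L,
                                   null = FALSE) {
  stopifnot(inherits(parcellation, "parcellation"),
            nrow(parcellation) == ncol(rows$features))
  nets <- setdiff(unique(parcellation$network), character(0))
  out <- list()
  for (nw in nets) {
    idx <- parcellation$roi_id[parcellation$network == nw]
    if (length(idx) < 2) {
      message("skipping network '", nw, "' with <2 ROIs")
      next
    }
    sub <- rows
    sub$features <- rows$features[, idx, drop = FALSE]
    out[[nw]] <- run_experiment(sub, scheme = scheme, runs = runs,
                                holdout_families = holdout_families,
                                top_p = length(idx), cost_grid = cost_grid,
                                seed = derive_seed(seed, nw), null = null)
  }
  out
}
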