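#' Enumerate all ordered scan-pair comparisons of a cohort
#'
#' Every ordered, self-inclusive pair of scans (S x S for S scans) is listed
#' and labeled by the relationship between the subjects the two scans come
#' from: `self_same_scan`, `self_other_scan`, `MZ`, `DZ`, `sibling`, or
#' `unrelated`. Comparisons are directional records: (A -> B) and (B -> A)
#' are distinct rows.
#'
#' @param cohort a validated [cohort].
#' @return data.frame with columns `model_scan`, `target_scan`,
#'   `relationship`; relationship group counts are attached as attribute
#'   `"counts"` (they always sum to S^2).
#' @export
enumerate_comparisons <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  scans <- cohort$scans
  s <- nrow(scans)
  subj_of <- stats::setNames(scans$subject_id, scans$scan_id)
  rel_lookup <- pair_relationships(cohort)
  grid <- expand.grid(model_scan = scans$scan_id, target_scan = scans$scan_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  a <- subj_of[grid$model_scan]; b <- subj_of[grid$target_scan]
  rel <- ifelse(grid$model_scan == grid$target_scan, "self_same_scan",
         ifelse(a == b, "self_other_scan",
                unname(rel_lookup[pair_key(a, b)])))
  rel[is.na(rel)] <- "unrelated"
  grid$relationship <- rel
  counts <- table(factor(rel, levels = c("self_same_scan", "self_other_scan",
                                         "MZ", "DZ", "sibling", "unrelated")))
  stopifnot(sum(counts) == s^2)
  attr(grid, "counts") <- counts
  grid
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

# named vector: unordered subject-pair key -> zygosity class
pair_relationships <- function(cohort) {
  z <- cohort$zygosity
  if (!nrow(z)) return(stats::setNames(character(), character()))
  stats::setNames(z$class, pair_key(z$subject_a, z$subject_b))
}

#' Split a scan's retained frames into disjoint fit / evaluation halves
#'
#' Contiguous first/second-half split of the retained frames: the first
#' `floor(n/2)` frames fit the model, the remainder (the extra frame, when n
#' is odd) evaluate it. Used for same-scan self comparisons so the model
#' always predicts fresh data.
#'
#' @param ts a [scan_timeseries].
#' @return list of two [scan_timeseries]: `fit` and `eval`.
#' @export
split_half_self <- function(ts) {
  stopifnot(inherits(ts, "scan_timeseries"))
  x <- retained(ts)
  n <- nrow(x)
  if (n < 20L) stop("need at least 20 retained frames for a split-half")
  h <- n %/% 2L
  list(fit = scan_timeseries(x[seq_len(h), , drop = FALSE], ts$tr,
                             paste0(ts$scan_id, "_fit")),
       eval = scan_timeseries(x[(h + 1L):n, , drop = FALSE], ts$tr,
                              paste0(ts$scan_id, "_eval")))
}

#' Run every ordered scan-pair comparison of a cohort
#'
#' One connectotype is fit per scan on its full retained frames; for the
#' same-scan self comparison the scan is split in half, the first half fits
#' a dedicated model and the second half is predicted (fresh data). All other
#' comparisons predict the full target scan with the model scan's full-frame
#' model. Each comparison yields the per-ROI prediction-observation
#' correlations, their mean, and the Fisher z of the mean.
#'
#' @param cohort a [cohort].
#' @param scans named list of preprocessed [scan_timeseries], keyed by
#'   `scan_id`. Scans missing from the list (e.g. excluded for motion) are
#'   skipped and their comparisons dropped with a message.
#' @param comparisons optional subset of rows from [enumerate_comparisons()]
#'   to evaluate (default: all).
#' @param ... passed to [fit_connectotype()] (e.g. `rank_grid`, `cv_folds`,
#'   `rank`).
#' @return object of class `pair_comparisons`: data.frame `comparisons` with
#'   `model_scan`, `target_scan`, `relationship`, `mean_r`, `z_mean`,
#'   `n_valid_rois`, plus matrix `r_mat` (comparisons x M per-ROI
#'   correlations) and the fitted `models`.
#' @export
run_all_comparisons <- function(cohort, scans, comparisons = NULL, ...) {
  stopifnot(inherits(cohort, "cohort"))
  cmp <- comparisons %||% enumerate_comparisons(cohort)
  avail <- intersect(cohort$scans$scan_id, names(scans))
  missing <- setdiff(unique(c(cmp$model_scan, cmp$target_scan)), avail)
  if (length(missing)) {
    message("skipping ", length(missing), " scan(s) without usable data: ",
            paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ...")
    cmp <- cmp[cmp$model_scan %in% avail & cmp$target_scan %in% avail, ]
  }
  models <- lapply(scans[avail], fit_connectotype, ...)
  halves <- list()
  m <- models[[1]]$M
  r_mat <- matrix(NA_real_, nrow(cmp), m)
  mean_r <- numeric(nrow(cmp)); n_valid <- integer(nrow(cmp))
  for (k in seq_len(nrow(cmp))) {
    ms <- cmp$model_scan[k]; tg <- cmp$target_scan[k]
    if (cmp$relationship[k] == "self_same_scan") {
      if (is.null(halves[[ms]]))
        halves[[ms]] <- split_half_self(scans[[ms]])
      mod <- fit_connectotype(halves[[ms]]$fit, ...)
      obs <- retained(halves[[ms]]$eval)
    } else {
      mod <- models[[ms]]
      obs <- retained(scans[[tg]])
    }
    prof <- similarity(predict(mod, obs), obs)
    r_mat[k, ] <- prof$r_per_roi
    mean_r[k] <- prof$mean_r
    n_valid[k] <- sum(prof$valid_mask)
  }
  cmp$mean_r <- mean_r
  cmp$z_mean <- fisher_z(pmin(pmax(mean_r, -1), 1))
  cmp$n_valid_rois <- n_valid
  structure(list(comparisons = cmp, r_mat = r_mat, models = models),
            class = "pair_comparisons")
}

#' @export
print.pair_comparisons <- function(x, ...) {
  cat(sprintf("pair_comparisons: %d ordered comparisons, %d ROIs\n",
              nrow(x$comparisons), ncol(x$r_mat)))
  agg <- stats::aggregate(mean_r ~ relationship, x$comparisons, mean)
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Contrast two groups of comparisons on Fisher-z similarity
#'
#' Welch (unequal-variance) two-sample t test on the Fisher-z transformed
#' mean correlations of two relationship groups, with Cohen's d.
#'
#' @param z_a,z_b numeric vectors of z-transformed mean correlations.
#' @return list with `t`, `df`, `p`, `cohens_d`, group means.
#' @export
group_contrast <- function(z_a, z_b) {
  if (length(z_a) < 2 || length(z_b) < 2)
    stop("each group needs at least 2 comparisons")
  if (stats::sd(z_a) == 0 && stats::sd(z_b) == 0) {
    eq <- isTRUE(all.equal(mean(z_a), mean(z_b)))
    return(list(t = if (eq) 0 else Inf, df = NA_real_, p = if (eq) 1 else 0,
                cohens_d = if (eq) 0 else Inf,
                mean_a = mean(z_a), mean_b = mean(z_b)))
  }
  tt <- stats::t.test(z_a, z_b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, cohens_d = cohen_d(z_a, z_b),
       mean_a = mean(z_a), mean_b = mean(z_b))
}

#' Association between cross-scan self similarity and inter-session interval
#'
#' Pearson correlation (with p-value) between the mean prediction similarity
#' of same-subject cross-scan comparisons and the time elapsed between the
#' two sessions.
#'
#' @param mean_r similarity of each self cross-scan comparison.
#' @param interval inter-session interval for each comparison (same length;
#'   any consistent unit).
#' @return list with `r`, `p`, `n`.
#' @export
interval_association <- function(mean_r, interval) {
  stopifnot(length(mean_r) == length(interval))
  if (length(mean_r) < 3) stop("need at least 3 comparisons with intervals")
  if (stats::sd(interval) == 0)
    stop("intervals are constant; association undefined")
  ct <- stats::cor.test(mean_r, interval)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(mean_r))
}
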