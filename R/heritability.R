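#' Rank-based inverse normal transform
#'
#' Values are replaced by standard-normal quantiles of `(rank - 0.5) / n`,
#' with average ranks for ties, enforcing normality of the outcome before
#' the ANOVA. An all-equal input maps to all zeros with a warning.
#'
#' @param x numeric vector (n >= 3).
#' @return transformed numeric vector.
#' @export
rank_inverse_normal <- function(x) {
  stopifnot(length(x) >= 3, all(is.finite(x)))
  if (length(unique(x)) == 1L) {
    warning("all values equal; rank-inverse-normal transform returns zeros")
    return(rep(0, length(x)))
  }
  stats::qnorm((rank(x, ties.method = "average") - 0.5) / length(x))
}

#' Assemble pair outcomes from pair comparisons
#'
#' The ANOVA unit is the subject pair: for each zygosity pair the two
#' ordered comparison directions (A predicts B, B predicts A; averaged over
#' available scan combinations) are averaged per ROI so each pair
#' contributes once. Unrelated pairs are all (or a sampled subset of)
#' unordered unrelated subject pairs present in the comparisons. Factor
#' coding follows the twin design: shared environment has two levels
#' (related / unrelated); shared genetics has three (MZ; DZ or non-twin
#' sibling; unrelated).
#'
#' @param pc a `pair_comparisons` object.
#' @param cohort the [cohort].
#' @param max_unrelated optional cap on the number of unrelated pairs kept
#'   (sampled deterministically with `seed`).
#' @param seed seed for the optional unrelated subsampling.
#' @return object of class `pair_outcomes`: outcome matrix (pairs x M),
#'   `genetics` and `environment` factors, and pair bookkeeping.
#' @export
pair_outcomes <- function(pc, cohort, max_unrelated = NULL, seed = 1L) {
  stopifnot(inherits(pc, "pair_comparisons"), inherits(cohort, "cohort"))
  cmp <- pc$comparisons
  subj_of <- stats::setNames(cohort$scans$subject_id, cohort$scans$scan_id)
  sa <- unname(subj_of[cmp$model_scan]); sb <- unname(subj_of[cmp$target_scan])
  keep <- cmp$relationship %in% c("MZ", "DZ", "sibling", "unrelated")
  key <- pair_key(sa, sb)
  rel_of <- tapply(cmp$relationship[keep], key[keep], `[`, 1)
  keys <- names(rel_of)
  if (!is.null(max_unrelated)) {
    unrel <- keys[rel_of == "unrelated"]
    if (length(unrel) > max_unrelated) {
      drop_keys <- local_seed(derive_seed(seed, "unrel_subset"),
                              sample(unrel, length(unrel) - max_unrelated))
      keys <- setdiff(keys, drop_keys)
      rel_of <- rel_of[keys]
    }
  }
  m <- ncol(pc$r_mat)
  out <- matrix(NA_real_, length(keys), m)
  for (i in seq_along(keys)) {
    rows <- which(key == keys[i] & keep)
    out[i, ] <- colMeans(pc$r_mat[rows, , drop = FALSE], na.rm = TRUE)
  }
  rel <- unname(rel_of[keys])
  genetics <- factor(ifelse(rel == "MZ", "MZ",
                     ifelse(rel %in% c("DZ", "sibling"), "DZ_or_sib",
                            "unrelated")),
                     levels = c("MZ", "DZ_or_sib", "unrelated"))
  environment <- factor(ifelse(rel == "unrelated", "unrelated", "related"),
                        levels = c("related", "unrelated"))
  structure(list(outcomes = out, genetics = genetics,
                 environment = environment, pair = keys),
            class = "pair_outcomes")
}

#' @export
print.pair_outcomes <- function(x, ...) {
  cat(sprintf("pair_outcomes: %d pairs x %d ROIs\n", nrow(x$outcomes),
              ncol(x$outcomes)))
  print(table(x$genetics))
  invisible(x)
}

#' Simulate pair outcomes with planted variance fractions
#'
#' Generates per-pair per-ROI outcomes whose sequential sum-of-squares
#' fractions for shared genetics and shared environment equal `h2` and `c2`
#' in expectation: group means are offset by `a = sqrt(3*h2/2)` (MZ +a,
#' DZ/sibling -a) on top of a relatedness offset `b = 3*sqrt(c2/2)`, with
#' unit total variance, matching the balanced three-group design (equal
#' numbers of MZ, DZ/sibling and matched unrelated pairs). Used for
#' parameter-recovery checks of the ANOVA machinery.
#'
#' @param n_mz,n_dzsib numbers of MZ and DZ/sibling pairs.
#' @param n_unrelated size of the unrelated pool (resampled downstream).
#' @param M number of ROIs (outcome variables).
#' @param h2,c2 planted genetics / environment variance fractions.
#' @param seed seed.
#' @return a `pair_outcomes` object.
#' @export
simulate_pair_outcomes <- function(n_mz = 58L, n_dzsib = 58L,
                                   n_unrelated = 300L, M = 30L,
                                   h2 = 0.2, c2 = 0.2, seed = 1L) {
  stopifnot(h2 >= 0, c2 >= 0, h2 + c2 < 1)
  a <- sqrt(3 * h2 / 2)
  b <- 3 * sqrt(c2 / 2)
  mu <- c(rep(b + a, n_mz), rep(b - a, n_dzsib), rep(0, n_unrelated))
  n <- length(mu)
  out <- local_seed(derive_seed(seed, "pair_outcomes"),
                    mu + matrix(stats::rnorm(n * M, 0, sqrt(1 - h2 - c2)),
                                n, M))
  structure(list(
    outcomes = out,
    genetics = factor(rep(c("MZ", "DZ_or_sib", "unrelated"),
                          c(n_mz, n_dzsib, n_unrelated)),
                      levels = c("MZ", "DZ_or_sib", "unrelated")),
    environment = factor(rep(c("related", "unrelated"),
                             c(n_mz + n_dzsib, n_unrelated)),
                         levels = c("related", "unrelated")),
    pair = sprintf("P%04d", seq_len(n))),
    class = "pair_outcomes")
}

#' Repeated-measures ANOVA sum-of-squares decomposition
#'
#' Three-way (ROI x shared environment x shared genetics) decomposition with
#' ROI as the repeated (within-pair) measure and only the main effects
#' tested; interactions are pooled into the residual. Sums of squares are
#' sequential (Type I) with ROI entered first, shared environment second and
#' shared genetics third — the only ordering under which both main effects
#' are estimable, because the factors are partially aliased by construction
#' (related/unrelated is a coarsening of the three genetics levels). The
#' genetics term therefore captures exactly the MZ vs DZ/sibling contrast
#' beyond relatedness; with no MZ pairs it is structurally aliased and its
#' SS is reported as 0 with an explicit flag.
#'
#' Outcomes are rank-inverse-normal transformed per ROI (within the supplied
#' pair set) before decomposition. Heritability and shared environment are
#' the ratios of the genetics and environment SS to the total SS.
#'
#' @param po a `pair_outcomes` object.
#' @param roi_subset optional integer vector of ROI columns (default: all).
#' @param transform apply [rank_inverse_normal()] per ROI first.
#' @return list: `ss` table (term, df, ss), `h2`, `c2`, `p_genetics`,
#'   `p_environment`, `aliased`, `ss_total`.
#' @export
rm_anova_ss <- function(po, roi_subset = NULL, transform = TRUE) {
  stopifnot(inherits(po, "pair_outcomes"))
  roi_subset <- roi_subset %||% seq_len(ncol(po$outcomes))
  stopifnot(length(roi_subset) >= 1)
  if (nlevels(droplevels(po$environment)) < 2)
    stop("both environment levels must be present")
  y_mat <- po$outcomes[, roi_subset, drop = FALSE]
  if (transform) y_mat <- apply(y_mat, 2, rank_inverse_normal)
  n <- nrow(y_mat); m <- ncol(y_mat)
  y <- as.vector(y_mat)
  roi <- factor(rep(seq_len(m), each = n))
  env <- rep(droplevels(po$environment), m)
  gen <- rep(droplevels(po$genetics), m)
  aliased <- nlevels(gen) < 3 || !("MZ" %in% levels(gen))
  form <- if (m > 1) y ~ roi + env + gen else y ~ env + gen
  fit <- stats::lm(form)
  an <- stats::anova(fit)
  terms <- rownames(an)
  get_ss <- function(t) if (t %in% terms) an[t, "Sum Sq"] else 0
  get_p <- function(t) if (t %in% terms) an[t, "Pr(>F)"] else NA_real_
  ss_gen <- if ("gen" %in% terms && an["gen", "Df"] > 0) an["gen", "Sum Sq"]
            else 0
  ss_total <- sum(an[, "Sum Sq"])
  # degenerate all-constant outcomes: zero variance, zero fractions
  frac <- function(ss) if (ss_total > 0) ss / ss_total else 0
  list(ss = data.frame(term = terms, df = an$Df, ss = an$`Sum Sq`),
       ss_total = ss_total,
       h2 = frac(ss_gen),
       c2 = frac(get_ss("env")),
       p_genetics = if (ss_gen > 0) get_p("gen") else NA_real_,
       p_environment = get_p("env"),
       aliased = aliased)
}

#' Estimate heritability and shared environment with resampled matching
#'
#' The unrelated pool is far larger than the related groups, so per ANOVA a
#' fresh random matched subset of `n_unrelated_match` unrelated pairs is
#' drawn and the SS fractions recomputed; the estimate is the mean over
#' `n_anovas` decompositions with percentile 95% confidence intervals.
#'
#' @param po a `pair_outcomes` object.
#' @param level `"whole_brain"`, `"network"` or `"roi"`.
#' @param roi_subset ROI columns defining the network / single ROI when
#'   `level != "whole_brain"`.
#' @param n_unrelated_match unrelated pairs drawn per ANOVA.
#' @param n_anovas resampling count (study scale: 1,000).
#' @param seed master seed.
#' @return object of class `heritability_estimate` with `h2`, `c2`, their
#'   CIs, median p-values, and flags.
#' @export
estimate_heritability <- function(po, level = c("whole_brain", "network",
                                                "roi"),
                                  roi_subset = NULL,
                                  n_unrelated_match = 58L, n_anovas = 1000L,
                                  seed = 1L) {
  level <- match.arg(level)
  stopifnot(inherits(po, "pair_outcomes"))
  unrel <- which(po$environment == "unrelated")
  rel <- which(po$environment == "related")
  if (length(unrel) < n_unrelated_match)
    stop(sprintf("unrelated pool (%d) smaller than match size (%d)",
                 length(unrel), n_unrelated_match))
  unreliable <- min(table(droplevels(po$genetics[rel]))) < 2
  h2 <- c2 <- pg <- pe <- numeric(n_anovas)
  aliased <- FALSE
  for (k in seq_len(n_anovas)) {
    idx <- c(rel, local_seed(derive_seed(seed, paste0("anova", k)),
                             sample(unrel, n_unrelated_match)))
    sub <- structure(list(outcomes = po$outcomes[idx, , drop = FALSE],
                          genetics = po$genetics[idx],
                          environment = po$environment[idx],
                          pair = po$pair[idx]),
                     class = "pair_outcomes")
    res <- rm_anova_ss(sub, roi_subset = roi_subset)
    h2[k] <- res$h2; c2[k] <- res$c2
    pg[k] <- res$p_genetics; pe[k] <- res$p_environment
    aliased <- aliased || res$aliased
  }
  structure(list(level = level, roi_subset = roi_subset,
                 h2 = mean(h2), c2 = mean(c2),
                 h2_ci = stats::quantile(h2, c(0.025, 0.975), names = FALSE),
                 c2_ci = stats::quantile(c2, c(0.025, 0.975), names = FALSE),
                 p_genetics = stats::median(pg, na.rm = TRUE),
                 p_environment = stats::median(pe, na.rm = TRUE),
                 n_anovas = n_anovas, aliased = aliased,
                 unreliable = unreliable, draws = data.frame(h2 = h2, c2 = c2)),
            class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf("heritability_estimate (%s, %d ANOVAs)\n", x$level, x$n_anovas))
  cat(sprintf("  h2 = %.3f [%.3f, %.3f]\n", x$h2, x$h2_ci[1], x$h2_ci[2]))
  cat(sprintf("  c2 = %.3f [%.3f, %.3f]\n", x$c2, x$c2_ci[1], x$c2_ci[2]))
  if (x$aliased)
    cat("  note: genetics factor aliased (no MZ contrast available)\n")
  if (x$unreliable)
    cat("  note: <2 pairs in a genetics level; estimate unreliable\n")
  invisible(x)
}

#' ROI-wise heritability estimates with multiple-comparison correction
#'
#' One estimate per ROI (each ROI's outcome analysed alone), with the
#' genetics p-values corrected across all ROIs (Bonferroni by default,
#' Benjamini-Hochberg available).
#'
#' @param po a `pair_outcomes` object.
#' @param n_unrelated_match,n_anovas,seed as in [estimate_heritability()].
#' @param correction `"bonferroni"` or `"BH"`.
#' @return data.frame with one row per ROI: `roi`, `h2`, `c2`, `p`,
#'   `p_adjusted`.
#' @export
estimate_heritability_roiwise <- function(po, n_unrelated_match = 58L,
                                          n_anovas = 100L, seed = 1L,
                                          correction = c("bonferroni", "BH")) {
  correction <- match.arg(correction)
  m <- ncol(po$outcomes)
  ests <- lapply(seq_len(m), function(j)
    estimate_heritability(po, level = "roi", roi_subset = j,
                          n_unrelated_match = n_unrelated_match,
                          n_anovas = n_anovas, seed = derive_seed(seed, j)))
  p <- vapply(ests, `[[`, 0, "p_genetics")
  data.frame(roi = seq_len(m),
             h2 = vapply(ests, `[[`, 0, "h2"),
             c2 = vapply(ests, `[[`, 0, "c2"),
             p = p,
             p_adjusted = stats::p.adjust(p, method = correction))
}
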