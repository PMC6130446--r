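#' Specification for a synthetic family-structured cohort
#'
#' The generator plants kinship structure in the conditional-dependence
#' (precision-matrix) domain: each subject's ROI time series are multivariate
#' Gaussian with precision \eqn{\Theta_s} whose off-diagonal edge weights
#' decompose into a shared base pattern plus additive genetic (kinship-
#' correlated), shared-environment (family-shared) and unique Gaussian edge
#' fields with variance fractions `g2`, `c2`, `e2`. Planting in the precision
#' domain makes the ground-truth connectotype analytically available:
#' `b[i,j] = -theta[i,j]/theta[i,i]`.
#'
#' @param templates named integer vector of family templates:
#'   `mz` (MZ twin pair), `dz` (DZ twin pair), `sib` (non-twin sibling pair),
#'   `trio` (three non-twin siblings), `singleton`.
#' @param M ROI count (>= 5).
#' @param frames frames per scan (>= 30).
#' @param scans_per_subject scans per subject.
#' @param tr sampling interval in seconds.
#' @param g2,c2,e2 additive-genetic, shared-environment and unique variance
#'   fractions of the edge weights; must sum to 1.
#' @param base_density fraction of off-diagonal precision entries in the
#'   shared support.
#' @param base_sd standard deviation of the shared base edge weights.
#' @param dev_scale standard deviation of the per-subject edge deviations
#'   (the g/c/e mixture) around the base weight.
#' @param ar_phi temporal AR(1) smoothing coefficient applied to the sampled
#'   frames (exercises prewhitening; 0 disables).
#' @param fd_median median of the lognormal frame-displacement generator (mm).
#' @param seed master seed; all generator randomness derives from it.
#' @return a validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(templates = c(mz = 6, dz = 6, sib = 12, trio = 6,
                                         singleton = 30),
                           M = 30L, frames = 150L, scans_per_subject = 1L,
                           tr = 2.5, g2 = 0.4, c2 = 0.2, e2 = 0.4,
                           base_density = 0.15, base_sd = 0.35,
                           dev_scale = 0.35, ar_phi = 0.3,
                           fd_median = 0.1, seed = 1L) {
  templates <- templates[templates > 0]
  stopifnot(length(templates) > 0,
            all(names(templates) %in% c("mz", "dz", "sib", "trio", "singleton")),
            M >= 5, frames >= 30, scans_per_subject >= 1,
            tr > 0, g2 >= 0, c2 >= 0, e2 >= 0,
            abs(g2 + c2 + e2 - 1) < 1e-8,
            base_density > 0, base_density <= 1, ar_phi >= 0, ar_phi < 1)
  structure(list(templates = templates, M = as.integer(M),
                 frames = as.integer(frames),
                 scans_per_subject = as.integer(scans_per_subject), tr = tr,
                 g2 = g2, c2 = c2, e2 = e2, base_density = base_density,
                 base_sd = base_sd, dev_scale = dev_scale, ar_phi = ar_phi,
                 fd_median = fd_median, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Instantiate the pedigree of a synthetic spec
#'
#' Families are generated from the templates; zygosity pairs are recorded
#' pairwise (all pairs within a trio), and each subject receives
#' `scans_per_subject` scans with ordinal session numbers.
#'
#' @param spec a [synthetic_spec].
#' @return a [cohort] object.
#' @export
make_pedigree <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  counts <- spec$templates
  if (sum(counts) == 0) stop("zero families")
  sizes <- c(mz = 2L, dz = 2L, sib = 2L, trio = 3L, singleton = 1L)
  classes <- c(mz = "MZ", dz = "DZ", sib = "sibling", trio = "sibling")
  subjects <- list(); scans <- list(); zyg <- list()
  sid <- 0L; fid <- 0L
  for (tpl in names(counts)) {
    for (k in seq_len(counts[[tpl]])) {
      fid <- fid + 1L
      fam <- sprintf("F%03d", fid)
      ids <- character(sizes[[tpl]])
      for (j in seq_len(sizes[[tpl]])) {
        sid <- sid + 1L
        ids[j] <- sprintf("S%03d", sid)
        subjects[[sid]] <- data.frame(subject_id = ids[j], family_id = fam,
                                      template = tpl)
        scans[[sid]] <- data.frame(
          scan_id = sprintf("%s_v%d", ids[j], seq_len(spec$scans_per_subject)),
          subject_id = ids[j], session = seq_len(spec$scans_per_subject))
      }
      if (tpl %in% names(classes)) {
        prs <- utils::combn(ids, 2)
        zyg[[length(zyg) + 1L]] <- data.frame(subject_a = prs[1, ],
                                              subject_b = prs[2, ],
                                              class = classes[[tpl]])
      }
    }
  }
  cohort(do.call(rbind, subjects), do.call(rbind, scans),
         if (length(zyg)) do.call(rbind, zyg) else NULL)
}

#' Plant subject-level precision matrices with kinship structure
#'
#' A sparse symmetric support is drawn once; per subject the edge weights are
#' `w_s = w_base + dev_scale * (sqrt(g2) G_s + sqrt(c2) C_f + sqrt(e2) E_s)`
#' where the genetic field G has cross-subject correlation equal to the
#' kinship coefficient (MZ 1, DZ/sibling 0.5, unrelated 0), C is shared
#' within family and E is independent. Each precision matrix is made
#' symmetric positive definite by diagonal loading to a minimum eigenvalue
#' of 0.1, and the ground-truth coefficient matrix is derived as
#' `B[i,j] = -Theta[i,j]/Theta[i,i]`.
#'
#' @param spec a [synthetic_spec].
#' @param pedigree the [cohort] from [make_pedigree()].
#' @return a `synthetic_truth` list: per-subject `Theta` and `B`, the
#'   kinship matrix, the edge support, the shared base weights, and the
#'   planted fractions.
#' @export
make_precisions <- function(spec, pedigree) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(pedigree, "cohort"))
  m <- spec$M
  subj <- pedigree$subjects
  n_sub <- nrow(subj)
  local_seed(derive_seed(spec$seed, "precisions"), {
    ut <- which(upper.tri(matrix(0, m, m)))
    support <- ut[stats::runif(length(ut)) < spec$base_density]
    if (length(support) < m) # keep at least ~one edge per ROI on average
      support <- sample(ut, m)
    ne <- length(support)
    w_base <- stats::rnorm(ne, 0, spec$base_sd)

    kin <- kinship_matrix(pedigree)
    fams <- unique(subj$family_id)
    c_field <- matrix(stats::rnorm(ne * length(fams)), ne,
                      dimnames = list(NULL, fams))
    g_fam <- matrix(stats::rnorm(ne * length(fams)), ne,
                    dimnames = list(NULL, fams))
    theta <- vector("list", n_sub); b_true <- vector("list", n_sub)
    names(theta) <- names(b_true) <- subj$subject_id
    for (s in seq_len(n_sub)) {
      fam <- subj$family_id[s]
      tpl <- subj$template[s] %||% "singleton"
      g_s <- switch(tpl,
        mz = g_fam[, fam],
        dz = ,
        sib = ,
        trio = sqrt(0.5) * g_fam[, fam] + sqrt(0.5) * stats::rnorm(ne),
        stats::rnorm(ne))
      dev <- spec$dev_scale * (sqrt(spec$g2) * g_s +
                               sqrt(spec$c2) * c_field[, fam] +
                               sqrt(spec$e2) * stats::rnorm(ne))
      w <- matrix(0, m, m)
      w[support] <- w_base + dev
      w <- w + t(w)
      lam <- min(eigen(w, symmetric = TRUE, only.values = TRUE)$values)
      th <- w + diag(0.1 - min(lam, 0), m)
      theta[[s]] <- th
      b <- -th / diag(th)
      diag(b) <- 0
      b_true[[s]] <- b
    }
    structure(list(Theta = theta, B = b_true, kinship = kin,
                   support = support, base = w_base, spec = spec),
              class = "synthetic_truth")
  })
}

# Expected genetic-field correlation between subjects (MZ 1, DZ/sib 0.5,
# unrelated 0); diagonal 1.
kinship_matrix <- function(pedigree) {
  ids <- pedigree$subjects$subject_id
  kin <- diag(length(ids))
  dimnames(kin) <- list(ids, ids)
  z <- pedigree$zygosity
  for (i in seq_len(nrow(z))) {
    v <- if (z$class[i] == "MZ") 1 else 0.5
    kin[z$subject_a[i], z$subject_b[i]] <- v
    kin[z$subject_b[i], z$subject_a[i]] <- v
  }
  kin
}

#' Sample ROI time series from planted precision matrices
#'
#' Frames are drawn i.i.d. from a zero-mean multivariate normal with
#' covariance `solve(Theta_s)` and then, when `ar_phi > 0`, passed through a
#' per-column AR(1) recursion scaled to preserve the stationary covariance
#' (so prewhitening is genuinely exercised downstream).
#'
#' @param truth a `synthetic_truth` from [make_precisions()].
#' @param spec the [synthetic_spec].
#' @param pedigree the [cohort].
#' @param frames optional frame-count override.
#' @return named list of [scan_timeseries], one per scan.
#' @export
sample_timeseries <- function(truth, spec, pedigree, frames = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  frames <- frames %||% spec$frames
  scans <- pedigree$scans
  out <- vector("list", nrow(scans))
  names(out) <- scans$scan_id
  for (k in seq_len(nrow(scans))) {
    subj <- scans$subject_id[k]
    out[[k]] <- local_seed(
      derive_seed(spec$seed, paste0("ts_", scans$scan_id[k])),
      {
        x <- rmvn_precision(frames, truth$Theta[[subj]])
        if (spec$ar_phi > 0) {
          x <- apply(x, 2, function(col)
            stats::filter(col, spec$ar_phi, method = "recursive"))
          x <- x * sqrt(1 - spec$ar_phi^2)
        }
        scan_timeseries(x, tr = spec$tr, scan_id = scans$scan_id[k])
      })
  }
  out
}

# draw n rows from N(0, Theta^-1) via the Cholesky factor of Theta
rmvn_precision <- function(n, theta) {
  ch <- tryCatch(chol(theta),
                 error = function(e) stop("precision matrix is not SPD"))
  z <- matrix(stats::rnorm(n * ncol(theta)), n)
  t(backsolve(ch, t(z)))
}

#' Generate per-frame displacement traces
#'
#' Lognormal per-frame FD with a configurable median and an optional
#' per-family multiplicative median shift, used to build positive and
#' negative controls for familiality-of-motion checks.
#'
#' @param spec a [synthetic_spec].
#' @param pedigree the [cohort].
#' @param family_shift per-family shift magnitude on the log scale
#'   (0 = no familial motion structure).
#' @return named list of FD vectors, one per scan.
#' @export
make_fd <- function(spec, pedigree, family_shift = 0) {
  stopifnot(family_shift >= 0)
  fams <- unique(pedigree$subjects$family_id)
  shifts <- local_seed(derive_seed(spec$seed, "fd_family"),
                       stats::setNames(stats::rnorm(length(fams), 0,
                                                    family_shift), fams))
  fam_of <- stats::setNames(pedigree$subjects$family_id,
                            pedigree$subjects$subject_id)
  out <- lapply(seq_len(nrow(pedigree$scans)), function(k) {
    sc <- pedigree$scans[k, ]
    local_seed(derive_seed(spec$seed, paste0("fd_", sc$scan_id)),
               stats::rlnorm(spec$frames,
                             log(spec$fd_median) + shifts[fam_of[sc$subject_id]],
                             0.5))
  })
  stats::setNames(out, pedigree$scans$scan_id)
}

#' Generate per-subject anatomical measures with their own familial structure
#'
#' Per-ROI cortical thickness and sulcal depth are generated with the same
#' additive genetic / shared environment / unique decomposition as the edge
#' weights, plus a head-size confounder that scales both measures, so the
#' anatomy-control classifier and its brain-size adjustments are testable.
#'
#' @param spec a [synthetic_spec].
#' @param pedigree the [cohort].
#' @param g2,c2 variance fractions for the anatomical fields (remainder is
#'   unique variance).
#' @param head_effect strength of the head-size confounder.
#' @return anatomy data.frame (`subject_id`, `roi_id`, `thickness`,
#'   `sulcal_depth`, `head_size`).
#' @export
make_anatomy <- function(spec, pedigree, g2 = spec$g2, c2 = spec$c2,
                         head_effect = 0.5) {
  subj <- pedigree$subjects
  m <- spec$M
  e2 <- 1 - g2 - c2
  stopifnot(e2 >= 0)
  local_seed(derive_seed(spec$seed, "anatomy"), {
    fams <- unique(subj$family_id)
    base_th <- 2.5 + 0.3 * stats::rnorm(m)
    base_su <- 1.0 + 0.2 * stats::rnorm(m)
    gf <- matrix(stats::rnorm(m * length(fams)), m,
                 dimnames = list(NULL, fams))
    cf_th <- matrix(stats::rnorm(m * length(fams)), m,
                    dimnames = list(NULL, fams))
    rows <- lapply(seq_len(nrow(subj)), function(s) {
      fam <- subj$family_id[s]
      tpl <- subj$template[s] %||% "singleton"
      g_s <- switch(tpl,
        mz = gf[, fam],
        dz = , sib = , trio = sqrt(0.5) * gf[, fam] +
          sqrt(0.5) * stats::rnorm(m),
        stats::rnorm(m))
      head <- 1 + 0.1 * stats::rnorm(1)
      field <- sqrt(g2) * g_s + sqrt(c2) * cf_th[, fam] +
        sqrt(e2) * stats::rnorm(m)
      data.frame(subject_id = subj$subject_id[s], roi_id = seq_len(m),
                 thickness = base_th + 0.15 * field +
                   head_effect * (head - 1),
                 sulcal_depth = base_su + 0.1 * field +
                   0.5 * head_effect * (head - 1),
                 head_size = head)
    })
    do.call(rbind, rows)
  })
}

#' Generate a complete synthetic cohort bundle
#'
#' Convenience wrapper: pedigree, planted precisions, sampled time series,
#' FD traces and anatomy in one deterministic call. Identical spec (and its
#' seed) reproduces the bundle bit-identically.
#'
#' @param spec a [synthetic_spec].
#' @param fd,anatomy logical switches for the optional artifacts.
#' @return list with `cohort`, `truth`, `scans` (list of [scan_timeseries]),
#'   optionally `fd` and `anatomy`, plus a synthetic parcellation covering
#'   the M ROIs.
#' @export
simulate_cohort <- function(spec, fd = FALSE, anatomy = FALSE) {
  ped <- make_pedigree(spec)
  truth <- make_precisions(spec, ped)
  scans <- sample_timeseries(truth, spec, ped)
  if (anatomy) ped$anatomical <- make_anatomy(spec, ped)
  list(cohort = ped, truth = truth, scans = scans,
       fd = if (fd) make_fd(spec, ped) else NULL,
       anatomy = if (anatomy) ped$anatomical else NULL,
       parcellation = synthetic_parcellation(spec$M),
       spec = spec)
}

#' Parcellation table for a synthetic cohort
#'
#' Assigns the M synthetic ROIs round-robin to five named functional
#' networks plus an unassigned bucket, so network-level machinery
#' (per-network classifiers, network heritability) is exercisable.
#'
#' @param M ROI count.
#' @return a [parcellation] table.
#' @export
synthetic_parcellation <- function(M) {
  nets <- c("default", "fronto_parietal", "dorsal_attention",
            "cingulo_opercular", "visual", "unassigned")
  parcellation(seq_len(M), rep_len(nets, M),
               n_vertices = 60L + ((seq_len(M) * 53L) %% 120L),
               hemisphere = rep_len(c("L", "R"), M))
}

#' Write a synthetic cohort bundle to the on-disk file layout
#'
#' Emits the full set of delimited text files consumed by the loaders:
#' roster + zygosity TSVs, parcellation TSV, one time-course TSV per scan,
#' optional FD traces and anatomy table.
#'
#' @param bundle result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, a character vector of files written.
#' @export
write_synthetic_cohort <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    write_cohort(bundle$cohort, file.path(dir, "roster.tsv"),
                 file.path(dir, "zygosity.tsv")),
    write_parcellation(bundle$parcellation, file.path(dir, "parcellation.tsv")))
  for (id in names(bundle$scans))
    files <- c(files, write_timeseries(bundle$scans[[id]],
                                       file.path(dir, paste0(id, ".tsv"))))
  for (id in names(bundle$fd %||% list()))
    files <- c(files, write_fd(bundle$fd[[id]],
                               file.path(dir, paste0(id, "_fd.txt"))))
  if (!is.null(bundle$anatomy))
    files <- c(files, write_anatomy(bundle$anatomy,
                                    file.path(dir, "anatomy.tsv")))
  invisible(files)
}
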