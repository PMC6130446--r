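#' Run the full analysis pipeline from a single configuration
#'
#' Executes the stages in dependency order — simulate (or load), preprocess,
#' fit/compare, classify, heritability — and writes every artifact plus a
#' manifest (file, MD5 content hash) and the master seed to the output
#' directory. Reruns with the same configuration and seed produce identical
#' content hashes for every stochastic stage.
#'
#' @param config a named list (or path to a JSON file) with components:
#'   `out_dir` (output directory), `seed` (master seed), `synthetic`
#'   (arguments for [synthetic_spec()]; omit to load an existing cohort via
#'   `data_dir`), `data_dir` (directory holding `roster.tsv`,
#'   `zygosity.tsv`, `parcellation.tsv` and per-scan TSVs; `tr` required),
#'   `tr`, `preprocess` (list: `profile`, `ar_order`), `classify` (list:
#'   `runs`, `top_p`, `holdout_families`, `max_unrelated`, `null`),
#'   `heritability` (list: `n_anovas`, `n_unrelated_match`, or `NULL` to
#'   skip).
#' @return invisibly, the manifest data.frame (`file`, `md5`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    stopifnot(file.exists(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config), !is.null(config$out_dir))
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # --- stage: simulate or load -------------------------------------------
  if (!is.null(config$synthetic)) {
    spec <- do.call(synthetic_spec,
                    c(config$synthetic, list(seed = derive_seed(seed, "sim"))))
    bundle <- simulate_cohort(spec)
    write_synthetic_cohort(bundle, file.path(out_dir, "data"))
    cohort <- bundle$cohort
    scans_raw <- bundle$scans
    parc <- bundle$parcellation
    tr <- spec$tr
  } else {
    dd <- config$data_dir
    if (is.null(dd) || !dir.exists(dd))
      stop("config must provide either 'synthetic' or an existing 'data_dir'")
    tr <- config$tr %||% stop("config$tr required when loading data")
    parc <- load_parcellation(file.path(dd, "parcellation.tsv"))
    zp <- file.path(dd, "zygosity.tsv")
    cohort <- load_cohort(file.path(dd, "roster.tsv"),
                          if (file.exists(zp)) zp)
    scans_raw <- lapply(cohort$scans$scan_id, function(id)
      load_timeseries(file.path(dd, paste0(id, ".tsv")), parc, tr = tr,
                      scan_id = id))
    names(scans_raw) <- cohort$scans$scan_id
  }

  # --- stage: preprocess --------------------------------------------------
  pp <- config$preprocess %||% list()
  ar_order <- pp$ar_order %||% 1L
  scans <- lapply(scans_raw, function(ts)
    if (ar_order > 0) remove_autocorrelation(ts, ar_order) else ts)

  # --- stage: fit and compare --------------------------------------------
  cl <- config$classify %||% list()
  cmp_all <- enumerate_comparisons(cohort)
  pos <- which(cmp_all$relationship %in% c("MZ", "DZ", "sibling",
                                           "self_same_scan",
                                           "self_other_scan"))
  unrel <- which(cmp_all$relationship == "unrelated")
  max_unrel <- cl$max_unrelated %||% 2000L
  if (length(unrel) > max_unrel)
    unrel <- local_seed(derive_seed(seed, "pool"), sample(unrel, max_unrel))
  pc <- run_all_comparisons(cohort, scans,
                            comparisons = cmp_all[sort(c(pos, unrel)), ])
  utils::write.table(pc$comparisons, file.path(out_dir, "comparisons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- stage: classify ----------------------------------------------------
  rows <- build_features(pc, cohort)
  top_p <- cl$top_p %||% max(10L, ceiling(ncol(rows$features) / 3))
  res <- run_experiment(rows, scheme = cl$scheme %||% "family_holdout",
                        runs = cl$runs %||% 50L,
                        holdout_families = cl$holdout_families %||% 3L,
                        top_p = top_p, seed = derive_seed(seed, "clf"),
                        null = isTRUE(cl$null %||% TRUE))
  clf_out <- list(scheme = res$scheme, runs = res$n_runs,
                  accuracy = unname(res$summary["mean"]),
                  accuracy_percentiles = as.list(res$summary),
                  null_accuracy = if (!is.null(res$null_summary))
                    unname(res$null_summary["mean"]))
  jsonlite::write_json(clf_out, file.path(out_dir, "classifier.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(res$runs, file.path(out_dir, "classifier_runs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- stage: heritability ------------------------------------------------
  he <- config$heritability
  if (!is.null(he)) {
    po <- pair_outcomes(pc, cohort)
    n_match <- min(he$n_unrelated_match %||% 58L,
                   sum(po$environment == "unrelated"))
    est <- estimate_heritability(po, level = "whole_brain",
                                 n_unrelated_match = n_match,
                                 n_anovas = he$n_anovas %||% 100L,
                                 seed = derive_seed(seed, "herit"))
    jsonlite::write_json(list(h2 = est$h2, c2 = est$c2,
                              h2_ci = est$h2_ci, c2_ci = est$c2_ci,
                              n_anovas = est$n_anovas,
                              aliased = est$aliased),
                         file.path(out_dir, "heritability.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  # --- manifest -----------------------------------------------------------
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE,
                                   full.names = TRUE),
                        file.path(out_dir, "manifest.tsv")))
  manifest <- data.frame(file = sub(paste0("^", out_dir, "/?"), "", files),
                         md5 = unname(tools::md5sum(files)), seed = seed)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
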