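#' Functional network vocabulary
#'
#' Named networks of the Gordon cortical parcellation plus the subcortical
#' network and the "unassigned" bucket for parcels without a community
#' assignment. Parcellation tables are validated against this vocabulary by
#' default; unknown labels are mapped to `"unassigned"` with a warning.
#'
#' @return character vector of network labels.
#' @export
network_vocabulary <- function() {
  c("auditory", "cingulo_opercular", "cingulo_parietal", "default",
    "dorsal_attention", "fronto_parietal", "retrosplenial_temporal",
    "salience", "somatosensory_hand", "somatosensory_mouth",
    "ventral_attention", "visual", "subcortical", "unassigned")
}

#' Construct a cohort object
#'
#' A cohort bundles subjects (with family membership), their scan sessions,
#' pairwise zygosity relationships and, optionally, per-subject per-ROI
#' anatomical measures. Zygosity is stored pairwise because the analysis unit
#' for kinship is the pair, not the subject.
#'
#' @param subjects data.frame with columns `subject_id`, `family_id`.
#' @param scans data.frame with columns `scan_id`, `subject_id`, `session`
#'   (calendar date or small integer session ordinal).
#' @param zygosity data.frame with columns `subject_a`, `subject_b`, `class`
#'   (one of `"MZ"`, `"DZ"`, `"sibling"`), or `NULL`.
#' @param anatomical optional data.frame with columns `subject_id`, `roi_id`,
#'   `thickness`, `sulcal_depth`, `head_size`.
#' @return an object of class `cohort`.
#' @export
cohort <- function(subjects, scans, zygosity = NULL, anatomical = NULL) {
  subjects <- as.data.frame(subjects)
  scans <- as.data.frame(scans)
  stopifnot(all(c("subject_id", "family_id") %in% names(subjects)),
            all(c("scan_id", "subject_id", "session") %in% names(scans)))
  subjects$subject_id <- as.character(subjects$subject_id)
  subjects$family_id <- as.character(subjects$family_id)
  scans$scan_id <- as.character(scans$scan_id)
  scans$subject_id <- as.character(scans$subject_id)
  if (nrow(subjects) == 0L) stop("empty cohort")
  if (anyDuplicated(subjects$subject_id))
    stop("duplicate subject_id in roster")
  if (anyDuplicated(scans$scan_id))
    stop("duplicate scan_id: ",
         paste(unique(scans$scan_id[duplicated(scans$scan_id)]), collapse = ", "))
  unknown <- setdiff(scans$subject_id, subjects$subject_id)
  if (length(unknown))
    stop("scan refers to unknown subject: ", paste(unknown, collapse = ", "))
  missing_scan <- setdiff(subjects$subject_id, scans$subject_id)
  if (length(missing_scan))
    stop("subject without any scan: ", paste(missing_scan, collapse = ", "))
  if (!is.null(zygosity) && nrow(zygosity)) {
    zygosity <- as.data.frame(zygosity)
    stopifnot(all(c("subject_a", "subject_b", "class") %in% names(zygosity)))
    zygosity$subject_a <- as.character(zygosity$subject_a)
    zygosity$subject_b <- as.character(zygosity$subject_b)
    zygosity$class <- normalize_zygosity(zygosity$class)
    fam <- stats::setNames(subjects$family_id, subjects$subject_id)
    bad <- which(is.na(fam[zygosity$subject_a]) | is.na(fam[zygosity$subject_b]))
    if (length(bad))
      stop("zygosity pair references unknown subject (row ",
           paste(bad, collapse = ", "), ")")
    cross <- which(fam[zygosity$subject_a] != fam[zygosity$subject_b])
    if (length(cross))
      stop("zygosity pair spans two families: ",
           paste(sprintf("%s/%s", zygosity$subject_a[cross],
                         zygosity$subject_b[cross]), collapse = ", "))
  } else {
    zygosity <- data.frame(subject_a = character(), subject_b = character(),
                           class = character())
  }
  structure(list(subjects = subjects, scans = scans, zygosity = zygosity,
                 anatomical = anatomical),
            class = "cohort")
}

normalize_zygosity <- function(x) {
  key <- tolower(gsub("[^a-z]", "", tolower(as.character(x))))
  map <- c(mz = "MZ", monozygotic = "MZ", identical = "MZ",
           dz = "DZ", dizygotic = "DZ", fraternal = "DZ",
           sib = "sibling", sibling = "sibling", nontwin = "sibling",
           nontwinsibling = "sibling")
  out <- map[key]
  if (anyNA(out))
    stop("unknown zygosity class: ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  unname(out)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d subjects, %d families, %d scans, %d zygosity pairs\n",
              nrow(x$subjects), length(unique(x$subjects$family_id)),
              nrow(x$scans), nrow(x$zygosity)))
  if (nrow(x$zygosity))
    print(table(x$zygosity$class))
  invisible(x)
}

#' Read a cohort roster (and optional zygosity table) from TSV files
#'
#' The roster has one row per scan with columns `subject_id`, `family_id`,
#' `scan_id`, `session`; the zygosity table has columns `subject_a`,
#' `subject_b`, `class`. All cohort invariants are validated on load.
#'
#' @param roster_path path to the roster TSV.
#' @param zygosity_path optional path to the zygosity TSV.
#' @return a [cohort] object.
#' @export
load_cohort <- function(roster_path, zygosity_path = NULL) {
  stopifnot(file.exists(roster_path))
  roster <- utils::read.delim(roster_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "family_id", "scan_id", "session")
  if (!all(need %in% names(roster)))
    stop("roster missing columns: ",
         paste(setdiff(need, names(roster)), collapse = ", "))
  if (nrow(roster) == 0L) stop("empty cohort")
  subjects <- unique(roster[, c("subject_id", "family_id")])
  zyg <- NULL
  if (!is.null(zygosity_path)) {
    stopifnot(file.exists(zygosity_path))
    zyg <- utils::read.delim(zygosity_path, stringsAsFactors = FALSE)
  }
  cohort(subjects, roster[, c("scan_id", "subject_id", "session")], zyg)
}

#' Write a cohort back to roster/zygosity TSV files
#'
#' @param x a [cohort] object.
#' @param roster_path,zygosity_path output paths (zygosity file only written
#'   when the cohort has zygosity pairs).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(x, roster_path, zygosity_path = NULL) {
  stopifnot(inherits(x, "cohort"))
  roster <- merge(x$scans, x$subjects, by = "subject_id", sort = FALSE)
  roster <- roster[, c("subject_id", "family_id", "scan_id", "session")]
  utils::write.table(roster, roster_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  out <- roster_path
  if (!is.null(zygosity_path) && nrow(x$zygosity)) {
    utils::write.table(x$zygosity, zygosity_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out <- c(out, zygosity_path)
  }
  invisible(out)
}

#' Construct a parcellation table
#'
#' @param roi_id integer vector `1..M` (contiguous).
#' @param network character network labels, validated against `vocabulary`.
#' @param n_vertices ROI sizes (vertex or grayordinate counts).
#' @param hemisphere optional hemisphere labels.
#' @param vocabulary allowed network labels; unknown labels are mapped to
#'   `"unassigned"` with a warning.
#' @return data.frame of class `parcellation`.
#' @export
parcellation <- function(roi_id, network, n_vertices = NA_integer_,
                         hemisphere = NA_character_,
                         vocabulary = network_vocabulary()) {
  roi_id <- as.integer(roi_id)
  if (anyDuplicated(roi_id) || !identical(sort(roi_id), seq_along(roi_id)))
    stop("non-contiguous ids: roi_id must be 1..M without gaps")
  network <- as.character(network)
  bad <- !(network %in% vocabulary)
  if (any(bad)) {
    warning(sprintf("%d unknown network label(s) (%s) mapped to 'unassigned'",
                    sum(bad), paste(unique(network[bad]), collapse = ", ")))
    network[bad] <- "unassigned"
  }
  out <- data.frame(roi_id = roi_id, network = network,
                    n_vertices = as.integer(n_vertices),
                    hemisphere = as.character(hemisphere))
  out <- out[order(out$roi_id), ]
  rownames(out) <- NULL
  class(out) <- c("parcellation", "data.frame")
  out
}

#' Read a parcellation table from TSV
#'
#' Expects columns `roi_id`, `network`, `n_vertices` and optionally
#' `hemisphere`.
#'
#' @param path path to the parcellation TSV.
#' @param vocabulary allowed network labels.
#' @return a [parcellation] table.
#' @export
load_parcellation <- function(path, vocabulary = network_vocabulary()) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("roi_id", "network", "n_vertices")
  if (!all(need %in% names(tab)))
    stop("parcellation missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  parcellation(tab$roi_id, tab$network, tab$n_vertices,
               tab$hemisphere %||% NA_character_, vocabulary = vocabulary)
}

#' @rdname load_parcellation
#' @param x a [parcellation] table.
#' @export
write_parcellation <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Number of ROIs per network
#'
#' @param x a [parcellation] table.
#' @return named integer vector of ROI counts per network label.
#' @export
network_sizes <- function(x) {
  stopifnot(inherits(x, "parcellation"))
  tab <- table(x$network)
  stats::setNames(as.integer(tab), names(tab))
}

#' Gordon-style parcellation table
#'
#' Reproduces the bookkeeping shape of the Gordon cortical parcellation:
#' 333 cortical ROIs spread over 12 functional networks with 47 unassigned
#' parcels, optionally extended by 19 subcortical regions (as used for
#' region-level heritability estimates, 333 + 19 = 352). ROI sizes are
#' synthetic placeholders; only the id/network bookkeeping is meaningful.
#'
#' @param subcortical logical; append the 19 subcortical regions.
#' @return a [parcellation] table with 333 or 352 rows.
#' @export
gordon_style_parcellation <- function(subcortical = FALSE) {
  counts <- c(auditory = 24, cingulo_opercular = 40, cingulo_parietal = 5,
              default = 41, dorsal_attention = 32, fronto_parietal = 24,
              retrosplenial_temporal = 8, salience = 4,
              somatosensory_hand = 38, somatosensory_mouth = 8,
              ventral_attention = 23, visual = 39, unassigned = 47)
  network <- rep(names(counts), counts)
  if (subcortical) network <- c(network, rep("subcortical", 19))
  m <- length(network)
  sizes <- 40L + ((seq_len(m) * 37L) %% 180L)  # deterministic placeholder sizes
  parcellation(seq_len(m), network, sizes,
               rep_len(c("L", "R"), m))
}

#' Construct a single-scan time-series object
#'
#' @param data numeric frames x M matrix of parcellated signals.
#' @param tr sampling interval (seconds).
#' @param scan_id scan identifier.
#' @param frame_mask logical retention mask (default: all frames retained).
#' @return object of class `scan_timeseries`.
#' @export
scan_timeseries <- function(data, tr, scan_id = "scan", frame_mask = NULL) {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), length(tr) == 1L, tr > 0)
  frame_mask <- frame_mask %||% rep(TRUE, nrow(data))
  stopifnot(length(frame_mask) == nrow(data), is.logical(frame_mask))
  if (any(!is.finite(data[frame_mask, , drop = FALSE]))) {
    idx <- which(!is.finite(data) & frame_mask, arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at frame %d, ROI %d", idx[1], idx[2]))
  }
  structure(list(data = data, tr = tr, scan_id = as.character(scan_id),
                 frame_mask = frame_mask),
            class = "scan_timeseries")
}

#' @export
print.scan_timeseries <- function(x, ...) {
  cat(sprintf("scan_timeseries '%s': %d frames (%d retained) x %d ROIs, TR %.3g s\n",
              x$scan_id, nrow(x$data), sum(x$frame_mask), ncol(x$data), x$tr))
  invisible(x)
}

# retained-frames matrix
retained <- function(ts) ts$data[ts$frame_mask, , drop = FALSE]

#' Read one scan's ROI time courses from a delimited text file
#'
#' Frames are rows, ROIs are columns (tab-delimited, optional header row of
#' ROI ids). The column count must match the parcellation.
#'
#' @param path path to the TSV matrix.
#' @param parcellation a [parcellation] table defining M.
#' @param tr sampling interval in seconds.
#' @param scan_id scan identifier (defaults to the file stem).
#' @return a [scan_timeseries] object.
#' @export
load_timeseries <- function(path, parcellation, tr,
                            scan_id = sub("\\.[^.]*$", "", basename(path))) {
  stopifnot(file.exists(path))
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  header <- suppressWarnings(anyNA(as.numeric(first)))
  mat <- as.matrix(utils::read.delim(path, header = header,
                                     colClasses = "numeric"))
  dimnames(mat) <- NULL
  m <- nrow(parcellation)
  if (ncol(mat) != m)
    stop(sprintf("time-series has %d columns but parcellation defines %d ROIs",
                 ncol(mat), m))
  if (any(!is.finite(mat))) {
    idx <- which(!is.finite(mat), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric or missing value at row %d, column %d",
                 idx[1], idx[2]))
  }
  scan_timeseries(mat, tr = tr, scan_id = scan_id)
}

#' @rdname load_timeseries
#' @param x a [scan_timeseries] object.
#' @param digits decimal digits written (round-trip precision).
#' @export
write_timeseries <- function(x, path, digits = 8) {
  utils::write.table(signif(x$data, digits), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a per-frame frame-displacement trace
#'
#' One non-negative value per frame, plain text, one value per line.
#'
#' @param path file path.
#' @return numeric vector of FD values (mm).
#' @export
load_fd <- function(path) {
  stopifnot(file.exists(path))
  fd <- scan(path, what = numeric(), quiet = TRUE)
  if (any(!is.finite(fd)) || any(fd < 0))
    stop("FD trace must be finite and non-negative")
  fd
}

#' @rdname load_fd
#' @param fd numeric FD vector.
#' @export
write_fd <- function(fd, path) {
  writeLines(format(fd, digits = 8, trim = TRUE, scientific = FALSE), path)
  invisible(path)
}

#' Read / write a per-subject per-ROI anatomical measure table
#'
#' Long format: `subject_id`, `roi_id`, `thickness`, `sulcal_depth`,
#' `head_size` (head size constant within subject).
#'
#' @param path file path.
#' @return data.frame of anatomical measures.
#' @export
load_anatomy <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "roi_id", "thickness", "sulcal_depth", "head_size")
  if (!all(need %in% names(tab)))
    stop("anatomy table missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  hs <- tapply(tab$head_size, tab$subject_id, function(v) length(unique(v)))
  if (any(hs != 1L))
    stop("head_size must be constant within subject")
  tab
}

#' @rdname load_anatomy
#' @param x anatomy data.frame.
#' @export
write_anatomy <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Oregon-style longitudinal cohort roster
#'
#' Builds a cohort with the printed shape of the youth longitudinal sample:
#' 159 subjects (131 with one scan, 27 with two, 1 with three; 188 scans in
#' total) and 16 sibling pairs whose scan multiplicities yield 46 ordered
#' sibling scan-pair comparisons and 60 same-subject cross-scan comparisons.
#' The published roster does not state the per-pair scan allocation; the
#' allocation used here (12 pairs with 1+1 scans, 2 with 2+1, 1 with 2+2,
#' 1 with 3+1) is the package's documented assumption consistent with every
#' printed count.
#'
#' @return a [cohort] object with 188 scans.
#' @export
oregon_style_cohort <- function() {
  sib_alloc <- list(c(1, 1), c(1, 1), c(1, 1), c(1, 1), c(1, 1), c(1, 1),
                    c(1, 1), c(1, 1), c(1, 1), c(1, 1), c(1, 1), c(1, 1),
                    c(2, 1), c(2, 1), c(2, 2), c(3, 1))
  subjects <- list(); zyg <- list(); scans <- list()
  sid <- 0L
  new_subj <- function(fam, nscan) {
    sid <<- sid + 1L
    id <- sprintf("S%03d", sid)
    subjects[[length(subjects) + 1L]] <<- data.frame(subject_id = id,
                                                     family_id = fam)
    scans[[length(scans) + 1L]] <<- data.frame(
      scan_id = sprintf("%s_v%d", id, seq_len(nscan)),
      subject_id = id, session = seq_len(nscan))
    id
  }
  for (k in seq_along(sib_alloc)) {
    fam <- sprintf("F%03d", k)
    a <- new_subj(fam, sib_alloc[[k]][1])
    b <- new_subj(fam, sib_alloc[[k]][2])
    zyg[[k]] <- data.frame(subject_a = a, subject_b = b, class = "sibling")
  }
  # remaining multi-scan singletons: 27 total two-scan subjects, 4 are siblings
  for (k in 1:23) new_subj(sprintf("F%03d", 16L + k), 2L)
  # remaining single-scan singletons: 131 total, 27 are siblings
  for (k in 1:104) new_subj(sprintf("F%03d", 39L + k), 1L)
  cohort(do.call(rbind, subjects), do.call(rbind, scans), do.call(rbind, zyg))
}
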