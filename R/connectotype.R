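#' Fit a connectotype model to one scan
#'
#' The connectotype expresses each ROI's (prewhitened) time course as a
#' weighted sum of all other ROIs: for ROI i, the coefficient row
#' `b[i, -i]` solves the least-squares regression of column i on the
#' remaining columns, regularized by a truncated-SVD pseudoinverse of the
#' predictor matrix. A single truncation rank, shared across the M per-ROI
#' regressions, is chosen to minimize total held-out squared prediction
#' error over contiguous-block cross-validation folds (blocks respect
#' temporal autocorrelation). Ties in CV error break toward the smaller
#' rank, i.e. toward more regularization. The underdetermined regime
#' (fewer frames than ROIs) is supported: the rank is capped by the number
#' of training frames.
#'
#' @param ts a [scan_timeseries] (retained frames are used) or a numeric
#'   frames x M matrix of residual time courses.
#' @param rank_grid candidate truncation ranks; default 10 log-spaced values
#'   in `[2, min(M - 1, frames - 1)]`. Values beyond what the folds can
#'   support are clipped with a warning.
#' @param cv_folds number of contiguous-block CV folds (default 4).
#' @param rank fix the truncation rank directly, skipping cross-validation.
#' @return an object of class `connectotype`: coefficient matrix `B`
#'   (M x M, zero diagonal, row i predicts ROI i), `rank_k`, `fit_frames`,
#'   and the per-rank CV error profile.
#' @seealso [predict.connectotype()], [similarity()]
#' @export
fit_connectotype <- function(ts, rank_grid = NULL, cv_folds = 4L,
                             rank = NULL) {
  x <- if (inherits(ts, "scan_timeseries")) retained(ts) else as.matrix(ts)
  n <- nrow(x); m <- ncol(x)
  if (n < 10L) stop("need at least 10 retained frames to fit a connectotype")
  if (m < 3L) stop("need at least 3 ROIs")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("all-constant ROI column(s): ",
         paste(which(sds == 0), collapse = ", "))
  max_rank <- min(m - 1L, n - 1L)
  if (!is.null(rank)) {
    rank_k <- min(as.integer(rank), max_rank)
    cv_err <- NULL
  } else {
    rank_grid <- rank_grid %||% default_rank_grid(m, n)
    rank_grid <- sort(unique(as.integer(rank_grid)))
    if (any(rank_grid < 1L)) stop("ranks must be >= 1")
    fold_cap <- min(m - 1L, floor(n * (cv_folds - 1L) / cv_folds) - 1L)
    if (any(rank_grid > fold_cap)) {
      warning(sprintf("rank grid clipped to <= %d (limited by fold size / M)",
                      fold_cap))
      rank_grid <- unique(pmin(rank_grid, fold_cap))
    }
    folds <- contiguous_folds(n, cv_folds)
    cv_err <- stats::setNames(numeric(length(rank_grid)),
                              as.character(rank_grid))
    for (f in seq_along(folds)) {
      te <- folds[[f]]; tr_idx <- setdiff(seq_len(n), te)
      xtr <- x[tr_idx, , drop = FALSE]; xte <- x[te, , drop = FALSE]
      for (i in seq_len(m)) {
        sv <- svd(xtr[, -i, drop = FALSE])
        uty <- crossprod(sv$u, xtr[, i])
        for (g in seq_along(rank_grid)) {
          k <- min(rank_grid[g], length(sv$d))
          b <- sv$v[, seq_len(k), drop = FALSE] %*%
            (uty[seq_len(k)] / sv$d[seq_len(k)])
          cv_err[g] <- cv_err[g] +
            sum((xte[, i] - xte[, -i, drop = FALSE] %*% b)^2)
        }
      }
    }
    rank_k <- rank_grid[which.min(cv_err)]  # ascending grid: ties -> smaller
  }
  b_mat <- matrix(0, m, m)
  for (i in seq_len(m)) {
    sv <- svd(x[, -i, drop = FALSE])
    k <- min(rank_k, sum(sv$d > sv$d[1] * 1e-12))
    uty <- crossprod(sv$u[, seq_len(k), drop = FALSE], x[, i])
    b_mat[i, -i] <- sv$v[, seq_len(k), drop = FALSE] %*% (uty / sv$d[seq_len(k)])
  }
  structure(list(B = b_mat, rank_k = as.integer(rank_k), fit_frames = n,
                 M = m, cv_error = cv_err),
            class = "connectotype")
}

default_rank_grid <- function(m, n) {
  hi <- min(m - 1L, n - 1L)
  if (hi <= 2L) return(seq_len(max(hi, 1L)))
  unique(round(exp(seq(log(2), log(hi), length.out = 10))))
}

contiguous_folds <- function(n, k) {
  k <- max(2L, min(as.integer(k), n %/% 2L))
  bounds <- round(seq(0, n, length.out = k + 1))
  lapply(seq_len(k), function(i) (bounds[i] + 1):bounds[i + 1])
}

#' @export
print.connectotype <- function(x, ...) {
  cat(sprintf("connectotype: %d ROIs, truncation rank %d, fit on %d frames\n",
              x$M, x$rank_k, x$fit_frames))
  invisible(x)
}

#' @export
coef.connectotype <- function(object, ...) object$B

#' @export
summary.connectotype <- function(object, ...) {
  b <- object$B[row(object$B) != col(object$B)]
  out <- list(M = object$M, rank_k = object$rank_k,
              fit_frames = object$fit_frames,
              coef_range = range(b), coef_sd = stats::sd(b),
              cv_error = object$cv_error)
  class(out) <- "summary.connectotype"
  out
}

#' @export
print.summary.connectotype <- function(x, ...) {
  cat(sprintf("connectotype: %d ROIs, rank %d, %d frames\n",
              x$M, x$rank_k, x$fit_frames))
  cat(sprintf("off-diagonal coefficients: range [%.3g, %.3g], sd %.3g\n",
              x$coef_range[1], x$coef_range[2], x$coef_sd))
  if (!is.null(x$cv_error)) {
    cat("CV error by rank:\n")
    print(signif(x$cv_error, 4))
  }
  invisible(x)
}

#' Predict ROI time courses from a connectotype
#'
#' Frame-wise prediction: each ROI's predicted signal is the weighted sum of
#' all other ROIs' observed signals in the target scan,
#' `predicted = observed %*% t(B)`.
#'
#' @param object a `connectotype`.
#' @param newdata a [scan_timeseries] or frames x M matrix (retained frames
#'   are used); M must match the model.
#' @param ... unused.
#' @return numeric frames x M matrix of predictions.
#' @export
predict.connectotype <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "scan_timeseries")) retained(newdata)
       else as.matrix(newdata)
  if (ncol(x) != object$M)
    stop(sprintf("model has %d ROIs but target has %d columns",
                 object$M, ncol(x)))
  x %*% t(object$B)
}

#' Per-ROI prediction-observation similarity
#'
#' Pearson correlation between predicted and observed time courses, one
#' value per ROI. ROIs whose predicted or observed column has zero variance
#' have undefined correlation; they are marked invalid and excluded from the
#' mean.
#'
#' @param predicted,observed equal-shape numeric matrices (frames x M).
#' @return object of class `similarity_profile` with `r_per_roi`, `mean_r`
#'   and `valid_mask`.
#' @export
similarity <- function(predicted, observed) {
  predicted <- as.matrix(predicted); observed <- as.matrix(observed)
  if (!all(dim(predicted) == dim(observed)))
    stop("predicted and observed must have identical shapes")
  if (nrow(predicted) < 3L) stop("need at least 3 retained frames")
  pc <- predicted - rep(colMeans(predicted), each = nrow(predicted))
  oc <- observed - rep(colMeans(observed), each = nrow(observed))
  sp <- sqrt(colSums(pc^2)); so <- sqrt(colSums(oc^2))
  valid <- sp > 0 & so > 0
  r <- rep(NA_real_, ncol(predicted))
  r[valid] <- colSums(pc[, valid, drop = FALSE] * oc[, valid, drop = FALSE]) /
    (sp[valid] * so[valid])
  r[valid] <- pmin(pmax(r[valid], -1), 1)
  structure(list(r_per_roi = r, mean_r = mean(r[valid]), valid_mask = valid),
            class = "similarity_profile")
}

#' @export
print.similarity_profile <- function(x, ...) {
  cat(sprintf("similarity_profile: mean r = %.4f over %d/%d valid ROIs\n",
              x$mean_r, sum(x$valid_mask), length(x$valid_mask)))
  invisible(x)
}

#' Fisher z-transform of a correlation
#'
#' `z = atanh(r)`. Correlations within 1e-12 of +/-1 are clamped before the
#' transform (with a message) so that numerically saturated correlations
#' stay finite; values strictly outside `[-1, 1]` are an error.
#'
#' @param r numeric vector of correlations.
#' @return numeric vector of z values.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) stop("|r| > 1 is not a correlation")
  clamp <- abs(r) >= 1 - 1e-12 & !is.na(r)
  if (any(clamp)) {
    message(sum(clamp), " correlation(s) at +/-1 clamped before Fisher z")
    r[clamp] <- sign(r[clamp]) * (1 - 1e-12)
  }
  atanh(r)
}

#' Pearson-correlation connectivity matrix (comparison utility)
#'
#' The classical functional-connectivity alternative to the connectotype:
#' the M x M Pearson correlation matrix of the ROI time courses. Provided
#' as a thin feature-extraction alternative for side-by-side comparisons,
#' not as a modeled pathway.
#'
#' @param ts a [scan_timeseries] or frames x M matrix.
#' @return M x M correlation matrix.
#' @export
correlation_connectivity <- function(ts) {
  x <- if (inherits(ts, "scan_timeseries")) retained(ts) else as.matrix(ts)
  stats::cor(x)
}
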