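# Shared fixtures and independent oracles for the test suite.

# Independent truncated-SVD least-squares oracle: reconstruct the rank-k
# matrix explicitly and take its Moore-Penrose pseudoinverse via MASS::ginv.
tsvd_oracle <- function(z, y, k) {
  sv <- svd(z)
  k <- min(k, sum(sv$d > 0))
  zk <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k) %*% t(sv$v[, seq_len(k), drop = FALSE])
  drop(MASS::ginv(zk) %*% y)
}

# brute-force connectotype at a fixed rank, via the oracle per ROI
connectotype_oracle <- function(x, k) {
  m <- ncol(x)
  b <- matrix(0, m, m)
  for (i in seq_len(m))
    b[i, -i] <- tsvd_oracle(x[, -i, drop = FALSE], x[, i], k)
  b
}

# small correlated multivariate time-series matrix
random_ts_matrix <- function(n, m, seed = 1) {
  set.seed(seed)
  mix <- diag(m) + matrix(rnorm(m * m, 0, 0.3), m)
  matrix(rnorm(n * m), n) %*% mix
}

# tiny two-family cohort (one sibling pair + singletons), one scan each
tiny_cohort <- function(n_singletons = 2) {
  subjects <- data.frame(
    subject_id = c("A", "B", paste0("X", seq_len(n_singletons))),
    family_id = c("F1", "F1", paste0("G", seq_len(n_singletons))))
  scans <- data.frame(scan_id = paste0(subjects$subject_id, "_v1"),
                      subject_id = subjects$subject_id, session = 1)
  cohort(subjects, scans,
         data.frame(subject_a = "A", subject_b = "B", class = "sibling"))
}

# deterministic small synthetic bundle for classifier/heritability unit tests
small_bundle <- function(seed = 42, M = 12, frames = 80,
                         templates = c(mz = 2, dz = 2, sib = 4,
                                       singleton = 4)) {
  simulate_cohort(synthetic_spec(templates = templates, M = M,
                                 frames = frames, seed = seed))
}
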