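# shared fixtures, all generated in code

# random real-valued templates in [0, 1]
random_templates <- function(M, m, n) {
  lapply(seq_len(M), function(i) matrix(runif(m * n), m, n))
}

# random orthonormal n x d matrix via QR
random_orthonormal <- function(n, d) {
  qr.Q(qr(matrix(rnorm(n * n), n, n)))[, seq_len(d), drop = FALSE]
}

# a small binary mask with foreground at the given (row, col) pairs
mask_at <- function(nrow, ncol, pts) {
  m <- matrix(0, nrow, ncol)
  m[pts] <- 1
  m
}

# independent 2DPCA oracle: stacked centered templates -> SVD
oracle_2dpca <- function(mats, d) {
  Gbar <- Reduce(`+`, mats) / length(mats)
  A <- do.call(rbind, lapply(mats, function(G) G - Gbar))
  sv <- svd(A)
  ev <- rep(0, ncol(A))
  ev[seq_along(sv$d)] <- sv$d^2
  list(mean = Gbar, cov = crossprod(A), eigenvalues = ev,
       W = sv$v[, seq_len(d), drop = FALSE])
}

# column-wise distance oracle written independently of feature_distance
oracle_distance <- function(A, B) {
  tot <- 0
  for (k in seq_len(ncol(A))) tot <- tot + sqrt(sum((A[, k] - B[, k])^2))
  tot
}

# small deterministic walking population shared across tests
fixture_population <- function(n_subjects = 6, seqs = 2, frames = 30,
                               seed = 42, ...) {
  generate_population(n_subjects, seqs, frames, seed = seed, ...)
}

split_gallery_probe <- function(pop) {
  first <- vapply(pop, function(s) s$sequence_id == "seq01", logical(1))
  list(gallery = pop[first], probe = pop[!first])
}
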