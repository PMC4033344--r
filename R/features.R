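.template_values <- function(x) {
  if (inherits(x, "gait_template")) x$values
  else if (is.matrix(x) && is.numeric(x)) x
  else stop("expected a gait_template or a numeric matrix")
}

# eigenvector sign convention: largest-magnitude component positive
.fix_signs <- function(V) {
  for (k in seq_len(ncol(V))) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) V[, k] <- -V[, k]
  }
  V
}

#' Fit a 2DPCA projection basis over training templates
#'
#' Two-dimensional PCA operates on the template matrices directly instead
#' of flattening them. With training templates \eqn{G_1,\dots,G_M} of
#' size m x n and element-wise mean \eqn{\bar G}, the image covariance
#' matrix is the n x n sum
#' \deqn{C_t = \sum_{i=1}^{M} (G_i - \bar G)^\top (G_i - \bar G),}
#' and the projection axes are the unit eigenvectors of \eqn{C_t} with
#' the d largest eigenvalues. The sum is deliberately unnormalized (no
#' 1/M): eigenvectors, and hence all projections and distances, are
#' unchanged by the scaling, and the eigenvalues are reported on the
#' same unnormalized scale.
#'
#' @param templates List of `gait_template`s (or plain matrices) of
#'   identical dimensions, length >= 2.
#' @param d Number of projection axes, `1 <= d <= n`. Default 20.
#' @return Object of class `gait_basis`: `mean` (m x n), `cov` (n x n),
#'   `eigenvalues` (length n, descending), `W` (n x d, unit columns,
#'   eigenvalue order, sign fixed by largest-magnitude component
#'   positive), `d`, `method = "2dpca"`.
#' @export
fit_basis <- function(templates, d = 20) {
  if (!is.list(templates) || length(templates) < 2L)
    stop("need at least 2 training templates")
  mats <- lapply(templates, .template_values)
  dims <- dim(mats[[1L]])
  for (i in seq_along(mats))
    if (!identical(dim(mats[[i]]), dims))
      stop("template ", i, " has mismatched dimensions")
  n <- dims[2L]
  d <- as.integer(d)
  if (d < 1L || d > n)
    stop("d must be between 1 and the template width n = ", n)
  Gbar <- Reduce(`+`, mats) / length(mats)
  Ct <- matrix(0, n, n)
  for (Gm in mats) {
    Gc <- Gm - Gbar
    Ct <- Ct + crossprod(Gc)
  }
  e <- eigen(Ct, symmetric = TRUE)
  W <- .fix_signs(e$vectors[, seq_len(d), drop = FALSE])
  structure(list(mean = Gbar, cov = Ct, eigenvalues = e$values,
                 W = W, d = d, method = "2dpca"),
            class = "gait_basis")
}

#' @export
print.gait_basis <- function(x, ...) {
  cat(sprintf("<gait_basis:%s> templates %dx%d, d=%d, top eigenvalue %.4g\n",
              x$method, nrow(x$mean), ncol(x$mean), x$d, x$eigenvalues[1L]))
  invisible(x)
}

#' Scatter trace of the projected features along a candidate axis
#'
#' For a unit column vector w the total scatter of the projections
#' `G w` over the training set equals the quadratic form `w' C_t w`
#' (the trace of the projected scatter matrix). It is maximized over
#' unit vectors by the top eigenvector of `C_t`, where it equals the
#' largest eigenvalue.
#'
#' @param basis A `gait_basis`.
#' @param w Numeric vector of length n with `|w| = 1` (tolerance 1e-6).
#' @return The scalar `w' C_t w`.
#' @export
scatter_trace <- function(basis, w) {
  stopifnot(inherits(basis, "gait_basis"))
  w <- as.numeric(w)
  if (length(w) != ncol(basis$cov))
    stop("candidate axis has wrong length")
  if (abs(sqrt(sum(w * w)) - 1) > 1e-6)
    stop("candidate axis must be a unit vector")
  drop(crossprod(w, basis$cov %*% w))
}

#' Project a template onto a 2DPCA basis
#'
#' The feature matrix is \eqn{Y = G W}, i.e. column k is \eqn{Y_k = G
#' W_k}, assembled in descending-eigenvalue order. The raw template is
#' projected (no mean subtraction): centering shifts every feature
#' matrix by the same constant and cancels in all distances.
#'
#' @param template `gait_template` or matrix matching the basis.
#' @param basis A `gait_basis`.
#' @return Object of class `gait_features`: an m x d matrix with
#'   attributes `subject_id`, `sequence_id`, `method`.
#' @export
project_template <- function(template, basis) {
  stopifnot(inherits(basis, "gait_basis"))
  G <- .template_values(template)
  if (!identical(dim(G), dim(basis$mean)))
    stop("template dimensions do not match the basis")
  Y <- G %*% basis$W
  structure(Y, class = c("gait_features", class(Y)),
            subject_id = if (inherits(template, "gait_template"))
              template$subject_id else "unknown",
            sequence_id = if (inherits(template, "gait_template"))
              template$sequence_id else "seq",
            method = "2dpca")
}

#' Distance between two feature matrices
#'
#' The sum over components of the Euclidean norms of the column
#' differences:
#' \deqn{d(Y^{(i)}, Y^{(j)}) = \sum_{k=1}^{d} \lVert Y^{(i)}_k -
#' Y^{(j)}_k \rVert_2.}
#' A sum of norms, so it is symmetric, zero iff the matrices are equal,
#' and satisfies the triangle inequality. For 1-column matrices (the
#' vectorized-PCA baseline) it reduces to the plain Euclidean distance.
#'
#' @param a,b `gait_features` (or plain matrices) of identical shape.
#' @return Non-negative scalar.
#' @export
feature_distance <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  if (!is.matrix(a)) a <- as.matrix(a)
  if (!is.matrix(b)) b <- as.matrix(b)
  if (!identical(dim(a), dim(b)))
    stop("feature matrices have mismatched shapes")
  diff <- a - b
  sum(sqrt(colSums(diff * diff)))
}

#' Reconstruct a template from its 2DPCA features
#'
#' The rank-d reconstruction \eqn{\tilde G = \sum_{k=1}^{d} Y_k
#' W_k^\top}. With a complete basis (d = n) the reconstruction is exact.
#' `components` selects a sub-range of axes so the individual
#' sub-images \eqn{Y_k W_k^\top} can be inspected.
#'
#' @param features `gait_features` from [project_template()].
#' @param basis The `gait_basis` used for the projection.
#' @param components Integer vector of component indices to include
#'   (default all; `integer(0)` gives the zero grid).
#' @return Numeric m x n matrix.
#' @export
reconstruct_template <- function(features, basis, components = NULL) {
  stopifnot(inherits(basis, "gait_basis"))
  Y <- unclass(features)
  if (ncol(Y) != basis$d) stop("feature columns do not match the basis d")
  if (is.null(components)) components <- seq_len(basis$d)
  if (length(components) == 0L)
    return(matrix(0, nrow(Y), nrow(basis$W)))
  if (any(components < 1L) || any(components > basis$d))
    stop("component indices out of range")
  Y[, components, drop = FALSE] %*% t(basis$W[, components, drop = FALSE])
}

#' Vectorized-PCA baseline over flattened templates
#'
#' Classical PCA on the column-major flattened templates: the (mn) x
#' (mn) covariance of the mean-centered vectors is eigendecomposed and
#' templates are projected onto the top d eigenvectors. This is the
#' baseline 2DPCA is compared against; its covariance grows with the
#' square of the pixel count while the image covariance of 2DPCA stays
#' n x n.
#'
#' @param templates List of templates as in [fit_basis()].
#' @param d Number of components; must not exceed the covariance rank
#'   (at most M - 1 for M templates).
#' @return Object of class `gait_pca_basis`: `mean` (length mn),
#'   `eigenvalues`, `W` (mn x d), `dims` = c(m, n), `d`,
#'   `method = "pca"`.
#' @export
fit_pca_baseline <- function(templates, d = 20) {
  if (!is.list(templates) || length(templates) < 2L)
    stop("need at least 2 training templates")
  mats <- lapply(templates, .template_values)
  dims <- dim(mats[[1L]])
  for (i in seq_along(mats))
    if (!identical(dim(mats[[i]]), dims))
      stop("template ", i, " has mismatched dimensions")
  X <- vapply(mats, as.numeric, numeric(prod(dims)))   # mn x M
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- tcrossprod(Xc)                                  # (mn) x (mn), sum form
  e <- eigen(C, symmetric = TRUE)
  tol <- max(e$values[1L], 0) * 1e-9
  rank <- sum(e$values > tol)
  d <- as.integer(d)
  if (d < 1L || d > rank)
    stop("d = ", d, " exceeds the covariance rank (", rank, ")")
  W <- .fix_signs(e$vectors[, seq_len(d), drop = FALSE])
  structure(list(mean = mu, eigenvalues = e$values, W = W,
                 dims = dims, d = d, method = "pca"),
            class = "gait_pca_basis")
}

#' @rdname fit_pca_baseline
#' @param template `gait_template` or matrix matching the basis.
#' @param basis A `gait_pca_basis`.
#' @return `project_pca()` returns a `gait_features` (a d x 1 column
#'   matrix) so the same distance and gallery machinery applies.
#' @export
project_pca <- function(template, basis) {
  stopifnot(inherits(basis, "gait_pca_basis"))
  G <- .template_values(template)
  if (!identical(dim(G), basis$dims))
    stop("template dimensions do not match the basis")
  y <- crossprod(basis$W, as.numeric(G) - basis$mean)  # d x 1
  structure(y, class = c("gait_features", class(y)),
            subject_id = if (inherits(template, "gait_template"))
              template$subject_id else "unknown",
            sequence_id = if (inherits(template, "gait_template"))
              template$sequence_id else "seq",
            method = "pca")
}

#' @rdname fit_pca_baseline
#' @param features A d x 1 feature column from [project_pca()].
#' @export
reconstruct_pca <- function(features, basis) {
  stopifnot(inherits(basis, "gait_pca_basis"))
  y <- as.numeric(unclass(features))
  if (length(y) != basis$d) stop("feature length does not match basis d")
  matrix(basis$mean + basis$W %*% y, basis$dims[1L], basis$dims[2L])
}

#' Serialize / deserialize a projection basis
#'
#' Portable container: a text header (one `key=value` per line, ended by
#' a blank line) followed by the flat arrays as little-endian IEEE-754
#' doubles in a fixed order (mean, cov or none, eigenvalues, W). The
#' round-trip is bit-exact.
#'
#' @param basis A `gait_basis` or `gait_pca_basis`.
#' @param file Path to write / read.
#' @return `read_basis()` returns the basis object; `write_basis()` the
#'   file path invisibly.
#' @export
write_basis <- function(basis, file) {
  is2d <- inherits(basis, "gait_basis")
  if (!is2d && !inherits(basis, "gait_pca_basis"))
    stop("expected a gait_basis or gait_pca_basis")
  dims <- if (is2d) dim(basis$mean) else basis$dims
  hdr <- c("gaitdiff-basis-v1",
           paste0("method=", basis$method),
           paste0("rows=", dims[1L]), paste0("cols=", dims[2L]),
           paste0("d=", basis$d),
           paste0("n_eigenvalues=", length(basis$eigenvalues)),
           "")
  con <- file(file, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  writeBin(as.numeric(basis$mean), con, size = 8, endian = "little")
  if (is2d) writeBin(as.numeric(basis$cov), con, size = 8, endian = "little")
  writeBin(as.numeric(basis$eigenvalues), con, size = 8, endian = "little")
  writeBin(as.numeric(basis$W), con, size = 8, endian = "little")
  invisible(file)
}

#' @rdname write_basis
#' @export
read_basis <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "gaitdiff-basis-v1"))
    stop("not a gaitdiff basis file: ", file)
  hdr <- list()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L || ln == "") break
    p <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    hdr[[p[[1L]]]] <- p[[2L]]
  }
  m <- as.integer(hdr$rows); n <- as.integer(hdr$cols)
  d <- as.integer(hdr$d); ne <- as.integer(hdr$n_eigenvalues)
  rd <- function(k) readBin(con, "numeric", n = k, size = 8, endian = "little")
  if (identical(hdr$method, "2dpca")) {
    mean <- matrix(rd(m * n), m, n)
    cov <- matrix(rd(n * n), n, n)
    ev <- rd(ne)
    W <- matrix(rd(n * d), n, d)
    structure(list(mean = mean, cov = cov, eigenvalues = ev, W = W,
                   d = d, method = "2dpca"), class = "gait_basis")
  } else {
    mean <- rd(m * n)
    ev <- rd(ne)
    W <- matrix(rd(m * n * d), m * n, d)
    structure(list(mean = mean, eigenvalues = ev, W = W,
                   dims = c(m, n), d = d, method = "pca"),
              class = "gait_pca_basis")
  }
}
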