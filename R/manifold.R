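#' Pairwise Euclidean distance matrix between samples
#'
#' @param x an [expr_set()] (or a plain numeric matrix, samples x genes).
#' @return An object of class `slle_dist`: list with `d` (symmetric N x N
#'   matrix, zero diagonal), `kind = "euclidean"`, `lambda_s = NA`.
#' @export
euclidean_distance_matrix <- function(x) {
  v <- if (inherits(x, "expr_set")) x$values else as.matrix(x)
  if (nrow(v) < 2L) stop("at least 2 samples required")
  if (!all(is.finite(v))) stop("non-finite values in input matrix")
  d <- as.matrix(stats::dist(v, method = "euclidean"))
  dimnames(d) <- NULL
  diag(d) <- 0
  structure(list(d = d, kind = "euclidean", lambda_s = NA_real_),
            class = "slle_dist")
}

#' Class-label-inflated (supervised) distance matrix
#'
#' Inflates between-class distances: D'(i,j) = D(i,j) + lambda_s * max(D)
#' when samples i and j carry different labels, and leaves same-class
#' distances untouched. With `lambda_s = 0` the result equals the input
#' (unsupervised limit); with `lambda_s = 1` neighborhoods become maximally
#' class-pure.
#'
#' @param d_euc an `slle_dist` of kind `"euclidean"`.
#' @param labels per-sample labels, exactly 2 distinct values.
#' @param lambda_s supervision strength in \[0, 1\].
#' @return An `slle_dist` of kind `"supervised"` with `lambda_s` recorded.
#' @export
supervised_distance_matrix <- function(d_euc, labels, lambda_s = 1) {
  stopifnot(inherits(d_euc, "slle_dist"))
  if (d_euc$kind != "euclidean") stop("input distances must be of kind 'euclidean'")
  if (!is.numeric(lambda_s) || length(lambda_s) != 1L || is.na(lambda_s) ||
      lambda_s < 0 || lambda_s > 1) {
    stop("lambda_s must be a single value in [0, 1]")
  }
  labels <- as.character(labels)
  n <- nrow(d_euc$d)
  if (length(labels) != n) stop("labels length must match distance matrix")
  if (length(unique(labels)) != 2L) stop("exactly 2 label classes required")
  differ <- outer(labels, labels, "!=")
  d <- d_euc$d + lambda_s * max(d_euc$d) * differ
  diag(d) <- 0
  structure(list(d = d, kind = "supervised", lambda_s = lambda_s),
            class = "slle_dist")
}

#' k-nearest-neighbor graph from a distance matrix
#'
#' Ties are broken by ascending sample index, so the graph is deterministic
#' across platforms.
#'
#' @param d an `slle_dist`.
#' @param k neighborhood size, `1 <= k <= N - 1`.
#' @return An object of class `neighbor_graph`: list with `k` and
#'   `neighbors`, an N x k integer matrix (row i = indices of the k nearest
#'   samples to i, nearest first, i excluded).
#' @export
knn_neighbors <- function(d, k) {
  stopifnot(inherits(d, "slle_dist"))
  n <- nrow(d$d)
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 1L || k > n - 1L) {
    stop("k must be an integer in [1, N-1]; got k=", k, " with N=", n)
  }
  k <- as.integer(k)
  nb <- matrix(0L, n, k)
  idx <- seq_len(n)
  for (i in idx) {
    ord <- order(d$d[i, ], idx)         # stable: (distance, index) ascending
    ord <- ord[ord != i]
    nb[i, ] <- ord[seq_len(k)]
  }
  structure(list(k = k, neighbors = nb, dist_kind = d$kind),
            class = "neighbor_graph")
}

#' Locally linear reconstruction weights
#'
#' For each sample i the local Gram matrix over its neighbors,
#' G_jl = (x_i - x_j) . (x_i - x_l), is solved for the weights minimizing
#' the reconstruction error || x_i - sum_j W_ij x_j ||^2 subject to the
#' weights summing to 1. G is singular whenever k exceeds the local rank,
#' so `reg_tol * trace(G)` is added to its diagonal before solving
#' (`reg_tol = 0` is allowed for exactly solvable small cases).
#'
#' @param x an [expr_set()] or numeric matrix (samples x genes); weights are
#'   always solved from these original coordinates, whichever distance
#'   defined the neighborhoods.
#' @param g a `neighbor_graph` over the same samples.
#' @param reg_tol non-negative Gram regularization scale (default `1e-3`).
#' @return An object of class `weight_matrix`: list with `w` (N x N, rows
#'   sum to 1, support on neighbors), `graph`, `reg_tol`, and `recon_error`
#'   (per-sample squared reconstruction error).
#' @export
reconstruction_weights <- function(x, g, reg_tol = 1e-3) {
  v <- if (inherits(x, "expr_set")) x$values else as.matrix(x)
  stopifnot(inherits(g, "neighbor_graph"))
  n <- nrow(v)
  if (nrow(g$neighbors) != n) stop("neighbor graph inconsistent with input matrix")
  if (!is.numeric(reg_tol) || reg_tol < 0) stop("reg_tol must be >= 0")
  k <- g$k
  w <- matrix(0, n, n)
  eps <- numeric(n)
  for (i in seq_len(n)) {
    nbr <- g$neighbors[i, ]
    z <- sweep(v[nbr, , drop = FALSE], 2L, v[i, ])   # neighbors minus x_i
    gram <- z %*% t(z)
    if (reg_tol > 0) {
      tr <- sum(diag(gram))
      diag(gram) <- diag(gram) + reg_tol * (if (tr > 0) tr else 1)
    }
    wi <- tryCatch(solve(gram, rep(1, k)),
                   error = function(e) {
                     stop("singular local Gram matrix at sample ", i,
                          "; increase reg_tol", call. = FALSE)
                   })
    wi <- wi / sum(wi)
    w[i, nbr] <- wi
    eps[i] <- sum((v[i, ] - drop(wi %*% v[nbr, , drop = FALSE]))^2)
  }
  structure(list(w = w, graph = g, reg_tol = reg_tol, recon_error = eps),
            class = "weight_matrix")
}

#' Embedding cost matrix M = (I - W)' (I - W)
#'
#' Equivalent to the sparse sum form
#' M_ij = delta_ij - W_ij - W_ji + sum_k W_ki W_kj. For any row-stochastic
#' W the result is symmetric positive semidefinite and annihilates the
#' all-ones vector.
#'
#' @param w a `weight_matrix` (or a plain row-stochastic matrix).
#' @return An object of class `cost_matrix`: list with `m`.
#' @export
embedding_cost_matrix <- function(w) {
  wm <- if (inherits(w, "weight_matrix")) w$w else as.matrix(w)
  if (nrow(wm) != ncol(wm)) stop("weight matrix must be square")
  iw <- diag(nrow(wm)) - wm
  m <- crossprod(iw)
  m <- (m + t(m)) / 2
  structure(list(m = m), class = "cost_matrix")
}

#' Low-dimensional embedding from the cost matrix
#'
#' Takes the eigenvectors of M belonging to the d+1 smallest eigenvalues and
#' discards the translation mode (the constant eigenvector at eigenvalue 0).
#' When the near-null space of M has dimension > 1 (disconnected neighbor
#' graphs, e.g. fully class-pure supervised neighborhoods), the constant
#' direction is projected out of that subspace and the remainder is
#' re-orthonormalized, which keeps the retained coordinates exactly
#' centered. Columns are scaled by sqrt(N) so that (1/N) Y'Y = I, and each
#' column's sign is fixed so its largest-magnitude entry is positive.
#'
#' @param m a `cost_matrix`.
#' @param d target dimension, `d <= N - 2`.
#' @param null_tol eigenvalues below this are treated as the null space.
#' @return An object of class `lle_embedding`: list with `y` (N x d),
#'   `d`, and `eigenvalues` (the d retained eigenvalues, ascending).
#' @export
lle_embed <- function(m, d, null_tol = 1e-8) {
  mm <- if (inherits(m, "cost_matrix")) m$m else as.matrix(m)
  n <- nrow(mm)
  if (!is.numeric(d) || length(d) != 1L || d != round(d) || d < 1L || d > n - 2L) {
    stop("embedding dimension d must be an integer in [1, N-2]; got d=", d,
         " with N=", n)
  }
  d <- as.integer(d)
  eig <- eigen(mm, symmetric = TRUE)
  vals <- rev(eig$values)                 # ascending
  vecs <- eig$vectors[, rev(seq_len(n)), drop = FALSE]

  null_idx <- which(vals < null_tol)
  if (length(null_idx) == 0L) null_idx <- 1L
  ones <- rep(1 / sqrt(n), n)
  u0 <- vecs[, null_idx, drop = FALSE]
  # project the constant direction out of the near-null block
  resid <- u0 - ones %*% crossprod(ones, u0)
  sv <- svd(resid)
  keep0 <- sv$u[, sv$d > 1e-6, drop = FALSE]
  rest_idx <- setdiff(seq_len(n), null_idx)
  y <- cbind(keep0, vecs[, rest_idx, drop = FALSE])
  yvals <- c(rep(0, ncol(keep0)), vals[rest_idx])
  if (ncol(y) < d) stop("not enough non-trivial eigenvectors for d=", d)
  y <- y[, seq_len(d), drop = FALSE]
  yvals <- yvals[seq_len(d)]

  # deterministic sign: largest-magnitude entry positive
  for (j in seq_len(d)) {
    piv <- which.max(abs(y[, j]))
    if (y[piv, j] < 0) y[, j] <- -y[, j]
  }
  y <- y * sqrt(n)                        # (1/N) Y'Y = I
  structure(list(y = y, d = d, eigenvalues = yvals), class = "lle_embedding")
}

#' Supervised locally linear embedding
#'
#' Pipeline: Euclidean distances -> class-inflated distances (strength
#' `lambda_s`) -> k-nearest-neighbor graph -> reconstruction weights from
#' the original coordinates -> cost matrix -> bottom-eigenvector embedding.
#' With `lambda_s = 0` this is plain unsupervised LLE. By default only
#' neighbor selection uses the supervised distances; set
#' `supervised_weights = TRUE` to use them in the Gram matrix too (the
#' weights are then solved in a space where the class indicator is an extra
#' coordinate; this is a non-default variant).
#'
#' @param x an [expr_set()].
#' @param k neighborhood size (default 5).
#' @param lambda_s supervision strength in \[0, 1\] (default 1; 0 gives
#'   plain LLE).
#' @param d embedding dimension (default 2, twice the number of classes
#'   being a reasonable upper scale for two-class data).
#' @param reg_tol Gram regularization scale (default 1e-3).
#' @param supervised_weights see Description.
#' @return An `lle_embedding`.
#' @export
slle <- function(x, k = 5, lambda_s = 1, d = 2, reg_tol = 1e-3,
                 supervised_weights = FALSE) {
  stopifnot(inherits(x, "expr_set"))
  de <- euclidean_distance_matrix(x)
  dn <- if (lambda_s > 0) supervised_distance_matrix(de, x$labels, lambda_s) else de
  g <- knn_neighbors(dn, k)
  xv <- x$values
  if (supervised_weights && lambda_s > 0) {
    # append a class-indicator coordinate so between-class displacements are
    # penalized inside the Gram matrix as well (non-default variant)
    ind <- as.numeric(factor(x$labels))
    xv <- cbind(xv, ind * sqrt(lambda_s) * max(de$d))
  }
  w <- reconstruction_weights(xv, g, reg_tol)
  m <- embedding_cost_matrix(w)
  lle_embed(m, d)
}
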