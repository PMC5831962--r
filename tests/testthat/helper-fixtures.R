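# in-code fixtures shared across test files

# random two-class expression set, samples x genes
random_expr <- function(n = 12, d = 6, seed = 1, sep = 0) {
  set.seed(seed)
  labels <- rep(c("a", "b"), length.out = n)
  v <- matrix(rnorm(n * d), n, d)
  v[labels == "b", ] <- v[labels == "b", ] + sep
  expr_set(v, labels)
}

# constrained least-squares oracle for reconstruction weights: solve the
# KKT system of min ||x_i - sum w_j x_j||^2 s.t. sum w = 1 directly
# (independent route: full (k+1)-dim bordered system on the covariance of
# the neighbor coordinates, not the local Gram of differences)
cls_weights_oracle <- function(xi, nbrs) {
  k <- nrow(nbrs)
  a <- nbrs %*% t(nbrs)                    # k x k, <x_j, x_l>
  b <- drop(nbrs %*% xi)                   # k,   <x_j, x_i>
  kkt <- rbind(cbind(2 * a, 1), c(rep(1, k), 0))
  sol <- solve(kkt, c(2 * b, 1))
  unname(sol[seq_len(k)])
}

# exhaustive pair-counting AUC oracle
auc_pairs_oracle <- function(labels, scores, positive) {
  pos <- which(labels == positive)
  neg <- which(labels != positive)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}
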