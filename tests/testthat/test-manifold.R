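test_that("euclidean distances: known values and brute-force agreement", {
  x <- expr_set(rbind(c(0, 0), c(3, 4)), labels = c("a", "b"))
  d <- euclidean_distance_matrix(x)
  expect_equal(d$d[1, 2], 5)
  expect_equal(d$d[2, 1], 5)
  expect_equal(diag(d$d), c(0, 0))

  # duplicated rows -> zero distance
  y <- expr_set(rbind(c(1, 2), c(1, 2), c(0, 0)), labels = c("a", "a", "b"))
  expect_equal(euclidean_distance_matrix(y)$d[1, 2], 0)

  # brute-force per-pair oracle on random data
  set.seed(7)
  v <- matrix(rnorm(30), 3, 10)
  d3 <- euclidean_distance_matrix(expr_set(v, labels = c("a", "b", "a")))$d
  for (i in 1:3) for (j in 1:3) {
    expect_equal(d3[i, j], sqrt(sum((v[i, ] - v[j, ])^2)), tolerance = 1e-12)
  }

  v[1, 1] <- NA
  expect_error(expr_set(v, labels = c("a", "b", "a")), "missing")
})

test_that("supervised distances implement the class-inflation formula", {
  x <- random_expr(6, 4, seed = 2)
  de <- euclidean_distance_matrix(x)

  # lambda = 0: unsupervised limit, exact equality
  d0 <- supervised_distance_matrix(de, x$labels, 0)
  expect_identical(d0$d, de$d)
  expect_equal(d0$kind, "supervised")

  # direct substitution: entry 2 with max 10, lambda 1
  dm <- matrix(c(0, 2, 10, 2, 0, 3, 10, 3, 0), 3, 3)
  des <- structure(list(d = dm, kind = "euclidean", lambda_s = NA_real_),
                   class = "slle_dist")
  ds <- supervised_distance_matrix(des, c("p", "q", "p"), 1)
  expect_equal(ds$d[1, 2], 12)  # different classes: 2 + 1*10
  expect_equal(ds$d[1, 3], 10)  # same class: unchanged

  # entry-wise double-loop oracle at lambda = 0.5
  dh <- supervised_distance_matrix(de, x$labels, 0.5)
  mx <- max(de$d)
  for (i in 1:6) for (j in 1:6) {
    expected <- de$d[i, j] +
      if (i != j && x$labels[i] != x$labels[j]) 0.5 * mx else 0
    expect_equal(dh$d[i, j], expected, tolerance = 1e-12)
  }
  # dominance invariant
  expect_true(all(dh$d >= de$d - 1e-12))

  expect_error(supervised_distance_matrix(de, x$labels, 1.5), "lambda_s")
})

test_that("knn neighbor graphs are correct and deterministically tie-broken", {
  x <- expr_set(matrix(c(0, 1, 10), 3, 1), labels = c("a", "a", "b"))
  g <- knn_neighbors(euclidean_distance_matrix(x), 1)
  expect_equal(g$neighbors[2, ], 1L)   # middle point's nearest is 0

  # k = N-1: complete graph
  g2 <- knn_neighbors(euclidean_distance_matrix(x), 2)
  for (i in 1:3) expect_setequal(g2$neighbors[i, ], setdiff(1:3, i))

  # full-sort oracle per row
  x8 <- random_expr(8, 5, seed = 3)
  d8 <- euclidean_distance_matrix(x8)
  g8 <- knn_neighbors(d8, 3)
  for (i in 1:8) {
    ord <- setdiff(order(d8$d[i, ]), i)
    expect_equal(g8$neighbors[i, ], ord[1:3])
  }

  # ties broken by ascending index
  dt <- matrix(1, 4, 4); diag(dt) <- 0
  gt <- knn_neighbors(structure(list(d = dt, kind = "euclidean",
                                     lambda_s = NA_real_),
                                class = "slle_dist"), 2)
  expect_equal(gt$neighbors[4, ], c(1L, 2L))

  expect_error(knn_neighbors(d8, 8), "k must be")
})

test_that("reconstruction weights: hand case, singular case, LS oracle", {
  # point (0,0) with neighbors (1,0) and (0,1): w = (1/2, 1/2), eps = 1/2
  v <- rbind(c(0, 0), c(1, 0), c(0, 1))
  x <- expr_set(v, labels = c("a", "b", "a"))
  g <- structure(list(k = 2L, neighbors = rbind(c(2L, 3L), c(1L, 3L), c(1L, 2L)),
                      dist_kind = "euclidean"), class = "neighbor_graph")
  w <- reconstruction_weights(x, g, reg_tol = 0)
  expect_equal(w$w[1, 2:3], c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(w$recon_error[1], 0.5, tolerance = 1e-12)

  # collinear neighbors: singular at reg_tol = 0, symmetric at reg_tol > 0
  v2 <- rbind(c(0, 0), c(1, 0), c(-1, 0))
  x2 <- expr_set(v2, labels = c("a", "b", "a"))
  g2 <- structure(list(k = 2L, neighbors = rbind(c(2L, 3L), c(1L, 3L), c(1L, 2L)),
                      dist_kind = "euclidean"), class = "neighbor_graph")
  expect_error(reconstruction_weights(x2, g2, reg_tol = 0), "singular")
  w2 <- reconstruction_weights(x2, g2, reg_tol = 1e-6)
  expect_equal(w2$w[1, 2:3], c(0.5, 0.5), tolerance = 1e-9)

  # constrained-LS oracle, several random instances
  for (seed in 1:3) {
    xr <- random_expr(10, 6, seed = seed)
    gr <- knn_neighbors(euclidean_distance_matrix(xr), 3)
    wr <- reconstruction_weights(xr, gr, reg_tol = 0)
    for (i in 1:10) {
      nbr <- gr$neighbors[i, ]
      expected <- cls_weights_oracle(xr$values[i, ],
                                     xr$values[nbr, , drop = FALSE])
      expect_equal(unname(wr$w[i, nbr]), expected, tolerance = 1e-6)
    }
  }
})

test_that("weight rows sum to 1 and support stays on neighbors (property)", {
  for (seed in 1:5) {
    x <- random_expr(11, 4, seed = seed)
    g <- knn_neighbors(euclidean_distance_matrix(x), 4)
    w <- reconstruction_weights(x, g)
    expect_equal(rowSums(w$w), rep(1, 11), tolerance = 1e-9)
    for (i in 1:11) {
      off <- setdiff(which(w$w[i, ] != 0), g$neighbors[i, ])
      expect_length(off, 0)
    }
  }
})

test_that("cost matrix: sum form equals product form, PSD, null vector", {
  # degenerate W = 0 -> identity
  m0 <- embedding_cost_matrix(matrix(0, 4, 4))
  expect_equal(m0$m, diag(4))

  for (seed in 1:4) {
    x <- random_expr(6, 3, seed = seed)
    g <- knn_neighbors(euclidean_distance_matrix(x), 2)
    w <- reconstruction_weights(x, g)$w
    m <- embedding_cost_matrix(w)$m

    # sum form of the cost matrix, entry by entry
    ref <- matrix(0, 6, 6)
    for (i in 1:6) for (j in 1:6) {
      ref[i, j] <- (i == j) - w[i, j] - w[j, i] + sum(w[, i] * w[, j])
    }
    expect_equal(m, ref, tolerance = 1e-12)

    expect_equal(m, t(m), tolerance = 1e-9)
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
    expect_equal(drop(m %*% rep(1, 6)), rep(0, 6), tolerance = 1e-8)
  }
})

test_that("embedding matches a dense eigendecomposition oracle", {
  x <- random_expr(12, 5, seed = 9)
  g <- knn_neighbors(euclidean_distance_matrix(x), 4)
  m <- embedding_cost_matrix(reconstruction_weights(x, g))
  emb <- lle_embed(m, 3)

  eig <- eigen(m$m, symmetric = TRUE)
  vals <- rev(eig$values)
  # retained eigenvalues are the (2..d+1)-smallest
  expect_equal(emb$eigenvalues, vals[2:4], tolerance = 1e-8)
  # retained columns span the same eigenvectors up to sign
  vecs <- eig$vectors[, 12:1][, 2:4]
  for (j in 1:3) {
    expect_equal(abs(cor(emb$y[, j], vecs[, j])), 1, tolerance = 1e-6)
  }
  # orthogonal to the constant vector
  expect_equal(colSums(emb$y), rep(0, 3), tolerance = 1e-6)
  # scaling and centering invariants
  expect_equal(colMeans(emb$y), rep(0, 3), tolerance = 1e-8)
  expect_equal(crossprod(emb$y) / 12, diag(3), tolerance = 1e-6)

  expect_error(lle_embed(m, 11), "dimension d")
})

test_that("embedding recovers a 1-D manifold ordering", {
  set.seed(4)
  t <- seq(0, 1, length.out = 20)   # even spacing keeps the k=2 graph connected
  basis <- qr.Q(qr(matrix(rnorm(25), 5, 5)))[, 1]
  v <- outer(t, basis) + matrix(rnorm(100, sd = 1e-6), 20, 5)
  x <- expr_set(v, labels = rep(c("a", "b"), 10))
  g <- knn_neighbors(euclidean_distance_matrix(x), 2)
  emb <- lle_embed(embedding_cost_matrix(reconstruction_weights(x, g)), 1)
  expect_equal(abs(cor(emb$y[, 1], seq_along(t), method = "spearman")), 1)
})

test_that("slle: lambda 0 equals plain LLE; lambda 1 purifies neighborhoods", {
  x <- random_expr(14, 6, seed = 11)
  e0 <- slle(x, k = 4, lambda_s = 0, d = 2)
  de <- euclidean_distance_matrix(x)
  g <- knn_neighbors(de, 4)
  ref <- lle_embed(embedding_cost_matrix(reconstruction_weights(x, g)), 2)
  expect_identical(e0$y, ref$y)

  # two well-separated Gaussian classes: supervised neighbors are class-pure
  xs <- random_expr(20, 4, seed = 12, sep = 6)
  ds <- supervised_distance_matrix(euclidean_distance_matrix(xs), xs$labels, 1)
  gs <- knn_neighbors(ds, 5)
  for (i in 1:20) {
    expect_true(all(xs$labels[gs$neighbors[i, ]] == xs$labels[i]))
  }

  # embedding invariants on a 40-sample two-class set
  x40 <- random_expr(40, 8, seed = 13, sep = 3)
  e40 <- slle(x40, k = 5, lambda_s = 1, d = 2)
  expect_equal(colMeans(e40$y), rep(0, 2), tolerance = 1e-8)
  expect_equal(crossprod(e40$y) / 40, diag(2), tolerance = 1e-6)
})
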