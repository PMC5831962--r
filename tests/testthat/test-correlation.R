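test_that("tie-averaged ranks: known vectors and tie handling", {
  expect_equal(rank_with_ties(c(0.7, 0.3, 0.5, 0.2, 0.8)), c(4, 2, 3, 1, 5))
  expect_equal(rank_with_ties(c(0.9, 0.3, 0.4, 0.1, 0.7)), c(5, 2, 3, 1, 4))
  expect_equal(rank_with_ties(c(1, 2, 2, 3)), c(1, 2.5, 2.5, 4))
  expect_equal(rank_with_ties(c(5, 5, 5)), c(2, 2, 2))
  expect_error(rank_with_ties(c(1, NA, 2)), "finite")
})

test_that("rank sums equal N(N+1)/2 for arbitrary tie patterns (property)", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(2:40, 1)
    v <- sample(round(rnorm(n), sample(0:2, 1)))  # induces ties
    expect_identical(sum(rank_with_ties(v)), n * (n + 1) / 2)
    r <- rank_with_ties(v)
    expect_gte(min(r), 1); expect_lte(max(r), n)
  }
})

test_that("spearman_rho: worked example, identities, oracle on ties", {
  a1 <- c(0.7, 0.3, 0.5, 0.2, 0.8)
  a2 <- c(0.9, 0.3, 0.4, 0.1, 0.7)
  expect_equal(spearman_rho(a1, a2), 0.9, tolerance = 1e-15)
  # tie-free closed form: 1 - 6*sum(d^2)/(n(n^2-1)), here sum(d^2) = 2
  expect_equal(spearman_rho(a1, a2), 1 - 6 * 2 / (5 * 24), tolerance = 1e-15)

  expect_equal(spearman_rho(a1, a1), 1)
  expect_equal(spearman_rho(1:3, 3:1), -1)
  expect_error(spearman_rho(rep(2, 4), 1:4), "constant")

  # independent oracle on tied data: base R's Spearman
  set.seed(22)
  for (rep in 1:10) {
    a <- sample(round(rnorm(8), 1)); b <- sample(round(rnorm(8), 1))
    if (min(a) == max(a) || min(b) == max(b)) next
    expect_equal(spearman_rho(a, b), cor(a, b, method = "spearman"),
                 tolerance = 1e-12)
  }

  # invariance under strictly increasing transforms; symmetry
  a <- rnorm(15); b <- rnorm(15)
  expect_equal(spearman_rho(exp(a), b), spearman_rho(a, b), tolerance = 1e-12)
  expect_equal(spearman_rho(a, b), spearman_rho(b, a), tolerance = 1e-12)
  expect_lte(abs(spearman_rho(a, b)), 1 + 1e-12)
})

test_that("correlation_matrix matches pairwise calls", {
  set.seed(23)
  v <- matrix(rnorm(40), 8, 5)
  v <- cbind(v, v[, 1])               # duplicated attribute
  colnames(v) <- paste0("g", 1:6)
  cm <- correlation_matrix(v)
  expect_equal(diag(cm), rep(1, 6), ignore_attr = TRUE)
  expect_equal(cm[1, 6], 1)
  expect_equal(cm, t(cm))
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(cm[i, j], spearman_rho(v[, i], v[, j]), tolerance = 1e-12)
  }
})

test_that("redundancy filter: duplicates, boundaries, post-check oracle", {
  set.seed(24)
  a <- rnorm(20); c_ <- rnorm(20)
  v <- cbind(A = a, B = a, C = c_)
  log <- redundancy_filter(c("A", "B", "C"), v, threshold = 0.3)
  expect_equal(log$kept, c("A", "C"))
  expect_equal(log$removed$removed_id, "B")
  expect_equal(log$removed$kept_id, "A")
  expect_equal(abs(log$removed$rho), 1)

  # threshold 1 and no perfect correlations: nothing removed
  v2 <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("A", "B", "C")))
  log2 <- redundancy_filter(c("A", "B", "C"), v2, threshold = 1)
  expect_equal(log2$kept, c("A", "B", "C"))
  expect_equal(nrow(log2$removed), 0L)

  # planted coexpression blocks: exhaustive pairwise post-check
  set.seed(25)
  base <- matrix(rnorm(30 * 4), 30, 4)
  blocks <- do.call(cbind, lapply(1:4, function(b) {
    cbind(base[, b], base[, b] + rnorm(30, sd = 0.05),
          -base[, b] + rnorm(30, sd = 0.05))
  }))
  v3 <- cbind(blocks, matrix(rnorm(30 * 8), 30, 8))
  colnames(v3) <- paste0("g", seq_len(ncol(v3)))
  log3 <- redundancy_filter(colnames(v3), v3, threshold = 0.5)
  kept <- v3[, log3$kept, drop = FALSE]
  for (i in seq_len(ncol(kept) - 1)) for (j in (i + 1):ncol(kept)) {
    expect_lt(abs(spearman_rho(kept[, i], kept[, j])), 0.5)
  }
  # partition invariant
  expect_setequal(c(log3$kept, log3$removed$removed_id), colnames(v3))
  expect_length(intersect(log3$kept, log3$removed$removed_id), 0)
  expect_true(all(abs(log3$removed$rho) >= 0.5))

  # determinism given the order
  log3b <- redundancy_filter(colnames(v3), v3, threshold = 0.5)
  expect_identical(log3, log3b)

  # signed mode keeps negatively coexpressed attributes
  neg <- cbind(A = a, B = -a + rnorm(20, sd = 0.01))
  expect_equal(redundancy_filter(c("A", "B"), neg, 0.5)$kept, "A")
  expect_equal(redundancy_filter(c("A", "B"), neg, 0.5, absolute = FALSE)$kept,
               c("A", "B"))

  # constant attribute dropped with warning
  vc <- cbind(A = a, K = rep(1, 20))
  expect_warning(logc <- redundancy_filter(c("A", "K"), vc, 0.3), "constant")
  expect_equal(logc$kept, "A")

  expect_error(redundancy_filter(character(0), v, 0.3), "empty")
})

test_that("lowering the threshold never increases survivors (property)", {
  set.seed(26)
  v <- matrix(rnorm(25 * 15), 25, 15,
              dimnames = list(NULL, paste0("g", 1:15)))
  v[, 2] <- v[, 1] + rnorm(25, sd = 0.3)
  v[, 3] <- v[, 1] + rnorm(25, sd = 0.6)
  n_kept <- vapply(seq(0, 1, 0.25), function(th) {
    length(redundancy_filter(colnames(v), v, th)$kept)
  }, numeric(1))
  expect_true(all(diff(n_kept) >= 0))
})
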