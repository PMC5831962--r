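#' PCA explained-variance contribution profile
#'
#' Centers the input, takes the eigen-spectrum of the sample covariance,
#' and normalizes it into explained-variance fractions (the quantities a
#' Pareto diagram plots) plus the cumulative curve and the component
#' loadings.
#'
#' @param x numeric matrix, samples in rows.
#' @return An object of class `contribution_profile`: list with `fractions`
#'   (non-negative, non-increasing, summing to 1), `cumulative`, `loadings`
#'   (variables x components), `scores` (samples x components).
#' @export
pca_contribution <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("at least 2 samples required for PCA")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  tot <- sum(ev)
  if (tot <= 0) stop("input has zero total variance")
  frac <- ev / tot
  structure(
    list(fractions = frac, cumulative = cumsum(frac),
         loadings = p$rotation, scores = p$x),
    class = "contribution_profile"
  )
}

#' Relevance ranking of genes against an embedding
#'
#' Each gene's relevance is the contribution-weighted sum, over embedding
#' components, of the absolute Spearman correlation between the gene's
#' expression profile and that component:
#' relevance(g) = sum_c fractions_c * |rho(expr_g, Y_c)|. Constant genes
#' get relevance 0 with a warning. Ties in the ranking are broken by
#' ascending original gene index.
#'
#' @param x an [expr_set()].
#' @param emb an `lle_embedding` computed from `x` (or any samples x
#'   components score matrix wrapped the same way).
#' @param contrib a `contribution_profile` of the embedding columns; by
#'   default computed internally with [pca_contribution()].
#' @return An object of class `gene_ranking`: list with `gene_ids`
#'   (descending relevance), `relevance` (named, same order).
#' @export
gene_relevance <- function(x, emb, contrib = NULL) {
  stopifnot(inherits(x, "expr_set"))
  y <- if (inherits(emb, "lle_embedding")) emb$y else as.matrix(emb)
  if (nrow(y) != nrow(x$values)) stop("embedding and expression disagree on sample count")
  if (is.null(contrib)) contrib <- pca_contribution(y)
  # genes are correlated with the embedding columns as given; the PCA
  # profile only supplies the explained-variance weights (for an LLE
  # embedding these are near-uniform because (1/N) Y'Y = I)
  comp <- y
  wts <- contrib$fractions[seq_len(ncol(comp))]

  rx <- rank_columns(x$values)
  rc <- apply(comp, 2L, function(col) {
    r <- rank_with_ties(col); r - mean(r)
  })
  cx <- sweep(rx, 2L, colMeans(rx))
  sx <- sqrt(colSums(cx^2))             # zero for constant genes
  sc <- sqrt(colSums(rc^2))
  if (any(sx == 0)) {
    warning(sum(sx == 0), " constant gene(s) assigned relevance 0", call. = FALSE)
  }
  rho <- crossprod(cx, rc)              # genes x components, unnormalized
  denom <- outer(sx, sc)
  rho <- ifelse(denom > 0, rho / denom, 0)
  rel <- drop(abs(rho) %*% wts)
  names(rel) <- x$gene_ids
  ord <- order(-rel, seq_along(rel))    # ties: ascending gene index
  structure(list(gene_ids = x$gene_ids[ord], relevance = rel[ord]),
            class = "gene_ranking")
}

#' Feature-gene selection by supervised embedding and correlation filtering
#'
#' The full procedure: (1) embed the samples with supervised locally linear
#' embedding ([slle()]); (2) weight the embedding components by PCA
#' explained variance ([pca_contribution()]); (3) rank the original genes
#' by contribution-weighted |Spearman| association with the components
#' ([gene_relevance()]); (4) greedily remove coexpressed genes whose
#' correlation with a higher-ranked survivor reaches `threshold`
#' ([redundancy_filter()]); (5) keep the top `n_select` survivors.
#'
#' `mode` exposes the ablations: `"lle"` (unsupervised embedding, no
#' filter), `"slle"` (supervised embedding, no filter), `"sc2"` (no
#' embedding: relevance from PCA on the raw expression matrix, then the
#' filter), and `"full"` (the default, all stages).
#'
#' @param x an [expr_set()] with two classes.
#' @param k neighborhood size (default 5).
#' @param lambda_s supervision strength in \[0, 1\] (default 1).
#' @param d embedding dimension (default 2).
#' @param threshold redundancy threshold on |rho| (default 0.3).
#' @param n_select number of genes to return (default 5); if fewer genes
#'   survive the filter, all survivors are returned with a warning.
#' @param mode `"full"`, `"lle"`, `"slle"`, or `"sc2"`.
#' @param reg_tol Gram regularization scale (default 1e-3).
#' @param absolute passed to [redundancy_filter()].
#' @return An object of class `selection_result`: list with `selected`
#'   (ordered gene ids), `relevance` (named scores of the selected genes),
#'   `ranking` (the full `gene_ranking`), `log` (`redundancy_log` or NULL),
#'   `params`.
#' @export
slle_sc2_select <- function(x, k = 5, lambda_s = 1, d = 2, threshold = 0.3,
                            n_select = 5, mode = c("full", "lle", "slle", "sc2"),
                            reg_tol = 1e-3, absolute = TRUE) {
  stopifnot(inherits(x, "expr_set"))
  mode <- match.arg(mode)
  if (n_select < 1) stop("n_select must be >= 1")

  if (mode == "sc2") {
    contrib <- pca_contribution(x$values)
    dd <- min(d, ncol(contrib$scores))
    emb <- contrib$scores[, seq_len(dd), drop = FALSE]
    contrib$fractions <- contrib$fractions[seq_len(dd)]
    contrib$scores <- emb
    ranking <- gene_relevance(x, emb, contrib)
  } else {
    ls <- if (mode == "lle") 0 else lambda_s
    emb <- slle(x, k = k, lambda_s = ls, d = d, reg_tol = reg_tol)
    ranking <- gene_relevance(x, emb)
  }

  use_filter <- mode %in% c("full", "sc2")
  if (use_filter) {
    log <- redundancy_filter(ranking$gene_ids, x, threshold = threshold,
                             absolute = absolute)
    survivors <- log$kept
  } else {
    log <- NULL
    survivors <- ranking$gene_ids
  }
  if (n_select > length(survivors)) {
    warning("n_select = ", n_select, " exceeds the ", length(survivors),
            " surviving genes; returning all survivors", call. = FALSE)
  }
  sel <- utils::head(survivors, n_select)
  structure(
    list(selected = sel,
         relevance = ranking$relevance[sel],
         ranking = ranking,
         log = log,
         params = list(k = k, lambda_s = lambda_s, d = d,
                       threshold = threshold, n_select = n_select,
                       mode = mode, reg_tol = reg_tol, absolute = absolute)),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result (mode=", x$params$mode, "): ", length(x$selected),
      " gene(s)\n", sep = "")
  print(data.frame(gene = x$selected, relevance = unname(x$relevance)))
  if (!is.null(x$log)) {
    cat(nrow(x$log$removed), " gene(s) removed as redundant at threshold ",
        x$log$threshold, "\n", sep = "")
  }
  invisible(x)
}
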