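#' Tie-averaged ranks in original sample order
#'
#' The smallest value receives rank 1 and the largest rank N; samples with
#' equal values share the average of the ranks they span. Ranks are
#' returned in the original sample order.
#'
#' @param values finite numeric vector of length >= 2.
#' @return Numeric vector of ranks; sums to N(N+1)/2 exactly.
#' @export
rank_with_ties <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values to rank")
  if (!is.numeric(values) || !all(is.finite(values))) {
    stop("values must be finite numeric")
  }
  n <- length(values)
  ord <- order(values, seq_len(n))    # ascending; stable on ties
  r <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && values[ord[j + 1L]] == values[ord[i]]) j <- j + 1L
    r[ord[i:j]] <- (i + j) / 2         # average of spanned ranks i..j
    i <- j + 1L
  }
  r
}

#' Spearman's rank correlation of two attributes
#'
#' Pearson correlation applied to the tie-averaged ranks of the two
#' vectors. Invariant under strictly increasing transforms of either
#' argument; lies in \[-1, 1\].
#'
#' @param a,b finite numeric vectors of equal length >= 2.
#' @return The correlation (single number).
#' @export
spearman_rho <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  ra <- rank_with_ties(a)
  rb <- rank_with_ties(b)
  da <- ra - mean(ra)
  db <- rb - mean(rb)
  va <- sum(da^2)
  vb <- sum(db^2)
  if (va == 0 || vb == 0) {
    stop("Spearman correlation undefined for a constant attribute")
  }
  sum(da * db) / sqrt(va * vb)
}

#' Spearman correlation matrix over attributes
#'
#' @param x numeric matrix with attributes (genes) in columns and samples
#'   in rows.
#' @return Symmetric matrix with unit diagonal of pairwise Spearman
#'   correlations.
#' @export
correlation_matrix <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need at least 2 attributes")
  r <- apply(x, 2L, rank_with_ties)
  rho <- stats::cor(r)                  # Pearson on ranks, batch form
  diag(rho) <- 1
  rho
}

# ranks per gene column, for repeated correlation against the same data
rank_columns <- function(x) apply(as.matrix(x), 2L, rank_with_ties)

# Pearson correlation of one centered rank column against many
cor_one_vs_many <- function(rank_mat, i, js) {
  a <- rank_mat[, i] - mean(rank_mat[, i])
  b <- sweep(rank_mat[, js, drop = FALSE], 2L, colMeans(rank_mat[, js, drop = FALSE]))
  num <- drop(crossprod(b, a))
  den <- sqrt(sum(a^2) * colSums(b^2))
  out <- ifelse(den > 0, num / den, 0)
  names(out) <- colnames(rank_mat)[js]
  out
}

#' Greedy coexpression-redundancy filter
#'
#' Walks the attributes in relevance order: the highest-relevance surviving
#' attribute is kept, and every lower-ranked survivor whose Spearman
#' correlation with it reaches the threshold is removed as redundant
#' (coexpressed); this repeats until the list is exhausted. By default the
#' comparison uses |rho|, so strong negative coexpression is removed too;
#' set `absolute = FALSE` to compare the signed coefficient.
#'
#' Constant attributes carry no rank information and are dropped up front
#' with a warning.
#'
#' @param ordered_attrs character vector of attribute (gene) ids in
#'   descending relevance order.
#' @param x an [expr_set()] (or samples x genes matrix with column names)
#'   holding the expression of those attributes.
#' @param threshold correlation threshold in \[0, 1\] (default 0.3).
#' @param absolute compare |rho| (default) or signed rho to the threshold.
#' @return An object of class `redundancy_log`: list with `kept` (ordered
#'   ids), `removed` (data.frame removed_id, kept_id, rho), `threshold`.
#' @export
redundancy_filter <- function(ordered_attrs, x, threshold = 0.3,
                              absolute = TRUE) {
  v <- if (inherits(x, "expr_set")) x$values else as.matrix(x)
  if (length(ordered_attrs) == 0L) stop("empty attribute list")
  if (!all(ordered_attrs %in% colnames(v))) {
    stop("ordered_attrs contains ids absent from the expression matrix")
  }
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")

  v <- v[, ordered_attrs, drop = FALSE]
  const <- apply(v, 2L, function(col) min(col) == max(col))
  if (any(const)) {
    warning("dropping ", sum(const), " constant attribute(s) before filtering: ",
            paste(utils::head(ordered_attrs[const], 5L), collapse = ", "),
            call. = FALSE)
    v <- v[, !const, drop = FALSE]
    ordered_attrs <- ordered_attrs[!const]
  }
  if (ncol(v) == 0L) stop("no non-constant attributes to filter")

  rk <- rank_columns(v)
  p <- ncol(rk)
  alive <- rep(TRUE, p)
  kept <- integer(0)
  rem_id <- character(0); rem_by <- character(0); rem_rho <- numeric(0)
  for (i in seq_len(p)) {
    if (!alive[i]) next
    kept <- c(kept, i)
    below <- which(alive & seq_len(p) > i)
    if (!length(below)) next
    rho <- cor_one_vs_many(rk, i, below)
    cmp <- if (absolute) abs(rho) else rho
    hit <- below[cmp >= threshold]
    if (length(hit)) {
      alive[hit] <- FALSE
      rem_id <- c(rem_id, ordered_attrs[hit])
      rem_by <- c(rem_by, rep(ordered_attrs[i], length(hit)))
      rem_rho <- c(rem_rho, rho[match(hit, below)])
    }
  }
  structure(
    list(kept = ordered_attrs[kept],
         removed = data.frame(removed_id = rem_id, kept_id = rem_by,
                              rho = rem_rho, stringsAsFactors = FALSE),
         threshold = threshold, absolute = absolute),
    class = "redundancy_log"
  )
}

#' @export
print.redundancy_log <- function(x, ...) {
  cat("redundancy_log: kept ", length(x$kept), ", removed ",
      nrow(x$removed), " at threshold ", x$threshold,
      if (x$absolute) " (|rho|)" else " (signed rho)", "\n", sep = "")
  invisible(x)
}
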