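#' Confusion counts from true and predicted labels
#'
#' @param truth,pred label vectors of equal length.
#' @param positive the positive class label (see [resolve_positive()]).
#' @return An object of class `confusion_counts`: list with integer `tp`,
#'   `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, pred, positive) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(truth) != length(pred)) stop("truth and pred lengths differ")
  tpos <- truth == positive
  ppos <- pred == positive
  structure(
    list(tp = sum(tpos & ppos), tn = sum(!tpos & !ppos),
         fp = sum(!tpos & ppos), fn = sum(tpos & !ppos)),
    class = "confusion_counts"
  )
}

#' Classification metrics for imbalanced two-class problems
#'
#' Computes overall accuracy, TPR (recall/sensitivity), TNR (specificity),
#' precision, F-measure (harmonic mean of precision and recall) and G-mean
#' (geometric mean of TPR and TNR, robust to class imbalance). Precision
#' with no positive predictions is defined as 0 (and then F-measure is 0).
#'
#' @param c a `confusion_counts` object (or a list with tp, tn, fp, fn).
#' @return Named list: `acc`, `tpr`, `tnr`, `precision`, `f_measure`,
#'   `g_mean`.
#' @export
confusion_metrics <- function(c) {
  tp <- c$tp; tn <- c$tn; fp <- c$fp; fn <- c$fn
  if (any(c(tp, tn, fp, fn) < 0)) stop("counts must be non-negative")
  if (tp + fn == 0) stop("no samples of the positive class")
  if (tn + fp == 0) stop("no samples of the negative class")
  acc <- (tp + tn) / (tp + tn + fp + fn)
  tpr <- tp / (tp + fn)
  tnr <- tn / (tn + fp)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  f <- if (precision + tpr == 0) 0 else 2 * precision * tpr / (precision + tpr)
  list(acc = acc, tpr = tpr, tnr = tnr, precision = precision,
       f_measure = f, g_mean = sqrt(tpr * tnr))
}

#' Area under the ROC curve (rank statistic with tie correction)
#'
#' Mann-Whitney formulation: with tie-averaged ranks of the scores, AUC =
#' (sum of positive ranks - n_pos(n_pos+1)/2) / (n_pos * n_neg); ties count
#' one half. Equals trapezoidal integration of the ROC curve.
#'
#' @param labels label vector, both classes present.
#' @param scores finite numeric scores, higher = more positive.
#' @param positive the positive class label.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(labels, scores, positive) {
  labels <- as.character(labels)
  if (length(labels) != length(scores)) stop("labels and scores lengths differ")
  if (!all(is.finite(scores))) stop("scores must be finite")
  pos <- labels == positive
  npos <- sum(pos); nneg <- sum(!pos)
  if (npos == 0 || nneg == 0) {
    stop("both classes must be present; missing ",
         if (npos == 0) "positive" else "negative", " class")
  }
  r <- rank_with_ties(scores)
  (sum(r[pos]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# --- classifier backends -----------------------------------------------------
#
# The evaluation harness delegates classification to established
# implementations where the environment provides one (MASS::lda, stats::glm);
# a minimal majority-vote kNN is built in because no kNN backend is
# available. Each backend is fit_predict(xtr, ytr, xte, positive) returning
# list(pred = labels, score = numeric, higher = more positive).

classifier_backend <- function(name, args = list()) {
  name <- match.arg(name, c("lda", "logistic", "knn"))
  switch(name,
    lda = function(xtr, ytr, xte, positive) {
      keep <- apply(xtr, 2L, function(v) max(v) > min(v))
      if (!any(keep)) stop("all predictors constant on the training fold")
      fit <- MASS::lda(x = xtr[, keep, drop = FALSE], grouping = factor(ytr))
      pr <- stats::predict(fit, xte[, keep, drop = FALSE])
      list(pred = as.character(pr$class),
           score = pr$posterior[, positive])
    },
    logistic = function(xtr, ytr, xte, positive) {
      df <- as.data.frame(xtr); names(df) <- paste0("v", seq_len(ncol(xtr)))
      df$.y <- as.integer(ytr == positive)
      fit <- suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
      nd <- as.data.frame(xte); names(nd) <- paste0("v", seq_len(ncol(xte)))
      p <- suppressWarnings(stats::predict(fit, nd, type = "response"))
      other <- setdiff(unique(as.character(ytr)), positive)[1L]
      list(pred = ifelse(p >= 0.5, positive, other), score = p)
    },
    knn = function(xtr, ytr, xte, positive) {
      kk <- if (!is.null(args$k)) args$k else 3L
      kk <- min(kk, nrow(xtr))
      other <- setdiff(unique(as.character(ytr)), positive)[1L]
      pred <- character(nrow(xte)); score <- numeric(nrow(xte))
      for (i in seq_len(nrow(xte))) {
        dd <- sqrt(colSums((t(xtr) - xte[i, ])^2))
        nb <- order(dd, seq_along(dd))[seq_len(kk)]
        frac <- mean(ytr[nb] == positive)
        score[i] <- frac
        pred[i] <- if (frac > 0.5) positive
                   else if (frac < 0.5) other
                   else as.character(ytr[nb[1L]])   # tie: nearest neighbor
      }
      list(pred = pred, score = score)
    }
  )
}

# stratified fold assignment: within each class, shuffled indices are split
# evenly and the remainder goes to the currently least-loaded folds, so both
# total fold sizes and per-fold class counts differ by at most 1
stratified_folds <- function(labels, folds) {
  n <- length(labels)
  if (folds < 2L) stop("folds must be >= 2")
  assign <- integer(n)
  load <- integer(folds)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < folds) {
      stop("class '", cl, "' has fewer samples (", length(idx),
           ") than folds (", folds, ")")
    }
    idx <- sample(idx)
    m <- length(idx)
    base <- m %/% folds
    extra <- m %% folds
    per <- rep(base, folds)
    if (extra > 0L) {
      recv <- order(load, seq_len(folds))[seq_len(extra)]
      per[recv] <- per[recv] + 1L
    }
    assign[idx] <- rep(seq_len(folds), times = per)
    load <- load + per
  }
  assign
}

# resolve the selector argument of cross_validate / threshold_sweep
resolve_selector <- function(selector) {
  if (is.null(selector)) return(function(train) train$gene_ids)
  if (is.function(selector)) return(selector)
  if (is.list(selector)) {
    return(function(train) do.call(slle_sc2_select, c(list(x = train), selector))$selected)
  }
  stop("selector must be NULL, a function(train) -> gene ids, or a list of ",
       "slle_sc2_select() parameters")
}

#' Stratified cross-validation with selection nested inside folds
#'
#' Gene selection is re-fit on each training fold (never on held-out
#' samples), the classifier is trained on the selected genes, and the
#' metrics of the held-out fold are recorded. Folds are stratified by
#' class; everything is reproducible given `seed`.
#'
#' @param x an [expr_set()] with two classes.
#' @param selector `NULL` (use all genes), a list of [slle_sc2_select()]
#'   parameters, or a `function(train_expr_set)` returning gene ids.
#' @param classifier `"lda"` (default), `"logistic"`, or `"knn"`.
#' @param folds number of folds (default 10).
#' @param repeats independent repetitions (default 2, giving 20 outcomes
#'   with the default folds).
#' @param seed integer RNG seed.
#' @param positive positive class label (default: see [resolve_positive()]).
#' @param classifier_args list of backend options (e.g. `list(k = 1)` for
#'   kNN).
#' @return An object of class `cv_report`: list with `per_fold`
#'   (data.frame: repeat, fold, acc, tpr, tnr, precision, f_measure,
#'   g_mean, auc, n_genes), `mean`, `sd`, `selected` (list of per-fold
#'   gene id vectors), `params`.
#' @export
cross_validate <- function(x, selector = NULL, classifier = "lda",
                           folds = 10, repeats = 2, seed = 1,
                           positive = NULL, classifier_args = list()) {
  stopifnot(inherits(x, "expr_set"))
  positive <- suppressWarnings(resolve_positive(x$labels, positive))
  sel_fun <- resolve_selector(selector)
  clf <- classifier_backend(classifier, classifier_args)

  set.seed(as.integer(seed))
  rows <- list(); chosen <- list(); ri <- 0L
  for (rep_i in seq_len(repeats)) {
    fold_of <- stratified_folds(x$labels, folds)
    for (f in seq_len(folds)) {
      test_idx <- which(fold_of == f)
      train <- subset_samples(x, -test_idx)
      test <- subset_samples(x, test_idx)
      if (length(unique(test$labels)) < 2L || length(unique(train$labels)) < 2L) {
        stop("fold ", f, " lacks a class; stratification failed")
      }
      genes <- sel_fun(train)
      out <- clf(train$values[, genes, drop = FALSE], train$labels,
                 test$values[, genes, drop = FALSE], positive)
      cc <- confusion_counts(test$labels, out$pred, positive)
      met <- confusion_metrics(cc)
      met$auc <- auc_score(test$labels, out$score, positive)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(rep = rep_i, fold = f, as.data.frame(met),
                               n_genes = length(genes))
      chosen[[ri]] <- genes
    }
  }
  per_fold <- do.call(rbind, rows)
  metric_cols <- c("acc", "tpr", "tnr", "precision", "f_measure", "g_mean", "auc")
  structure(
    list(per_fold = per_fold,
         mean = colMeans(per_fold[metric_cols]),
         sd = apply(per_fold[metric_cols], 2L, stats::sd),
         selected = chosen,
         params = list(classifier = classifier, folds = folds,
                       repeats = repeats, seed = seed, positive = positive,
                       selector = if (is.list(selector)) selector else NULL)),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat("cv_report: ", x$params$folds, "-fold x ", x$params$repeats,
      " repeat(s), classifier=", x$params$classifier, "\n", sep = "")
  print(round(rbind(mean = x$mean, sd = x$sd), 4))
  invisible(x)
}

#' Correlation-threshold sweep
#'
#' Evaluates the selection pipeline over a grid of redundancy thresholds
#' (default 0 to 1 in steps of 0.1). The expensive stages (embedding and
#' relevance ranking) do not depend on the threshold, so they are computed
#' once per training fold and only the filter and the classifier are redone
#' per threshold. `n_selected` reports the number of filter survivors on
#' the full dataset, which is non-decreasing in the threshold.
#'
#' @inheritParams cross_validate
#' @param thresholds numeric grid of thresholds in \[0, 1\].
#' @param k,lambda_s,d,reg_tol,mode selection parameters (see
#'   [slle_sc2_select()]).
#' @param n_select cap on the number of selected genes per fold
#'   (default `Inf`: all filter survivors are used).
#' @param classifier default `"knn"`: robust when a loose threshold keeps
#'   many genes.
#' @return An object of class `sweep_table`: data.frame with columns
#'   `threshold`, `mean_accuracy`, `n_selected`.
#' @export
threshold_sweep <- function(x, thresholds = seq(0, 1, by = 0.1),
                            k = 5, lambda_s = 1, d = 2, reg_tol = 1e-3,
                            mode = "full", n_select = Inf,
                            classifier = "knn", folds = 10, repeats = 1,
                            seed = 1, positive = NULL,
                            classifier_args = list()) {
  stopifnot(inherits(x, "expr_set"))
  if (any(thresholds < 0 | thresholds > 1)) stop("thresholds must lie in [0, 1]")
  positive <- suppressWarnings(resolve_positive(x$labels, positive))
  clf <- classifier_backend(classifier, classifier_args)
  rank_for <- function(train) {
    if (mode == "sc2") {
      contrib <- pca_contribution(train$values)
      dd <- min(d, ncol(contrib$scores))
      gene_relevance(train, contrib$scores[, seq_len(dd), drop = FALSE],
                     within(contrib, fractions <- fractions[seq_len(dd)]))
    } else {
      gene_relevance(train, slle(train, k = k, lambda_s = lambda_s, d = d,
                                 reg_tol = reg_tol))
    }
  }

  set.seed(as.integer(seed))
  acc <- matrix(NA_real_, nrow = 0, ncol = length(thresholds))
  for (rep_i in seq_len(repeats)) {
    fold_of <- stratified_folds(x$labels, folds)
    for (f in seq_len(folds)) {
      test_idx <- which(fold_of == f)
      train <- subset_samples(x, -test_idx)
      test <- subset_samples(x, test_idx)
      ranking <- rank_for(train)
      fold_acc <- vapply(thresholds, function(th) {
        survivors <- suppressWarnings(
          redundancy_filter(ranking$gene_ids, train, threshold = th)$kept)
        genes <- utils::head(survivors, n_select)
        out <- clf(train$values[, genes, drop = FALSE], train$labels,
                   test$values[, genes, drop = FALSE], positive)
        confusion_metrics(confusion_counts(test$labels, out$pred, positive))$acc
      }, numeric(1))
      acc <- rbind(acc, fold_acc)
    }
  }
  full_ranking <- rank_for(x)
  n_sel <- vapply(thresholds, function(th) {
    length(utils::head(suppressWarnings(
      redundancy_filter(full_ranking$gene_ids, x, threshold = th)$kept), n_select))
  }, numeric(1))
  structure(
    data.frame(threshold = thresholds, mean_accuracy = colMeans(acc),
               n_selected = n_sel),
    class = c("sweep_table", "data.frame")
  )
}
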