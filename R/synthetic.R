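#' Specification of a synthetic two-class expression dataset
#'
#' Describes the statistical structure the selection method assumes:
#' a handful of informative genes whose class means differ, blocks of
#' coexpressed (redundant) copies of each informative gene, and a large
#' majority of uninformative noise genes. Defaults mirror a small
#' microarray study: 30 samples per class, 5 informative blocks of 4
#' coexpressed members each, 200 noise genes, a 2-standard-deviation class
#' separation, and within-block correlation 0.9.
#'
#' @param n_samples_per_class samples in each of the two classes.
#' @param n_informative number of informative genes (= blocks).
#' @param copies_per_block redundant coexpressed copies per informative
#'   gene (block size is `1 + copies_per_block`).
#' @param n_noise number of pure-noise genes.
#' @param effect class mean shift in units of `noise_sd`.
#' @param within_block_rho target correlation between a copy and its block
#'   seed gene, in (0, 1].
#' @param noise_sd standard deviation of all Gaussian noise.
#' @return An object of class `synthetic_spec` (a validated list).
#' @export
synthetic_spec <- function(n_samples_per_class = 30, n_informative = 5,
                           copies_per_block = 3, n_noise = 200,
                           effect = 2.0, within_block_rho = 0.9,
                           noise_sd = 1) {
  stopifnot(n_samples_per_class >= 2, n_informative >= 1,
            copies_per_block >= 0, n_noise >= 0, effect >= 0, noise_sd > 0)
  if (within_block_rho <= 0 || within_block_rho > 1) {
    stop("within_block_rho must lie in (0, 1]")
  }
  structure(
    list(n_samples_per_class = as.integer(n_samples_per_class),
         n_informative = as.integer(n_informative),
         copies_per_block = as.integer(copies_per_block),
         n_noise = as.integer(n_noise),
         effect = effect, within_block_rho = within_block_rho,
         noise_sd = noise_sd),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic labeled expression dataset
#'
#' Informative gene of block b: Normal(+effect/2, noise_sd) in the positive
#' class and Normal(-effect/2, noise_sd) in the negative class. Each copy
#' in the block is `rho * seed_gene + sqrt(1 - rho^2) * independent noise`,
#' so block members are strongly coexpressed. Noise genes are
#' Normal(0, noise_sd). Deterministic given `seed`.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer RNG seed.
#' @return A list with `data` (an [expr_set()]; labels `"pos"`/`"neg"`) and
#'   `truth` (data.frame: gene_id, role in informative/copy/noise, block).
#' @export
generate_expression <- function(spec = synthetic_spec(), seed = 1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(as.integer(seed))
  npc <- spec$n_samples_per_class
  n <- 2L * npc
  labels <- rep(c("pos", "neg"), each = npc)
  shift <- ifelse(labels == "pos", spec$effect / 2, -spec$effect / 2)

  cols <- list(); ids <- character(0)
  role <- character(0); block <- integer(0)
  rho <- spec$within_block_rho
  for (b in seq_len(spec$n_informative)) {
    g <- shift + stats::rnorm(n, 0, spec$noise_sd)
    cols[[length(cols) + 1L]] <- g
    ids <- c(ids, sprintf("inf%d", b))
    role <- c(role, "informative"); block <- c(block, b)
    for (cp in seq_len(spec$copies_per_block)) {
      cols[[length(cols) + 1L]] <- rho * g +
        sqrt(1 - rho^2) * stats::rnorm(n, 0, spec$noise_sd)
      ids <- c(ids, sprintf("inf%d_copy%d", b, cp))
      role <- c(role, "copy"); block <- c(block, b)
    }
  }
  if (spec$n_noise > 0L) {
    noise <- matrix(stats::rnorm(n * spec$n_noise, 0, spec$noise_sd),
                    nrow = n)
    for (j in seq_len(spec$n_noise)) cols[[length(cols) + 1L]] <- noise[, j]
    ids <- c(ids, sprintf("noise%d", seq_len(spec$n_noise)))
    role <- c(role, rep("noise", spec$n_noise))
    block <- c(block, rep(NA_integer_, spec$n_noise))
  }
  values <- do.call(cbind, cols)
  colnames(values) <- ids
  list(
    data = expr_set(values, labels),
    truth = data.frame(gene_id = ids, role = role, block = block,
                       stringsAsFactors = FALSE)
  )
}

#' The five-sample, two-attribute worked example
#'
#' A tiny dataset used throughout the documentation and tests to
#' demonstrate tie-averaged ranking and the Spearman coefficient: attribute
#' a1 = (0.7, 0.3, 0.5, 0.2, 0.8), a2 = (0.9, 0.3, 0.4, 0.1, 0.7). Their
#' rank vectors are (4, 2, 3, 1, 5) and (5, 2, 3, 1, 4) and their Spearman
#' correlation is exactly 0.9.
#'
#' @return An [expr_set()] with 5 samples and 2 attributes (single class).
#' @export
worked_example <- function() {
  values <- cbind(a1 = c(0.7, 0.3, 0.5, 0.2, 0.8),
                  a2 = c(0.9, 0.3, 0.4, 0.1, 0.7))
  rownames(values) <- paste0("x", 1:5)
  expr_set(values, labels = rep("u", 5))
}
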