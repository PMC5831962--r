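#' Read a labeled expression matrix from delimited text
#'
#' Expected layout: genes as rows, first column gene identifiers, header
#' row of sample identifiers (the field convention); `orientation =
#' "samples"` accepts the transposed layout. Labels come from a separate
#' two-column file (sample_id, label), header optional.
#'
#' @param expr_path path to the expression file (TSV by default; comma
#'   accepted via `sep`).
#' @param labels_path path to the label file.
#' @param orientation `"genes"` (rows are genes, default) or `"samples"`.
#' @param sep field separator (default tab).
#' @param impute_missing passed to [expr_set()].
#' @return An [expr_set()].
#' @export
read_expression <- function(expr_path, labels_path, orientation = c("genes", "samples"),
                            sep = "\t", impute_missing = FALSE) {
  orientation <- match.arg(orientation)
  if (!file.exists(expr_path)) stop("expression file not found: ", expr_path)
  if (!file.exists(labels_path)) stop("label file not found: ", labels_path)
  tab <- utils::read.table(expr_path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cells in expression file")
  if (orientation == "genes") {
    values <- t(m)
    gene_ids <- ids
    sample_ids <- colnames(tab)[-1L]
  } else {
    values <- m
    gene_ids <- colnames(tab)[-1L]
    sample_ids <- ids
  }
  lab <- utils::read.table(labels_path, header = FALSE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "")
  if (ncol(lab) < 2L) stop("label file must have two columns: sample_id, label")
  if (identical(tolower(as.character(lab[1, 1])), "sample_id")) lab <- lab[-1L, ]
  pos <- match(sample_ids, as.character(lab[[1L]]))
  if (anyNA(pos)) {
    stop("samples missing from label file: ",
         paste(utils::head(sample_ids[is.na(pos)], 5L), collapse = ", "))
  }
  expr_set(values, labels = as.character(lab[[2L]])[pos],
           gene_ids = gene_ids, sample_ids = sample_ids,
           impute_missing = impute_missing)
}

#' Write an expression matrix and its labels as delimited text
#'
#' Genes as rows (round-trips through [read_expression()]).
#'
#' @param x an [expr_set()].
#' @param expr_path,labels_path output paths.
#' @param sep field separator.
#' @export
write_expression <- function(x, expr_path, labels_path, sep = "\t") {
  stopifnot(inherits(x, "expr_set"))
  tab <- data.frame(gene_id = x$gene_ids,
                    t(x$values), check.names = FALSE)
  colnames(tab) <- c("gene_id", x$sample_ids)
  utils::write.table(tab, expr_path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample_id = x$sample_ids, label = x$labels),
                     labels_path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(c(expr_path, labels_path))
}

#' Run manifest
#'
#' Records tool version, parameters, seed, mode, and md5 digests of the
#' input files. Timestamps are off by default so that identical runs
#' produce byte-identical outputs.
#'
#' @param params named list of run parameters.
#' @param seed integer seed used for the run.
#' @param inputs character vector of input file paths to digest.
#' @param mode pipeline mode string.
#' @param include_timestamp add a wall-clock timestamp (breaks byte-level
#'   reproducibility of the manifest file).
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(params = list(), seed = NA_integer_,
                         inputs = character(0), mode = "full",
                         include_timestamp = FALSE) {
  digests <- if (length(inputs)) {
    d <- tools::md5sum(inputs)
    as.list(stats::setNames(unname(d), basename(inputs)))
  } else list()
  structure(
    list(tool = "sllesc2",
         version = as.character(utils::packageVersion("sllesc2")),
         params = params, seed = seed, mode = mode,
         input_digests = digests,
         timestamp = if (include_timestamp)
           format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z") else NA),
    class = "run_manifest"
  )
}

#' Write a manifest as JSON text
#' @param manifest a [run_manifest()].
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read a manifest back from JSON text
#' @param path manifest path.
#' @return A `run_manifest`.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$params <- as.list(m$params)
  m$input_digests <- as.list(m$input_digests)
  structure(m, class = "run_manifest")
}

#' Write a selection result (and manifest) to a directory
#'
#' Emits `selection.tsv` (gene, relevance, rank), `redundancy_log.tsv`
#' (removed_id, kept_id, rho) when the filter ran, and `manifest.json`.
#' File contents are deterministic given identical inputs.
#'
#' @param result a `selection_result` from [slle_sc2_select()].
#' @param out_dir output directory (created if needed).
#' @param seed seed recorded in the manifest.
#' @param inputs input paths recorded (digested) in the manifest.
#' @return Invisibly, the paths written.
#' @export
write_selection <- function(result, out_dir, seed = NA_integer_,
                            inputs = character(0)) {
  stopifnot(inherits(result, "selection_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sel_path <- file.path(out_dir, "selection.tsv")
  utils::write.table(
    data.frame(gene = result$selected,
               relevance = unname(result$relevance),
               rank = seq_along(result$selected)),
    sel_path, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- sel_path
  if (!is.null(result$log)) {
    log_path <- file.path(out_dir, "redundancy_log.tsv")
    utils::write.table(result$log$removed, log_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, log_path)
  }
  man_path <- file.path(out_dir, "manifest.json")
  write_manifest(run_manifest(result$params, seed = seed, inputs = inputs,
                              mode = result$params$mode), man_path)
  invisible(c(paths, man_path))
}

#' Read a written selection back
#' @param out_dir directory written by [write_selection()].
#' @return List with `selection` and `removed` data.frames.
#' @export
read_selection <- function(out_dir) {
  sel <- utils::read.table(file.path(out_dir, "selection.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  log_path <- file.path(out_dir, "redundancy_log.tsv")
  removed <- if (file.exists(log_path)) {
    utils::read.table(log_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  } else NULL
  list(selection = sel, removed = removed)
}

#' Write a CV report or sweep table to a directory
#' @param report a `cv_report` or `sweep_table`.
#' @param out_dir output directory.
#' @param seed,inputs manifest fields.
#' @return Invisibly, the paths written.
#' @export
write_evaluation <- function(report, out_dir, seed = NA_integer_,
                             inputs = character(0)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(report, "cv_report")) {
    path <- file.path(out_dir, "cv_report.tsv")
    utils::write.table(report$per_fold, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    params <- report$params
  } else if (inherits(report, "sweep_table")) {
    path <- file.path(out_dir, "sweep.tsv")
    utils::write.table(as.data.frame(report), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    params <- list()
  } else stop("unsupported report type")
  man_path <- file.path(out_dir, "manifest.json")
  write_manifest(run_manifest(params, seed = seed, inputs = inputs), man_path)
  invisible(c(path, man_path))
}
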