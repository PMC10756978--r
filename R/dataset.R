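#' Assemble aligned multi-omics data over one gene list
#'
#' Restricts the three omics to the samples present in all three matrices
#' *and* labelled, reorders genes to `gene_list`, and re-indexes everything
#' identically, mirroring the complete-case design in which only samples
#' carrying all three omics are analysed.
#'
#' @param expr,meth,cna [feature_matrix()] objects for gene expression, DNA
#'   methylation and copy-number alteration.
#' @param labels Named character (or factor) vector mapping sample id to
#'   class name.
#' @param gene_list Ordered character vector of gene symbols to keep; every
#'   symbol must be present in all three omics.
#' @return A `multiomics_dataset`: list with elements `expression`,
#'   `methylation`, `cna` (aligned [feature_matrix()]s), `labels` (integer
#'   class indices in `0..K-1`, named by sample), `class_names` (ordered K
#'   class labels), `gene_ids` and `sample_ids`.
#' @export
assemble_dataset <- function(expr, meth, cna, labels, gene_list) {
  if (length(gene_list) == 0L) abort_validation("`gene_list` is empty.")
  if (length(labels) == 0L) abort_validation("`labels` is empty.")
  mats <- list(expression = expr, methylation = meth, cna = cna)
  for (nm in names(mats)) {
    missing <- setdiff(gene_list, rownames(mats[[nm]]))
    if (length(missing) > 0L) {
      abort_validation(sprintf(
        "gene '%s' from `gene_list` is absent from the %s matrix.",
        missing[1L], nm))
    }
  }
  samples <- Reduce(intersect, c(lapply(mats, colnames), list(names(labels))))
  if (length(samples) == 0L) {
    abort_validation("no sample is present in all three omics and labelled.")
  }
  # keep the expression matrix's sample order for determinism
  samples <- intersect(colnames(expr), samples)
  class_names <- if (is.factor(labels)) levels(labels) else sort(unique(as.character(labels)))
  if (length(class_names) < 2L) {
    abort_validation("need at least two classes in `labels`.")
  }
  lab_idx <- match(as.character(labels[samples]), class_names) - 1L
  aligned <- lapply(mats, function(m) {
    refm(unclass(m)[gene_list, samples, drop = FALSE], m)
  })
  structure(list(
    expression = aligned$expression,
    methylation = aligned$methylation,
    cna = aligned$cna,
    labels = stats::setNames(lab_idx, samples),
    class_names = class_names,
    gene_ids = gene_list,
    sample_ids = samples
  ), class = "multiomics_dataset")
}

#' @export
print.multiomics_dataset <- function(x, ...) {
  cat(sprintf(
    "<multiomics_dataset> %d genes x %d samples, %d classes (%s)\n",
    length(x$gene_ids), length(x$sample_ids), length(x$class_names),
    paste(x$class_names, collapse = ", ")))
  invisible(x)
}

#' Per-sample label summary of a dataset as a tibble
#'
#' @param x A `multiomics_dataset`.
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `class_index`, `class_name`.
#' @export
tidy.multiomics_dataset <- function(x, ...) {
  tibble::tibble(
    sample_id = x$sample_ids,
    class_index = unname(x$labels),
    class_name = x$class_names[unname(x$labels) + 1L]
  )
}

#' Write a dataset manifest (gene order, sample order, class map) as JSON
#'
#' @param dataset A `multiomics_dataset`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_dataset_manifest <- function(dataset, path) {
  jsonlite::write_json(list(
    gene_ids = dataset$gene_ids,
    sample_ids = dataset$sample_ids,
    class_names = dataset$class_names,
    labels = as.list(stats::setNames(unname(dataset$labels), dataset$sample_ids))
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
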