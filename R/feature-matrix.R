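#' Feature matrices: one omic as a genes-by-samples numeric matrix
#'
#' A `feature_matrix` is a plain numeric matrix (rows = genes, identified by
#' symbol rownames; columns = samples, identified by colnames) carrying an
#' `omic_kind` attribute (`"expression"`, `"methylation"` or `"cna"`). Values
#' are platform-native on read and dimensionless in \[0, 1\] after
#' [normalize_matrix()].
#'
#' @param values Numeric matrix with gene rownames and sample colnames.
#' @param omic_kind One of `"expression"`, `"methylation"`, `"cna"`.
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(values,
                           omic_kind = c("expression", "methylation", "cna")) {
  omic_kind <- match.arg(omic_kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_validation("`values` must be a numeric matrix.")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort_validation("`values` must have gene rownames and sample colnames.")
  }
  if (anyDuplicated(rownames(values))) {
    abort_validation("duplicate gene ids in `values` rownames.")
  }
  if (anyDuplicated(colnames(values))) {
    abort_validation("duplicate sample ids in `values` colnames.")
  }
  structure(values, omic_kind = omic_kind, class = c("feature_matrix", "matrix", "array"))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %s: %d genes x %d samples\n",
              attr(x, "omic_kind"), nrow(x), ncol(x)))
  print(utils::head(unclass(x)[, seq_len(min(ncol(x), 6L)), drop = FALSE], 4L))
  invisible(x)
}

omic_kind <- function(m) attr(m, "omic_kind") %||% "expression"

# Rebuild the class/attribute wrapper after a subsetting operation.
refm <- function(values, template) {
  structure(values, omic_kind = omic_kind(template),
            class = c("feature_matrix", "matrix", "array"))
}

#' Read one omic table from a tab-separated file
#'
#' Expects the cBioPortal-style export dialect: first column gene symbols
#' (conventionally headed `Hugo_Symbol`), remaining columns one per sample,
#' header row of sample ids, cells numeric or empty. Duplicate gene symbols
#' are resolved by keeping the first occurrence (with a warning); missing
#' cells are handled per `missing_policy`.
#'
#' @param path Path to the TSV file.
#' @inheritParams feature_matrix
#' @param missing_policy `"drop_gene"` (default) removes any gene row with a
#'   missing cell; `"impute_zero"` replaces missing cells with 0.
#' @return A [feature_matrix()].
#' @export
read_omics_table <- function(path,
                             omic_kind = c("expression", "methylation", "cna"),
                             missing_policy = c("drop_gene", "impute_zero")) {
  omic_kind <- match.arg(omic_kind)
  missing_policy <- match.arg(missing_policy)
  if (!file.exists(path)) {
    abort_io(sprintf("cannot read omics table: no such file '%s'", path))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    abort_validation(sprintf("omics table '%s' is empty.", path))
  }
  genes <- as.character(raw[[1L]])
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells),
                                 dimnames = dimnames(cells)))
  bad <- which(is.na(num) & !(is.na(cells) | cells == ""), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort_parse(sprintf(
      "non-numeric cell '%s' at gene '%s', sample '%s' in '%s'",
      cells[bad[1L, 1L], bad[1L, 2L]], genes[bad[1L, 1L]],
      colnames(cells)[bad[1L, 2L]], path))
  }
  dup <- duplicated(genes)
  if (any(dup)) {
    rlang::warn(sprintf(
      "dropping %d duplicated gene row(s) (%s ...); keeping first occurrence",
      sum(dup), paste(head(unique(genes[dup]), 3L), collapse = ", ")))
    num <- num[!dup, , drop = FALSE]
    genes <- genes[!dup]
  }
  missing <- is.na(num)
  if (any(missing)) {
    if (missing_policy == "drop_gene") {
      keep <- rowSums(missing) == 0L
      num <- num[keep, , drop = FALSE]
      genes <- genes[keep]
      if (nrow(num) == 0L) {
        abort_validation(sprintf(
          "all gene rows in '%s' had missing cells under drop_gene.", path))
      }
    } else {
      num[missing] <- 0
    }
  }
  rownames(num) <- genes
  feature_matrix(num, omic_kind)
}

#' Write a feature matrix back to TSV
#'
#' Inverse of [read_omics_table()]: first column `Hugo_Symbol`, one column per
#' sample. Values are written with full (up to 15 significant digit) decimal
#' text so a read/write cycle round-trips them exactly.
#'
#' @param m A [feature_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_omics_table <- function(m, path) {
  df <- data.frame(Hugo_Symbol = rownames(m),
                   apply(unclass(m), 2L, function(x) {
                     vapply(x, function(v) format(v, digits = 15L, trim = TRUE,
                                                  scientific = FALSE), "")
                   }),
                   check.names = FALSE, stringsAsFactors = FALSE)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Remove gene rows with near-constant values
#'
#' Drops every gene whose sample variance (denominator `n - 1`) falls below
#' `threshold`, keeping row order. The default 0.002 reads the conventional
#' "variance below 0.2%" expression-filter cutoff as an absolute variance on
#' the normalized \[0, 1\] scale.
#'
#' @param m A [feature_matrix()].
#' @param threshold Nonnegative variance cutoff; rows with variance
#'   `>= threshold` survive.
#' @return The filtered [feature_matrix()].
#' @export
filter_low_variance <- function(m, threshold = 0.002) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
    abort_validation("`threshold` must be a single nonnegative number.")
  }
  v <- apply(unclass(m), 1L, stats::var)
  keep <- v >= threshold
  if (!any(keep)) {
    abort_validation(sprintf(
      "variance filter at threshold %g removed every gene; lower the threshold.",
      threshold))
  }
  refm(unclass(m)[keep, , drop = FALSE], m)
}

#' Rescale a feature matrix into \[0, 1\]
#'
#' Brings the three omics onto one common dimensionless scale so their values
#' can colour image channels directly. `minmax_per_gene` (default) maps each
#' gene row's min to 0 and max to 1 (a constant row maps to 0.5);
#' `minmax_global` applies one affine map to the whole matrix.
#'
#' @param m A [feature_matrix()].
#' @param method `"minmax_per_gene"` or `"minmax_global"`.
#' @return The normalized [feature_matrix()]; every entry finite in \[0, 1\].
#' @export
normalize_matrix <- function(m, method = c("minmax_per_gene", "minmax_global")) {
  method <- match.arg(method)
  x <- unclass(m)
  if (nrow(x) == 0L || ncol(x) == 0L) abort_validation("matrix is empty.")
  if (!all(is.finite(x))) abort_validation("matrix contains non-finite entries.")
  if (method == "minmax_per_gene") {
    lo <- apply(x, 1L, min)
    hi <- apply(x, 1L, max)
    rng <- hi - lo
    const <- rng == 0
    rng[const] <- 1
    out <- (x - lo) / rng
    out[const, ] <- 0.5
  } else {
    lo <- min(x)
    hi <- max(x)
    out <- if (hi == lo) array(0.5, dim(x), dimnames(x)) else (x - lo) / (hi - lo)
  }
  refm(out, m)
}

#' Keep only genes whose symbol is on an approved list
#'
#' Used to discard rows whose identifier is not an approved (HUGO-style)
#' gene symbol.
#'
#' @param m A [feature_matrix()].
#' @param approved Character vector of approved symbols (non-empty).
#' @return The filtered [feature_matrix()], row order preserved.
#' @export
filter_symbols <- function(m, approved) {
  if (length(approved) == 0L) abort_validation("`approved` symbol set is empty.")
  keep <- rownames(m) %in% approved
  if (!any(keep)) {
    abort_validation("no gene symbols matched the approved list.")
  }
  refm(unclass(m)[keep, , drop = FALSE], m)
}

#' Read an approved-symbol or gene list file (one symbol per line)
#'
#' @param path Path to a text file with one symbol per line.
#' @return Character vector of symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("no such file '%s'", path))
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x)]
}

#' Read a sample-label table
#'
#' Two-column TSV `sample_id<TAB>class` with a header row.
#'
#' @param path Path to the labels TSV.
#' @return Named character vector: class per sample id.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("no such file '%s'", path))
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  if (ncol(df) < 2L || nrow(df) == 0L) {
    abort_validation(sprintf("labels table '%s' must have two columns.", path))
  }
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}
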