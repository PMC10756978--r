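#' Specification for a synthetic three-omics dataset
#'
#' The generator emulates the shape of a complete-case multi-omics cancer
#' cohort: three aligned gene x sample tables (expression, methylation,
#' CNA), a few hundred samples in a small number of tumour-grade classes, a
#' small set of signal genes whose per-omic means shift with class, and a
#' larger raw gene background that exercises the preprocessing filters
#' (near-constant rows, non-approved symbols) plus one omic missing a
#' fraction of samples so the complete-case intersection path always runs.
#'
#' @param n_samples Total labelled samples (default 387).
#' @param n_genes_raw Raw genes per omic before filtering (default 2000).
#' @param n_genes_signal Signal genes carrying class structure (default 14).
#' @param n_classes Number of classes (default 3).
#' @param class_proportions Simplex vector of class proportions.
#' @param effect_size Per-class mean shift per signal gene per omic, in
#'   normalized \[0, 1\] units (default 0.25, about three noise SDs).
#' @param noise_sd Within-class SD of every expressed value (default 0.08).
#' @param frac_low_variance Fraction of raw genes made near-constant
#'   (default 0.10).
#' @param frac_bad_symbols Fraction of raw genes given non-approved symbols
#'   (default 0.05).
#' @param frac_missing_omic Fraction of samples dropped from the methylation
#'   table (default 0.05), emulating samples lacking one omic.
#' @param seed Integer seed; everything is reproducible from it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_samples = 387L, n_genes_raw = 2000L,
                           n_genes_signal = 14L, n_classes = 3L,
                           class_proportions = rep(1 / n_classes, n_classes),
                           effect_size = 0.25, noise_sd = 0.08,
                           frac_low_variance = 0.10, frac_bad_symbols = 0.05,
                           frac_missing_omic = 0.05, seed = 1L) {
  if (!is_count(n_samples, 10L) || !is_count(n_genes_raw, 1L) ||
      !is_count(n_genes_signal, 1L) || !is_count(n_classes, 2L)) {
    abort_validation("invalid counts in synthetic spec.")
  }
  if (n_genes_signal > n_genes_raw) {
    abort_validation("`n_genes_signal` must not exceed `n_genes_raw`.")
  }
  if (abs(sum(class_proportions) - 1) > 1e-8 || any(class_proportions <= 0)) {
    abort_validation("`class_proportions` must be positive and sum to 1.")
  }
  if (effect_size < 0 || noise_sd <= 0) {
    abort_validation("need `effect_size` >= 0 and `noise_sd` > 0.")
  }
  if (frac_low_variance + frac_bad_symbols > 1) {
    abort_validation("`frac_low_variance` + `frac_bad_symbols` exceeds 1.")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_genes_raw = as.integer(n_genes_raw),
                 n_genes_signal = as.integer(n_genes_signal),
                 n_classes = as.integer(n_classes),
                 class_proportions = class_proportions,
                 effect_size = effect_size, noise_sd = noise_sd,
                 frac_low_variance = frac_low_variance,
                 frac_bad_symbols = frac_bad_symbols,
                 frac_missing_omic = frac_missing_omic,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# deterministic largest-remainder apportionment of n into proportions
apportion <- function(n, proportions) {
  raw <- n * proportions
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Generate a synthetic three-omics dataset
#'
#' Signal gene `g` in omic `o` has class-`c` mean `base[g, o] + c *
#' effect_size` (classes indexed from 0); background genes are
#' class-independent noise; near-constant genes have SD 0.005 so they fall
#' below the default variance filter; bad-symbol genes get identifiers
#' outside the approved list. All values are Gaussian draws truncated to
#' \[0, 1\]. When `out_dir` is given, the three raw TSV tables, labels TSV,
#' gene list, approved-symbol list and ground-truth JSON are written there.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Optional output directory for the TSV/JSON fixtures.
#' @return List with `expression`, `methylation`, `cna` (raw
#'   [feature_matrix()]s), `labels` (named character vector), `gene_list`
#'   (the signal genes), `approved_symbols`, and `ground_truth` (list with
#'   the planted class means, per-class counts, and gene category
#'   assignments).
#' @export
generate_multiomics <- function(spec = synthetic_spec(), out_dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    ns <- spec$n_samples; ng <- spec$n_genes_raw; K <- spec$n_classes
    sample_ids <- sprintf("S%04d", seq_len(ns))
    counts <- apportion(ns, spec$class_proportions)
    class_names <- sprintf("grade%d", seq_len(K) - 1L)
    labels <- sample(rep(class_names, counts))
    names(labels) <- sample_ids
    cls <- match(labels, class_names) - 1L

    n_low <- round(spec$frac_low_variance * ng)
    n_bad <- round(spec$frac_bad_symbols * ng)
    gene_ids <- sprintf("GS%04d", seq_len(ng))
    gene_ids[seq_len(spec$n_genes_signal)] <- sprintf(
      "SIG%02d", seq_len(spec$n_genes_signal))
    # bad symbols drawn from the tail, never overlapping the signal genes
    bad_idx <- if (n_bad > 0) (ng - n_bad + 1L):ng else integer(0)
    gene_ids[bad_idx] <- sprintf("probe_%04d", seq_along(bad_idx))
    # low-variance genes sit after the signal genes, before the bad tail
    low_idx <- if (n_low > 0) {
      spec$n_genes_signal + seq_len(min(n_low, ng - spec$n_genes_signal - n_bad))
    } else integer(0)

    omics <- c("expression", "methylation", "cna")
    base_max <- max(0.9 - (K - 1) * spec$effect_size, 0.15)
    base <- matrix(runif(spec$n_genes_signal * 3L, 0.1, base_max),
                   spec$n_genes_signal, 3L, dimnames = list(NULL, omics))
    mats <- list()
    for (o in seq_along(omics)) {
      mu <- matrix(runif(ng, 0.2, 0.8), ng, ns)      # background means
      mu[seq_len(spec$n_genes_signal), ] <-
        base[, o] + outer(rep(spec$effect_size, spec$n_genes_signal), cls)
      sd <- rep(spec$noise_sd, ng)
      sd[low_idx] <- 0.005
      x <- mu + matrix(rnorm(ng * ns), ng, ns) * sd
      x <- pmin(pmax(x, 0), 1)
      dimnames(x) <- list(gene_ids, sample_ids)
      mats[[omics[o]]] <- feature_matrix(x, omics[o])
    }
    # one omic lacks a fraction of samples, exercising the intersection
    n_drop <- round(spec$frac_missing_omic * ns)
    dropped <- if (n_drop > 0) sort(sample(ns, n_drop)) else integer(0)
    if (n_drop > 0) {
      mats$methylation <- refm(
        unclass(mats$methylation)[, -dropped, drop = FALSE], mats$methylation)
    }
    approved <- gene_ids[-bad_idx]
    if (length(bad_idx) == 0L) approved <- gene_ids
    gene_list <- gene_ids[seq_len(spec$n_genes_signal)]
    ground_truth <- list(
      class_names = class_names,
      class_counts = stats::setNames(as.list(counts), class_names),
      signal_genes = gene_list,
      low_variance_genes = gene_ids[low_idx],
      bad_symbol_genes = gene_ids[bad_idx],
      dropped_methylation_samples = sample_ids[dropped],
      base_means = base,
      effect_size = spec$effect_size,
      noise_sd = spec$noise_sd,
      seed = spec$seed
    )
    out <- list(expression = mats$expression, methylation = mats$methylation,
                cna = mats$cna, labels = labels, gene_list = gene_list,
                approved_symbols = approved, ground_truth = ground_truth)
    if (!is.null(out_dir)) write_synthetic(out, out_dir)
    out
  })
}

write_synthetic <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_omics_table(sim$expression, file.path(out_dir, "expression.tsv"))
  write_omics_table(sim$methylation, file.path(out_dir, "methylation.tsv"))
  write_omics_table(sim$cna, file.path(out_dir, "cna.tsv"))
  readr::write_tsv(tibble::tibble(sample_id = names(sim$labels),
                                  class = unname(sim$labels)),
                   file.path(out_dir, "labels.tsv"), progress = FALSE)
  writeLines(sim$gene_list, file.path(out_dir, "gene_list.txt"))
  writeLines(sim$approved_symbols, file.path(out_dir, "approved_symbols.txt"))
  gt <- sim$ground_truth
  gt$base_means <- apply(gt$base_means, 2L, identity, simplify = FALSE)
  jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Summarize how well an assembled dataset recovers the planted structure
#'
#' Reports per-class sample counts, realized effect sizes (the mean
#' difference between consecutive classes, per signal gene per omic) and
#' which planted genes survived preprocessing.
#'
#' @param dataset A `multiomics_dataset` built from a generated fixture.
#' @param ground_truth The `ground_truth` element of [generate_multiomics()].
#' @return A `ground_truth_report`: list with `class_counts` (tibble),
#'   `realized_effects` (tibble `gene`, `omic`, `effect`), and
#'   `signal_genes_recovered` (character).
#' @export
ground_truth_report <- function(dataset, ground_truth) {
  cls <- unname(dataset$labels)
  counts <- tibble::tibble(
    class_name = dataset$class_names,
    n = vapply(seq_along(dataset$class_names) - 1L,
               function(k) sum(cls == k), integer(1)))
  omics <- c("expression", "methylation", "cna")
  genes <- intersect(ground_truth$signal_genes, dataset$gene_ids)
  eff <- purrr::map_dfr(omics, function(o) {
    m <- unclass(dataset[[o]])
    purrr::map_dfr(genes, function(g) {
      mts <- vapply(seq_along(dataset$class_names) - 1L,
                    function(k) mean(m[g, cls == k]), numeric(1))
      tibble::tibble(gene = g, omic = o,
                     effect = mean(diff(mts)))
    })
  })
  structure(list(class_counts = counts, realized_effects = eff,
                 signal_genes_recovered = genes),
            class = "ground_truth_report")
}

#' @export
print.ground_truth_report <- function(x, ...) {
  cat(sprintf("<ground_truth_report> %d signal genes recovered; mean |effect| %.3f\n",
              length(x$signal_genes_recovered), mean(abs(x$realized_effects$effect))))
  print(x$class_counts)
  invisible(x)
}
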