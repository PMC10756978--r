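#' Pipeline configuration
#'
#' Collects every knob of the end-to-end flow: preprocessing thresholds,
#' embedding pair counts and schedule, image-template geometry, training
#' hyperparameters and the averaging mode, plus the input file paths and
#' output directory. One global `seed` fans out deterministically to
#' per-stage seeds via [stage_seed()].
#'
#' @param expression,methylation,cna Paths to the three omics TSV tables.
#' @param labels Path to the two-column labels TSV.
#' @param gene_list Optional path to the significant-gene list (one symbol
#'   per line). When `NULL`, the top `n_genes_fallback` genes of the
#'   filtered expression matrix by variance are used instead.
#' @param approved_symbols Optional path to the approved-symbol list; when
#'   `NULL` the symbol filter is skipped.
#' @param out_dir Output directory for all artifacts.
#' @param variance_threshold Expression variance filter cutoff.
#' @param normalization `"minmax_per_gene"` or `"minmax_global"`.
#' @param n_genes_fallback Fallback significant-gene count when no list is
#'   supplied.
#' @param n_nb,n_mn,n_fp PaCMAP per-anchor pair counts.
#' @param schedule A [phase_schedule()].
#' @param image_width,image_height,radius,margin Image-template geometry in
#'   pixels.
#' @param blend Zone-overlap blend rule (`"max"` or `"mean"`).
#' @param train A [train_config()].
#' @param stratified Stratify the train/test split by class.
#' @param averaging Headline metric averaging (`"micro"` or `"macro"`).
#' @param seed Global pipeline seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(expression, methylation, cna, labels,
                            gene_list = NULL, approved_symbols = NULL,
                            out_dir = tempfile("omicsgsn_run_"),
                            variance_threshold = 0.002,
                            normalization = c("minmax_per_gene", "minmax_global"),
                            n_genes_fallback = 14L,
                            n_nb = 10L, n_mn = 5L, n_fp = 20L,
                            schedule = phase_schedule(),
                            image_width = 32L, image_height = 32L,
                            radius = 3L, margin = 2L,
                            blend = c("max", "mean"),
                            train = train_config(),
                            stratified = TRUE,
                            averaging = c("micro", "macro"),
                            seed = 1L) {
  cfg <- list(expression = expression, methylation = methylation, cna = cna,
              labels = labels, gene_list = gene_list,
              approved_symbols = approved_symbols, out_dir = out_dir,
              variance_threshold = variance_threshold,
              normalization = match.arg(normalization),
              n_genes_fallback = as.integer(n_genes_fallback),
              n_nb = as.integer(n_nb), n_mn = as.integer(n_mn),
              n_fp = as.integer(n_fp), schedule = schedule,
              image_width = as.integer(image_width),
              image_height = as.integer(image_height),
              radius = as.integer(radius), margin = as.integer(margin),
              blend = match.arg(blend), train = train,
              stratified = isTRUE(stratified),
              averaging = match.arg(averaging), seed = as.integer(seed))
  for (p in c("expression", "methylation", "cna", "labels")) {
    if (!file.exists(cfg[[p]])) abort_validation(sprintf(
      "%s table does not exist: '%s'", p, cfg[[p]]))
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline config from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; `schedule`
#' and `train` may be nested maps of [phase_schedule()] / [train_config()]
#' arguments. Relative input paths are resolved against the YAML file's
#' directory.
#'
#' @param path Path to the YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (!is.null(p) && !file.exists(p)) file.path(base, p) else p
  for (k in c("expression", "methylation", "cna", "labels", "gene_list",
              "approved_symbols")) {
    if (!is.null(y[[k]])) y[[k]] <- rel(y[[k]])
  }
  if (!is.null(y$schedule)) y$schedule <- do.call(phase_schedule, y$schedule)
  if (!is.null(y$train)) y$train <- do.call(train_config, y$train)
  do.call(pipeline_config, y)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort_runtime(sprintf("pipeline stage '%s' failed: %s", stage,
                          conditionMessage(e)), parent = e)
  })
}

#' Run the full pipeline: preprocess, embed, render, train, evaluate
#'
#' Executes every stage in order and persists the intermediate artifacts
#' under `config$out_dir`: normalized expression TSV, embedding TSV,
#' template JSON, per-sample PNGs plus image manifest, training-history
#' CSV, evaluation JSON and a run manifest recording every effective
#' parameter and per-stage seed. Rerunning with the same config reproduces
#' the report.
#'
#' @param config A [pipeline_config()].
#' @return The test-set `evaluation_report`, with the trained model,
#'   dataset, embedding, split and history attached as attributes.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  dataset <- run_stage("preprocess", {
    expr <- read_omics_table(config$expression, "expression")
    meth <- read_omics_table(config$methylation, "methylation")
    cna <- read_omics_table(config$cna, "cna")
    labels <- read_labels(config$labels)
    # variance filter runs on the raw values: per-gene min-max rescaling
    # would stretch every non-constant row to full [0, 1] span and erase
    # the very low-variance structure the filter is meant to remove
    expr <- filter_low_variance(expr, config$variance_threshold)
    expr <- normalize_matrix(expr, config$normalization)
    meth <- normalize_matrix(meth, config$normalization)
    cna <- normalize_matrix(cna, config$normalization)
    if (!is.null(config$approved_symbols)) {
      approved <- read_gene_list(config$approved_symbols)
      expr <- filter_symbols(expr, approved)
      meth <- filter_symbols(meth, approved)
      cna <- filter_symbols(cna, approved)
    }
    genes <- if (!is.null(config$gene_list)) {
      read_gene_list(config$gene_list)
    } else {
      v <- apply(unclass(expr), 1L, stats::var)
      rownames(expr)[order(-v)][seq_len(min(config$n_genes_fallback, nrow(expr)))]
    }
    ds <- assemble_dataset(expr, meth, cna, labels, genes)
    write_dataset_manifest(ds, file.path(out, "dataset_manifest.json"))
    write_omics_table(ds$expression, file.path(out, "expression_normalized.tsv"))
    ds
  })

  embedding <- run_stage("embed", {
    emb <- pacmap_embed(unclass(dataset$expression),
                        n_nb = config$n_nb, n_mn = config$n_mn,
                        n_fp = config$n_fp, schedule = config$schedule,
                        seed = stage_seed(config$seed, "embed"))
    write_embedding(emb, file.path(out, "embedding.tsv"))
    emb
  })

  rendered <- run_stage("render", {
    template <- fit_template(embedding, width = config$image_width,
                             height = config$image_height,
                             radius = config$radius, margin = config$margin)
    write_template(template, file.path(out, "template.json"))
    imgs <- render_dataset(dataset, template, blend = config$blend,
                           out_dir = file.path(out, "images"))
    list(template = template, images = imgs)
  })

  trained <- run_stage("train", {
    y <- unname(dataset$labels)
    split <- split_train_test(y, config$train$train_fraction,
                              seed = stage_seed(config$seed, "split"),
                              stratified = config$stratified)
    x <- stack_images(rendered$images)
    model <- build_cnn(c(config$image_height, config$image_width, 3L),
                       n_classes = length(dataset$class_names),
                       seed = stage_seed(config$seed, "init"))
    cfg <- config$train
    cfg$seed <- stage_seed(config$seed, "train")
    model <- train_cnn(model, x[, , , split$train, drop = FALSE],
                       y[split$train], cfg,
                       validation = list(images = x[, , , split$test, drop = FALSE],
                                         labels = y[split$test]))
    readr::write_csv(tidy(model), file.path(out, "history.csv"),
                     progress = FALSE)
    list(model = model, split = split, x = x, y = y)
  })

  report <- run_stage("evaluate", {
    probs <- predict(trained$model,
                     trained$x[, , , trained$split$test, drop = FALSE])
    rep <- evaluate_predictions(trained$y[trained$split$test], probs,
                                averaging = config$averaging)
    write_evaluation(rep, file.path(out, "evaluation.json"))
    rep
  })

  manifest <- config
  manifest$schedule <- unclass(manifest$schedule)
  manifest$train <- unclass(manifest$train)
  manifest$stage_seeds <- lapply(
    stats::setNames(nm = c("embed", "split", "init", "train")),
    function(s) stage_seed(config$seed, s))
  jsonlite::write_json(unclass(manifest), file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  attr(report, "model") <- trained$model
  attr(report, "dataset") <- dataset
  attr(report, "embedding") <- embedding
  attr(report, "template") <- rendered$template
  attr(report, "split") <- trained$split
  report
}
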