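# Shared fixture builders; everything is generated in code at test time.

toy_matrix <- function(values, genes = NULL, samples = NULL,
                       omic = "expression") {
  m <- as.matrix(values)
  rownames(m) <- genes %||% paste0("G", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("S", seq_len(ncol(m)))
  feature_matrix(m, omic)
}

write_toy_tsv <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# n points in `dims` dimensions arranged as 3 well-separated Gaussian blobs
cluster_points <- function(n = 60L, dims = 10L, sep = 6, sd = 0.5,
                           seed = 5L) {
  withr::with_seed(seed, {
    cl <- rep(1:3, length.out = n)
    centers <- matrix(0, 3, dims)
    for (k in 1:3) centers[k, k] <- sep
    pts <- centers[cl, ] + matrix(rnorm(n * dims, sd = sd), n, dims)
    rownames(pts) <- paste0("g", seq_len(n))
    list(points = pts, cluster = cl)
  })
}

# two-class linearly separable image fixture: class 0 images are red-ish,
# class 1 images green-ish, with mild value jitter
separable_images <- function(n_per_class = 30L, size = 32L, seed = 9L) {
  withr::with_seed(seed, {
    n <- 2L * n_per_class
    x <- array(0, c(size, size, 3L, n))
    y <- rep(0:1, each = n_per_class)
    for (k in seq_len(n)) {
      ch <- y[k] + 1L
      x[, , ch, k] <- matrix(runif(size * size, 0.7, 1), size, size)
      x[, , 3L, k] <- matrix(runif(size * size, 0, 0.15), size, size)
    }
    list(images = x, labels = y)
  })
}

# small end-to-end synthetic scenario for pipeline tests
small_pipeline_config <- function(dir, seed = 7L, effect_size = 0.3,
                                  epochs = 3L, n_samples = 60L) {
  sim <- generate_multiomics(
    synthetic_spec(n_samples = n_samples, n_genes_raw = 120L,
                   n_genes_signal = 8L, effect_size = effect_size,
                   seed = seed),
    out_dir = dir)
  pipeline_config(
    expression = file.path(dir, "expression.tsv"),
    methylation = file.path(dir, "methylation.tsv"),
    cna = file.path(dir, "cna.tsv"),
    labels = file.path(dir, "labels.tsv"),
    gene_list = file.path(dir, "gene_list.txt"),
    approved_symbols = file.path(dir, "approved_symbols.txt"),
    out_dir = file.path(dir, "out"),
    image_width = 24L, image_height = 24L, radius = 2L, margin = 1L,
    n_nb = 4L, n_mn = 2L, n_fp = 3L,
    schedule = phase_schedule(t1 = 30L, t2 = 30L, t3 = 60L),
    train = train_config(epochs = epochs, seed = seed),
    seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
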