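# Template fitting and RGB rendering

embedding_of <- function(xy, genes = NULL) {
  tibble::tibble(gene = genes %||% paste0("g", seq_len(nrow(xy))),
                 x = xy[, 1], y = xy[, 2])
}

test_that("a single gene maps to the image center", {
  tpl <- fit_template(embedding_of(cbind(0.3, -2)), width = 33L, height = 33L,
                      radius = 3L, margin = 2L)
  expect_equal(tpl$gene_centers$row, 17)
  expect_equal(tpl$gene_centers$col, 17)
})

test_that("two genes span the inset box, 80 px apart at 100 px and inset 10", {
  emb <- embedding_of(rbind(c(0, 0), c(1, 0)))
  tpl <- fit_template(emb, width = 100L, height = 100L, radius = 5L,
                      margin = 5L)
  expect_equal(abs(diff(tpl$gene_centers$col)), 80)
  expect_equal(min(tpl$gene_centers$col), 0.5 + 10, tolerance = 1)
  # y-extent is zero: both rows sit at the vertical center
  expect_equal(tpl$gene_centers$row, c(50, 50))
})

test_that("the template is invariant to translating the embedding", {
  set.seed(4)
  xy <- matrix(rnorm(20), 10, 2)
  t1 <- fit_template(embedding_of(xy))
  t2 <- fit_template(embedding_of(sweep(xy, 2, c(7, -3), `+`)))
  expect_equal(t1$gene_centers, t2$gene_centers)
})

test_that("too-small images are rejected", {
  expect_error(fit_template(embedding_of(cbind(0, 0)), width = 10L,
                            height = 10L, radius = 3L, margin = 2L),
               class = "omicsgsn_validation_error")
})

test_that("a pure-expression gene paints a red disc on black", {
  tpl <- fit_template(embedding_of(cbind(0, 0)), width = 21L, height = 21L,
                      radius = 4L, margin = 2L)
  img <- render_sample(tpl, 1, 0, 0)
  center <- tpl$gene_centers
  inside <- outer((1:21 - center$row)^2, (1:21 - center$col)^2, `+`) <= 16
  expect_true(all(img[, , 1][inside] == 255L))
  expect_true(all(img[, , 1][!inside] == 0L))
  expect_true(all(img[, , 2:3] == 0L))
  # zero values on black background give an all-black image
  img0 <- render_sample(tpl, 0, 0, 0)
  expect_true(all(img0 == 0L))
  expect_error(render_sample(tpl, 1.5, 0, 0),
               class = "omicsgsn_validation_error")
})

test_that("overlapping zones blend per channel (max rule)", {
  # genes 1 and 2 sit 2 px apart after the affine fit; gene 3 anchors the
  # x-extent far away so their discs overlap
  emb <- embedding_of(rbind(c(0, 0), c(0.4, 0), c(4, 0)))
  tpl <- fit_template(emb, width = 41L, height = 21L, radius = 5L,
                      margin = 2L)
  img <- render_sample(tpl, c(0.2, 0.8, 0), c(0, 0, 0), c(0, 0, 0),
                       blend = "max")
  discs <- omicsgsn:::template_disc_indices(tpl)
  overlap <- setdiff(intersect(discs[[1]], discs[[2]]), discs[[3]])
  expect_gt(length(overlap), 0)
  expect_true(all(img[, , 1][overlap] == round(255 * 0.8)))
  expect_true(all(img[, , 1][overlap] == 204L))
  # mean blend averages the two contributions
  imgm <- render_sample(tpl, c(0.2, 0.8, 0), c(0, 0, 0), c(0, 0, 0),
                        blend = "mean")
  expect_true(all(imgm[, , 1][overlap] == round(255 * 0.5)))
})

test_that("every pixel is either in a zone or background, exactly once", {
  set.seed(6)
  tpl <- fit_template(embedding_of(matrix(rnorm(12), 6, 2)),
                      width = 32L, height = 32L, radius = 3L, margin = 2L)
  discs <- omicsgsn:::template_disc_indices(tpl)
  covered <- unique(unlist(discs))
  img <- render_sample(tpl, rep(1, 6), rep(1, 6), rep(1, 6))
  lit <- which(img[, , 1] == 255L)
  expect_identical(sort(covered), sort(lit))
  expect_identical(length(setdiff(seq_len(32 * 32), covered)),
                   32L * 32L - length(covered))
})

test_that("raising one gene's expression never dims red pixels (max blend)", {
  set.seed(13)
  tpl <- fit_template(embedding_of(matrix(rnorm(10), 5, 2)),
                      width = 32L, height = 32L, radius = 4L, margin = 2L)
  ev <- runif(5); mv <- runif(5); cv <- runif(5)
  img1 <- render_sample(tpl, ev, mv, cv, blend = "max")
  ev2 <- ev; ev2[3] <- min(1, ev[3] + 0.3)
  img2 <- render_sample(tpl, ev2, mv, cv, blend = "max")
  expect_true(all(img2[, , 1] >= img1[, , 1]))
  expect_identical(img2[, , 2:3], img1[, , 2:3])
})

test_that("changing methylation only touches the green channel", {
  set.seed(14)
  tpl <- fit_template(embedding_of(matrix(rnorm(8), 4, 2)))
  ev <- runif(4); mv <- runif(4); cv <- runif(4)
  img1 <- render_sample(tpl, ev, mv, cv)
  img2 <- render_sample(tpl, ev, runif(4), cv)
  expect_identical(img1[, , 1], img2[, , 1])
  expect_identical(img1[, , 3], img2[, , 3])
})

test_that("render_dataset writes one deterministic PNG per sample", {
  dir <- withr::local_tempdir()
  sim <- generate_multiomics(synthetic_spec(
    n_samples = 24L, n_genes_raw = 40L, n_genes_signal = 8L, seed = 3L))
  ds <- assemble_dataset(normalize_matrix(sim$expression),
                         normalize_matrix(sim$methylation),
                         normalize_matrix(sim$cna),
                         sim$labels, sim$gene_list)
  emb <- pacmap_embed(unclass(ds$expression), n_nb = 3L, n_mn = 2L,
                      n_fp = 2L, seed = 1L,
                      schedule = phase_schedule(10L, 10L, 20L))
  tpl <- fit_template(emb)
  d1 <- file.path(dir, "a"); d2 <- file.path(dir, "b")
  imgs1 <- render_dataset(ds, tpl, out_dir = d1)
  imgs2 <- render_dataset(ds, tpl, out_dir = d2)
  pngs <- list.files(d1, pattern = "\\.png$")
  expect_length(pngs, length(ds$sample_ids))
  manifest <- readr::read_tsv(file.path(d1, "images_manifest.tsv"),
                              show_col_types = FALSE)
  expect_identical(nrow(manifest), length(ds$sample_ids))
  # byte-identical across re-renders
  for (f in pngs[1:3]) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  # identical omics rows give identical images
  s1 <- ds$sample_ids[1]
  ds2 <- ds
  for (om in c("expression", "methylation", "cna")) {
    ds2[[om]][, 2] <- ds2[[om]][, 1]
  }
  imgs3 <- render_dataset(ds2, tpl)
  expect_identical(imgs3[[1]][, , ], imgs3[[2]][, , ])
})
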