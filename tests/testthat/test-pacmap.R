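# Scaled distances, pair construction, losses, initialization, optimization

test_that("sigma equals the mean 4th-6th neighbor distance (colinear oracle)", {
  pts <- cbind(0:9, 0)
  cache <- compute_sigmas(pts)
  # brute force for every point
  for (i in 1:10) {
    d <- sort(abs((0:9)[-i] - (i - 1)))
    expect_equal(cache$sigma[i], mean(d[4:6]))
  }
  expect_equal(cache$sigma[1], 5)
  expect_equal(cache$sigma[2], 4)
  expect_equal(cache$d2[1, 2], 1 / (5 * 4))
  expect_error(compute_sigmas(pts[1:6, ]), class = "omicsgsn_validation_error")
})

test_that("scaled distance is symmetric, zero on the diagonal and for
           coincident points", {
  set.seed(3)
  pts <- matrix(rnorm(8 * 3), 8, 3)
  pts[8, ] <- pts[1, ]                       # duplicate point
  cache <- compute_sigmas(pts)
  expect_equal(cache$d2, t(cache$d2))
  expect_equal(unname(diag(cache$d2)), rep(0, 8))
  expect_equal(cache$d2[1, 8], 0)
  expect_true(all(cache$d2[upper.tri(cache$d2)][cache$d2_raw[upper.tri(cache$d2)] > 0] > 0))
})

test_that("neighbor selection matches a brute-force full-sort oracle", {
  set.seed(20)
  for (rep in 1:20) {
    n <- sample(8:50, 1)
    pts <- matrix(rnorm(n * 5), n, 5)
    cache <- compute_sigmas(pts)
    n_nb <- sample(1:min(6, n - 1), 1)
    got <- select_neighbor_pairs(cache, n_nb)
    for (i in seq_len(n)) {
      others <- setdiff(seq_len(n), i)
      oracle <- others[order(cache$d2[i, others], others)][seq_len(n_nb)]
      expect_identical(sort(unname(got[got[, 1] == i, 2])), sort(oracle))
    }
  }
})

test_that("neighbor ties break toward the smaller index", {
  # mirror-symmetric layout: points 2 and 3 tie exactly in scaled distance
  pts <- cbind(c(0, -1, 1, -6, 6, -7, 7, -8, 8), 0)
  cache <- compute_sigmas(pts)
  got <- select_neighbor_pairs(cache, 1L)
  expect_identical(unname(got[got[, 1] == 1, 2]), 2L)
  expect_identical(nrow(select_neighbor_pairs(cache, 0L)), 0L)
  expect_error(select_neighbor_pairs(cache, 9L),
               class = "omicsgsn_validation_error")
})

test_that("random pair classes are seeded, reproducible and exclusive", {
  set.seed(2)
  pts <- matrix(rnorm(30 * 4), 30, 4)
  mn1 <- select_midnear_pairs(pts, 3L, seed = 5L)
  mn2 <- select_midnear_pairs(pts, 3L, seed = 5L)
  expect_identical(mn1, mn2)
  expect_true(all(mn1[, 1] != mn1[, 2]))
  cache <- compute_sigmas(pts)
  nb <- select_neighbor_pairs(cache, 4L)
  fp1 <- select_further_pairs(pts, nb, 5L, seed = 6L)
  expect_identical(fp1, select_further_pairs(pts, nb, 5L, seed = 6L))
  # no further pair duplicates a neighbor pair of the same anchor
  key <- function(p) paste(p[, 1], p[, 2])
  expect_length(intersect(key(fp1), key(nb)), 0L)
  expect_true(all(fp1[, 1] != fp1[, 2]))
  expect_identical(nrow(select_midnear_pairs(pts, 0L)), 0L)
  expect_identical(nrow(select_further_pairs(pts, nb, 0L)), 0L)
})

test_that("pair losses match their closed forms and monotone limits", {
  expect_equal(pair_loss(1, "neighbor"), 1 / 11)
  expect_equal(pair_loss(1, "midnear"), 1 / 10001)
  expect_equal(pair_loss(1, "further"), 1 / 2)
  # ya = (0,0), yb = (1,2): dtilde = 6
  dt <- sum(c(1, 2)^2) + 1
  expect_equal(pair_loss(dt, "neighbor"), 0.375)
  expect_equal(pair_loss(dt, "midnear"), 6 / 10006)
  expect_equal(pair_loss(dt, "further"), 1 / 7)
  grid <- exp(seq(log(1), log(1e6), length.out = 200))
  expect_true(all(diff(pair_loss(grid, "neighbor")) > 0))
  expect_true(all(diff(pair_loss(grid, "midnear")) > 0))
  expect_true(all(diff(pair_loss(grid, "further")) < 0))
  expect_lt(abs(pair_loss(1e12, "neighbor") - 1), 1e-10)
  expect_lt(pair_loss(1e12, "further"), 1e-10)
})

test_that("total loss sums pair classes with weights, linearly", {
  coords <- rbind(c(0, 0), c(1, 2), c(5, 5))
  pairs <- omicsgsn:::pair_set_empty()
  z <- total_loss(coords, pairs, c(1, 1, 1))
  expect_equal(z$total, 0)
  pairs$neighbor <- cbind(i = 1L, j = 2L)
  l <- total_loss(coords, pairs, c(1, 0, 0))
  expect_equal(l$total, 0.375)
  l2 <- total_loss(coords, pairs, c(2, 0, 0))
  expect_equal(l2$total, 2 * l$total)
  expect_equal(l2$total,
               2 * l2$loss_nb_total + 0 * l2$loss_mn_total + 0 * l2$loss_fp_total)
})

test_that("PCA initialization reproduces the eigen-decomposition oracle", {
  set.seed(31)
  pts <- matrix(rnorm(50 * 6), 50, 6)
  init <- pca_initialize(pts, scale = 1)
  ev <- eigen(cov(pts))$values[1:2]
  expect_equal(unname(apply(init, 2, var)), ev, tolerance = 1e-8)
  # axis-aligned 2-D input: embedding equals centered input up to sign
  pts2 <- cbind(c(-3, 0, 3, 6), c(0.1, -0.1, -0.1, 0.1))
  init2 <- pca_initialize(pts2, scale = 1)
  centered <- sweep(pts2, 2, colMeans(pts2))
  for (j in 1:2) {
    expect_true(isTRUE(all.equal(init2[, j], centered[, j], tolerance = 1e-8)) ||
                isTRUE(all.equal(init2[, j], -centered[, j], tolerance = 1e-8)))
  }
  expect_error(pca_initialize(matrix(1, 5, 3)),
               class = "omicsgsn_validation_error")
})

test_that("analytic loss gradient matches central finite differences", {
  set.seed(42)
  pts <- matrix(rnorm(10 * 4), 10, 4)
  pairs <- build_pair_set(pts, n_nb = 3L, n_mn = 2L, n_fp = 4L, seed = 7L)
  for (w in list(c(2, 500, 1), c(1, 0, 1), c(3, 3, 1))) {
    coords <- matrix(rnorm(20) * 0.5, 10, 2)
    g <- omicsgsn:::total_loss_gradient(coords, pairs, w)
    h <- 1e-6
    fd <- matrix(0, 10, 2)
    for (i in 1:10) for (j in 1:2) {
      cp <- coords; cp[i, j] <- cp[i, j] + h
      cm <- coords; cm[i, j] <- cm[i, j] - h
      fd[i, j] <- (total_loss(cp, pairs, w)$total -
                     total_loss(cm, pairs, w)$total) / (2 * h)
    }
    expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-8)), 1e-4)
  }
})

test_that("a zero-length schedule returns the initialization unchanged", {
  set.seed(8)
  pts <- matrix(rnorm(12 * 3), 12, 3)
  pairs <- build_pair_set(pts, n_nb = 2L, n_mn = 1L, n_fp = 2L, seed = 1L)
  init <- pca_initialize(pts)
  sch <- phase_schedule(t1 = 1L, t2 = 1L, t3 = 1L)
  sch$t1 <- 0L; sch$t2 <- 0L; sch$t3 <- 0L   # degenerate: no iterations
  out <- optimize_embedding(init, pairs, sch)
  expect_identical(out, init)
})

test_that("optimization separates clusters and lowers the loss", {
  fx <- cluster_points()
  emb <- pacmap_embed(fx$points, seed = 11L)
  co <- cbind(emb$x, emb$y)
  D <- as.matrix(dist(co))
  same <- outer(fx$cluster, fx$cluster, "==") & upper.tri(D)
  diff <- outer(fx$cluster, fx$cluster, "!=") & upper.tri(D)
  expect_lt(mean(D[same]), mean(D[diff]))
  expect_lt(attr(emb, "final_loss"), attr(emb, "initial_loss"))
})

test_that("embedding is reproducible and shape-correct", {
  set.seed(1)
  pts <- matrix(runif(14 * 200), 14, 200)
  rownames(pts) <- paste0("SIG", 1:14)
  e1 <- pacmap_embed(pts, seed = 3L)
  e2 <- pacmap_embed(pts, seed = 3L)
  expect_identical(e1$x, e2$x)
  expect_identical(e1$y, e2$y)
  expect_identical(nrow(e1), 14L)
  expect_true(all(is.finite(c(e1$x, e1$y))))
  expect_identical(e1$gene, paste0("SIG", 1:14))
})

test_that("inputs translated globally give the same embedding; rotating the
           embedded coordinates leaves the loss unchanged", {
  fx <- cluster_points(n = 30L, dims = 5L)
  e1 <- pacmap_embed(fx$points, seed = 2L)
  e2 <- pacmap_embed(sweep(fx$points, 2, rep(7, 5), `+`), seed = 2L)
  expect_equal(e1$x, e2$x, tolerance = 1e-6)
  expect_equal(e1$y, e2$y, tolerance = 1e-6)
  pairs <- attr(e1, "pairs")
  co <- cbind(e1$x, e1$y)
  th <- 0.7
  rot <- co %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(total_loss(rot, pairs, c(2, 3, 1))$total,
               total_loss(co, pairs, c(2, 3, 1))$total, tolerance = 1e-10)
})

test_that("smoothed loss decreases within phase interiors", {
  fx <- cluster_points(n = 40L, dims = 6L)
  pairs <- build_pair_set(fx$points, n_nb = 6L, n_mn = 3L, n_fp = 10L,
                          seed = 4L)
  init <- pca_initialize(fx$points)
  sch <- phase_schedule(t1 = 60L, t2 = 60L, t3 = 120L)
  res <- optimize_embedding(init, pairs, sch, trace = TRUE)
  tr <- res$loss_trace
  smooth <- stats::filter(tr, rep(1 / 5, 5), sides = 1)
  phases <- list(10:60, 70:120, 130:240)
  for (ph in phases) {
    s <- smooth[ph]
    # allow transient increases of at most 5% within a phase
    expect_true(all(diff(s) <= 0.05 * abs(s[-length(s)]) + 1e-9))
    expect_lt(s[length(s)], s[1] + 1e-9)
  }
})
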