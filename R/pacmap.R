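#' Local scale and scaled squared distances for neighbor selection
#'
#' For each point `i`, the local scale `sigma_i` is the mean Euclidean
#' distance to its 4th-6th nearest neighbors; neighbor selection then ranks
#' scaled squared distances `d2_select(i, j) = ||x_i - x_j||^2 / (sigma_i
#' sigma_j)`. The scaling compensates for neighborhoods of very different
#' magnitude in different regions of feature space. Scaled distances are used
#' only to choose neighbor pairs, never during optimization.
#'
#' Ties in the distance ranking are broken by smaller point index, so sigma
#' is deterministic; duplicate points (zero distances) are ranked like any
#' other.
#'
#' @param points Numeric matrix, one row per embedded observation (here:
#'   one gene's profile across samples). At least 7 points are required so
#'   the 4th-6th neighbors exist.
#' @return A `scaled_dist_cache`: list with `sigma` (length-n positive
#'   vector), `d2` (n x n scaled squared distances, symmetric with zero
#'   diagonal) and `d2_raw` (unscaled squared Euclidean distances).
#' @export
compute_sigmas <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 7L) abort_validation("need at least 7 points to compute sigma (4th-6th neighbors).")
  if (!all(is.finite(points))) abort_validation("points contain non-finite coordinates.")
  d2 <- as.matrix(stats::dist(points))^2
  sigma <- vapply(seq_len(n), function(i) {
    d <- sqrt(d2[i, -i])
    mean(sort(d, method = "radix")[4:6])
  }, numeric(1))
  if (any(sigma <= 0)) {
    # >= 7 coincident points: fall back to a tiny positive scale
    sigma[sigma <= 0] <- .Machine$double.eps
  }
  scaled <- d2 / outer(sigma, sigma)
  diag(scaled) <- 0
  structure(list(sigma = sigma, d2 = scaled, d2_raw = d2, n = n),
            class = "scaled_dist_cache")
}

#' Select neighbor pairs under scaled distance
#'
#' For every anchor point `i`, picks its `n_nb` nearest other points by the
#' scaled squared distance in `cache`; ties are broken toward the smaller
#' index, making the selection deterministic.
#'
#' @param cache A `scaled_dist_cache` from [compute_sigmas()].
#' @param n_nb Number of neighbors per anchor (`0 <= n_nb < n`).
#' @return Integer matrix with columns `i`, `j`, one row per pair.
#' @export
select_neighbor_pairs <- function(cache, n_nb) {
  n <- cache$n
  if (!is_count(n_nb)) abort_validation("`n_nb` must be a nonnegative count.")
  if (n_nb >= n) abort_validation("`n_nb` must be smaller than the number of points.")
  if (n_nb == 0L) return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j"))))
  pairs <- lapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(cache$d2[i, others], others)]
    cbind(i = i, j = ord[seq_len(n_nb)])
  })
  do.call(rbind, pairs)
}

#' Select mid-near pairs
#'
#' Mid-near pairs pull moderately distant points together to preserve global
#' structure. For each anchor, each pair is drawn by sampling 6 distinct
#' non-anchor points uniformly and keeping the second closest by (unscaled)
#' Euclidean distance.
#'
#' @param points Numeric point matrix (rows = points).
#' @param n_mn Mid-near pairs per anchor.
#' @param seed Integer seed; the selection is reproducible given the seed.
#' @return Integer matrix with columns `i`, `j`.
#' @export
select_midnear_pairs <- function(points, n_mn, seed = 1L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (!is_count(n_mn)) abort_validation("`n_mn` must be a nonnegative count.")
  if (n_mn == 0L) return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j"))))
  if (n < 7L) abort_validation("need at least 7 points to sample 6 mid-near candidates.")
  d2 <- as.matrix(stats::dist(points))^2
  with_seed(seed, {
    rows <- vector("list", n * n_mn)
    k <- 0L
    for (i in seq_len(n)) {
      for (r in seq_len(n_mn)) {
        cand <- sample(setdiff(seq_len(n), i), 6L)
        second <- cand[order(d2[i, cand], cand)][2L]
        k <- k + 1L
        rows[[k]] <- c(i, second)
      }
    }
    out <- do.call(rbind, rows)
    colnames(out) <- c("i", "j")
    out
  })
}

#' Select further (repulsive) pairs
#'
#' For each anchor, samples `n_fp` non-anchor points uniformly without
#' replacement, excluding that anchor's neighbor pairs.
#'
#' @param points Numeric point matrix.
#' @param neighbor_pairs Integer pair matrix from [select_neighbor_pairs()].
#' @param n_fp Further pairs per anchor.
#' @param seed Integer seed.
#' @return Integer matrix with columns `i`, `j`.
#' @export
select_further_pairs <- function(points, neighbor_pairs, n_fp, seed = 1L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (!is_count(n_fp)) abort_validation("`n_fp` must be a nonnegative count.")
  if (n_fp == 0L) return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j"))))
  with_seed(seed, {
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      nb_i <- neighbor_pairs[neighbor_pairs[, 1L] == i, 2L]
      eligible <- setdiff(seq_len(n), c(i, nb_i))
      if (length(eligible) < n_fp) {
        abort_validation(sprintf(
          "anchor %d has only %d eligible further candidates (< n_fp = %d).",
          i, length(eligible), n_fp))
      }
      rows[[i]] <- cbind(i = i, j = sample(eligible, n_fp))
    }
    do.call(rbind, rows)
  })
}

#' Build the three pair classes in one call
#'
#' @inheritParams select_midnear_pairs
#' @param n_nb,n_mn,n_fp Per-anchor counts of neighbor, mid-near and further
#'   pairs.
#' @param seed Integer seed for the random pair classes.
#' @return A `pair_set`: list of integer pair matrices `neighbor`,
#'   `midnear`, `further`.
#' @export
build_pair_set <- function(points, n_nb = 10L, n_mn = round(0.5 * n_nb),
                           n_fp = 2L * n_nb, seed = 1L) {
  cache <- compute_sigmas(points)
  nb <- select_neighbor_pairs(cache, n_nb)
  mn <- select_midnear_pairs(points, n_mn, seed = seed)
  fp <- select_further_pairs(points, nb, n_fp, seed = seed + 1L)
  structure(list(neighbor = nb, midnear = mn, further = fp), class = "pair_set")
}

pair_set_empty <- function() {
  e <- matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j")))
  structure(list(neighbor = e, midnear = e, further = e), class = "pair_set")
}

#' Per-pair embedding losses
#'
#' Evaluates the pair loss at `dt = ||y_a - y_b||^2 + 1` in the 2-D
#' embedding: attractive `dt / (10 + dt)` for neighbor pairs, weakly
#' attractive `dt / (10000 + dt)` for mid-near pairs, repulsive
#' `1 / (1 + dt)` for further pairs.
#'
#' @param dtilde Numeric vector of `||y_a - y_b||^2 + 1` values (all `>= 1`).
#' @param kind One of `"neighbor"`, `"midnear"`, `"further"`.
#' @return Numeric vector of losses.
#' @export
pair_loss <- function(dtilde, kind = c("neighbor", "midnear", "further")) {
  kind <- match.arg(kind)
  if (any(!is.finite(dtilde))) abort_validation("`dtilde` must be finite.")
  switch(kind,
    neighbor = dtilde / (10 + dtilde),
    midnear  = dtilde / (10000 + dtilde),
    further  = 1 / (1 + dtilde)
  )
}

dtilde_of <- function(coords, pairs) {
  if (nrow(pairs) == 0L) return(numeric(0))
  d <- coords[pairs[, 1L], , drop = FALSE] - coords[pairs[, 2L], , drop = FALSE]
  rowSums(d * d) + 1
}

#' Weighted total embedding loss
#'
#' Sums the per-pair losses in each class and combines them with the weights
#' in force: `total = w_nb * loss_nb + w_mn * loss_mn + w_fp * loss_fp`.
#'
#' @param coords Numeric n x 2 matrix of embedded coordinates.
#' @param pairs A `pair_set` from [build_pair_set()].
#' @param weights Numeric vector `c(w_nb, w_mn, w_fp)` of nonnegative loss
#'   weights.
#' @return A `loss_breakdown`: list with `loss_nb_total`, `loss_mn_total`,
#'   `loss_fp_total` and the weighted `total`.
#' @export
total_loss <- function(coords, pairs, weights = c(2, 3, 1)) {
  stopifnot(length(weights) == 3L, all(weights >= 0))
  nb <- sum(pair_loss(dtilde_of(coords, pairs$neighbor), "neighbor"))
  mn <- sum(pair_loss(dtilde_of(coords, pairs$midnear), "midnear"))
  fp <- sum(pair_loss(dtilde_of(coords, pairs$further), "further"))
  structure(list(
    loss_nb_total = nb, loss_mn_total = mn, loss_fp_total = fp,
    total = weights[1L] * nb + weights[2L] * mn + weights[3L] * fp
  ), class = "loss_breakdown")
}

# Analytic gradient of total_loss()$total with respect to coords.
# d(loss)/d(dt): NB 10/(10+dt)^2, MN 10000/(10000+dt)^2, FP -1/(1+dt)^2;
# d(dt)/d(y_a) = 2 (y_a - y_b).
total_loss_gradient <- function(coords, pairs, weights = c(2, 3, 1)) {
  grad <- matrix(0, nrow(coords), 2L)
  add <- function(p, w, dldt_fun) {
    if (nrow(p) == 0L || w == 0) return(invisible())
    diff <- coords[p[, 1L], , drop = FALSE] - coords[p[, 2L], , drop = FALSE]
    dt <- rowSums(diff * diff) + 1
    g <- (2 * w * dldt_fun(dt)) * diff
    for (col in 1:2) {
      grad[, col] <<- grad[, col] +
        tabulate2(p[, 1L], g[, col], nrow(coords)) -
        tabulate2(p[, 2L], g[, col], nrow(coords))
    }
  }
  add(pairs$neighbor, weights[1L], function(dt) 10 / (10 + dt)^2)
  add(pairs$midnear, weights[2L], function(dt) 10000 / (10000 + dt)^2)
  add(pairs$further, weights[3L], function(dt) -1 / (1 + dt)^2)
  grad
}

# scatter-add: sum w by integer index into a length-n vector
tabulate2 <- function(idx, w, n) {
  out <- numeric(n)
  s <- rowsum(w, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' PCA initialization of the 2-D embedding
#'
#' Projects mean-centered points onto the top two principal axes and scales
#' the result by a small factor so optimization starts from a compact,
#' globally informed layout.
#'
#' @param points Numeric point matrix (>= 2 points, >= 2 columns).
#' @param scale Multiplicative shrink factor applied to the projection
#'   (default 0.01).
#' @return Numeric n x 2 coordinate matrix.
#' @export
pca_initialize <- function(points, scale = 0.01) {
  points <- as.matrix(points)
  if (nrow(points) < 2L || ncol(points) < 2L) {
    abort_validation("PCA initialization needs >= 2 points and >= 2 dimensions.")
  }
  centered <- sweep(points, 2L, colMeans(points))
  if (all(abs(centered) < .Machine$double.eps * 100)) {
    abort_validation("all points are identical; PCA initialization is degenerate.")
  }
  pc <- stats::prcomp(points, center = TRUE, scale. = FALSE, rank. = 2L)
  coords <- pc$x[, 1:2, drop = FALSE]
  if (ncol(coords) < 2L) coords <- cbind(coords, 0)
  unname(coords) * scale
}

#' Three-phase weight schedule for PaCMAP optimization
#'
#' Phase 1 weights mid-near pairs heavily (decaying linearly from
#' `w_mn_init` to `w_mn_mid`) to set up global structure; phase 2 holds a
#' minimal-but-nonzero mid-near weight to refine local structure without
#' losing the global layout; phase 3 drops the mid-near weight to zero to
#' polish local structure. Neighbor and further weights are constant.
#'
#' @param t1,t2,t3 Positive per-phase iteration counts.
#' @param w_nb,w_fp Constant neighbor / further-pair weights.
#' @param w_mn_init,w_mn_mid Mid-near weight at the start of phase 1 and its
#'   value through phase 2.
#' @return A `phase_schedule` object.
#' @export
phase_schedule <- function(t1 = 100L, t2 = 100L, t3 = 250L,
                           w_nb = 2, w_fp = 1,
                           w_mn_init = 1000, w_mn_mid = 3) {
  if (!is_count(t1, 1L) || !is_count(t2, 1L) || !is_count(t3, 1L)) {
    abort_validation("phase lengths t1, t2, t3 must be positive integers.")
  }
  stopifnot(w_nb >= 0, w_fp >= 0, w_mn_init >= 0, w_mn_mid >= 0)
  structure(list(t1 = as.integer(t1), t2 = as.integer(t2), t3 = as.integer(t3),
                 w_nb = w_nb, w_fp = w_fp,
                 w_mn_init = w_mn_init, w_mn_mid = w_mn_mid),
            class = "phase_schedule")
}

schedule_weights <- function(schedule, iter) {
  with(schedule, {
    if (iter <= t1) {
      f <- if (t1 == 1L) 1 else (iter - 1) / (t1 - 1)
      w_mn <- w_mn_init + (w_mn_mid - w_mn_init) * f
    } else if (iter <= t1 + t2) {
      w_mn <- w_mn_mid
    } else {
      w_mn <- 0
    }
    c(w_nb, w_mn, w_fp)
  })
}

#' Optimize the embedding by phased adaptive-moment gradient descent
#'
#' Runs `t1 + t2 + t3` iterations of Adam-style updates on the 2-D
#' coordinates, minimizing [total_loss()] under the weights of
#' [phase_schedule()].
#'
#' @param init Numeric n x 2 initial coordinates (e.g. [pca_initialize()]).
#' @param pairs A `pair_set`.
#' @param schedule A `phase_schedule`.
#' @param lr Adam step size (default 1.0).
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @param trace If `TRUE`, also return the per-iteration total-loss trace.
#' @return Numeric n x 2 optimized coordinates; if `trace`, a list
#'   `list(coords, loss_trace)`.
#' @export
optimize_embedding <- function(init, pairs, schedule = phase_schedule(),
                               lr = 1.0, beta1 = 0.9, beta2 = 0.999,
                               eps = 1e-7, trace = FALSE) {
  coords <- as.matrix(init)
  stopifnot(ncol(coords) == 2L)
  total_iters <- schedule$t1 + schedule$t2 + schedule$t3
  m <- matrix(0, nrow(coords), 2L)
  v <- matrix(0, nrow(coords), 2L)
  loss_trace <- if (trace) numeric(total_iters) else NULL
  if (total_iters == 0L) {
    return(if (trace) list(coords = coords, loss_trace = loss_trace) else coords)
  }
  for (t in seq_len(total_iters)) {
    w <- schedule_weights(schedule, t)
    g <- total_loss_gradient(coords, pairs, w)
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    coords <- coords - lr * mhat / (sqrt(vhat) + eps)
    if (!all(is.finite(coords))) {
      abort_runtime(sprintf("embedding optimization diverged at iteration %d.", t))
    }
    if (trace) loss_trace[t] <- total_loss(coords, pairs, w)$total
  }
  if (trace) list(coords = coords, loss_trace = loss_trace) else coords
}

#' Embed genes into two dimensions with PaCMAP
#'
#' Full pipeline: scaled-distance neighbor graph, the three pair classes,
#' PCA initialization and three-phase adaptive-moment optimization. The
#' embedded observations are genes — each gene is one point, represented by
#' its profile across samples — so nearby genes have similar profiles and
#' the result can serve as a gene-similarity-network map.
#'
#' @param points Numeric matrix, one row per gene (rownames used as point
#'   ids when present) and one column per sample.
#' @param n_nb,n_mn,n_fp Per-anchor pair counts (defaults 10, 5, 20).
#' @param schedule A [phase_schedule()].
#' @param seed Integer seed governing the random pair classes.
#' @param init_scale Shrink factor for the PCA initialization.
#' @param lr Adam step size for the embedding updates.
#' @return A `gsn_embedding`: tibble with columns `gene`, `x`, `y`, plus
#'   attributes recording the configuration and the initial/final loss.
#' @export
pacmap_embed <- function(points, n_nb = 10L, n_mn = round(0.5 * n_nb),
                         n_fp = 2L * n_nb, schedule = phase_schedule(),
                         seed = 1L, init_scale = 0.01, lr = 1.0) {
  points <- as.matrix(points)
  n <- nrow(points)
  n_nb <- min(n_nb, n - 1L)
  n_fp <- min(n_fp, n - 1L - n_nb)
  pairs <- build_pair_set(points, n_nb = n_nb, n_mn = n_mn, n_fp = n_fp,
                          seed = seed)
  init <- pca_initialize(points, scale = init_scale)
  final_w <- schedule_weights(schedule, schedule$t1 + schedule$t2 + schedule$t3)
  loss0 <- total_loss(init, pairs, final_w)$total
  coords <- optimize_embedding(init, pairs, schedule, lr = lr)
  loss1 <- total_loss(coords, pairs, final_w)$total
  ids <- rownames(points) %||% paste0("p", seq_len(n))
  out <- tibble::tibble(gene = ids, x = coords[, 1L], y = coords[, 2L])
  structure(out,
            class = c("gsn_embedding", class(out)),
            pairs = pairs, seed = seed,
            config = list(n_nb = n_nb, n_mn = n_mn, n_fp = n_fp,
                          schedule = unclass(schedule), init_scale = init_scale,
                          lr = lr),
            initial_loss = loss0, final_loss = loss1)
}

embedding_coords <- function(embedding) {
  cbind(x = embedding$x, y = embedding$y)
}

#' Write / read an embedding as TSV (`gene<TAB>x<TAB>y`)
#'
#' @param embedding A `gsn_embedding` (or any tibble with gene/x/y columns).
#' @param path File path.
#' @return `path` (write) or a `gsn_embedding` tibble (read).
#' @export
write_embedding <- function(embedding, path) {
  readr::write_tsv(embedding[, c("gene", "x", "y")], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  df <- readr::read_tsv(path, col_types = "cdd", progress = FALSE)
  structure(df, class = c("gsn_embedding", class(df)))
}

#' @export
print.gsn_embedding <- function(x, ...) {
  cat(sprintf("<gsn_embedding> %d genes", nrow(x)))
  fl <- attr(x, "final_loss")
  if (!is.null(fl)) cat(sprintf(" (final loss %.4f)", fl))
  cat("\n")
  NextMethod()
}
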