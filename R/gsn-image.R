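#' Fit a fixed image template to a gene embedding
#'
#' Affinely maps the 2-D gene coordinates into the pixel rectangle inset by
#' `radius + margin` on every side, preserving aspect ratio (one common
#' scale for x and y), so every gene's circular zone lies fully inside the
#' image. The template is fixed once per dataset: every sample is rendered
#' on the same gene positions.
#'
#' @param embedding A `gsn_embedding` (tibble with `gene`, `x`, `y`).
#' @param width,height Image size in pixels.
#' @param radius Zone radius in pixels.
#' @param margin Extra inset in pixels between zones and the image border.
#' @param background Background RGB triple (0..255 integers).
#' @return A `gsn_template`: list with `width`, `height`, `radius`,
#'   `background` (RGB triple in 0..255) and `gene_centers` (tibble `gene`,
#'   `row`, `col` in pixel coordinates, 1-based).
#' @export
fit_template <- function(embedding, width = 32L, height = 32L,
                         radius = 3L, margin = 2L,
                         background = c(0L, 0L, 0L)) {
  if (nrow(embedding) < 1L) abort_validation("embedding has no genes.")
  inset <- radius + margin
  if (width <= 2L * inset || height <= 2L * inset) {
    abort_validation(sprintf(
      "image %dx%d too small for radius %d + margin %d.",
      width, height, radius, margin))
  }
  x <- embedding$x
  y <- embedding$y
  # continuous pixel coordinates: pixel i covers [i - 0.5, i + 0.5], so the
  # drawable square is [0.5, width + 0.5]; centers stay `inset` inside it
  col_lo <- 0.5 + inset; col_hi <- width + 0.5 - inset
  row_lo <- 0.5 + inset; row_hi <- height + 0.5 - inset
  rngx <- diff(range(x)); rngy <- diff(range(y))
  if (rngx == 0 && rngy == 0) {
    cols <- rep((1 + width) / 2, length(x))
    rows <- rep((1 + height) / 2, length(y))
  } else {
    # one common scale preserves aspect ratio; center within the inset box
    s <- min((col_hi - col_lo) / max(rngx, .Machine$double.eps),
             (row_hi - row_lo) / max(rngy, .Machine$double.eps))
    cx <- mean(range(x)); cy <- mean(range(y))
    cols <- (col_lo + col_hi) / 2 + (x - cx) * s
    # larger embedded y is drawn nearer the top (smaller row index)
    rows <- (row_lo + row_hi) / 2 - (y - cy) * s
  }
  structure(list(
    width = as.integer(width), height = as.integer(height),
    radius = as.integer(radius), margin = as.integer(margin),
    background = as.integer(background),
    gene_centers = tibble::tibble(gene = embedding$gene,
                                  row = round(rows), col = round(cols))
  ), class = "gsn_template")
}

#' @export
print.gsn_template <- function(x, ...) {
  cat(sprintf("<gsn_template> %dx%d px, %d genes, zone radius %d\n",
              x$width, x$height, nrow(x$gene_centers), x$radius))
  invisible(x)
}

# Per-gene list of pixel linear indices (into a height x width matrix)
# within Euclidean distance <= radius of the gene center.
template_disc_indices <- function(template) {
  h <- template$height; w <- template$width; r <- template$radius
  lapply(seq_len(nrow(template$gene_centers)), function(g) {
    r0 <- template$gene_centers$row[g]
    c0 <- template$gene_centers$col[g]
    rows <- max(1L, floor(r0 - r)):min(h, ceiling(r0 + r))
    cols <- max(1L, floor(c0 - r)):min(w, ceiling(c0 + r))
    grid <- expand.grid(row = rows, col = cols)
    keep <- (grid$row - r0)^2 + (grid$col - c0)^2 <= r^2
    (grid$col[keep] - 1L) * h + grid$row[keep]
  })
}

#' Render one sample as an RGB gene-similarity-network image
#'
#' Paints each gene's circular zone with the sample's three omics values:
#' red channel = gene expression, green = DNA methylation, blue = CNA, each
#' as `round(255 * value)`. Pixels covered by several overlapping zones
#' combine channel-wise per `blend`; pixels outside every zone keep the
#' background colour.
#'
#' @param template A [fit_template()] result.
#' @param expr_vals,meth_vals,cna_vals Numeric per-gene vectors in \[0, 1\],
#'   aligned to the template's gene order.
#' @param blend `"max"` (default) or `"mean"` for overlapping zones.
#' @return A `gsn_image`: integer `height x width x 3` array in 0..255.
#' @export
render_sample <- function(template, expr_vals, meth_vals, cna_vals,
                          blend = c("max", "mean")) {
  blend <- match.arg(blend)
  ng <- nrow(template$gene_centers)
  vals <- list(expr_vals, meth_vals, cna_vals)
  for (v in vals) {
    if (length(v) != ng) abort_validation("value vector length != number of genes.")
    if (any(!is.finite(v)) || any(v < 0 | v > 1)) {
      abort_validation("omics values must be finite and within [0, 1].")
    }
  }
  discs <- attr(template, "disc_cache") %||% template_disc_indices(template)
  h <- template$height; w <- template$width
  img <- array(rep(template$background, each = h * w), dim = c(h, w, 3L))
  acc <- array(0, dim = c(h, w, 3L))
  cover <- matrix(0L, h, w)
  for (g in seq_len(ng)) {
    idx <- discs[[g]]
    px <- c(255 * expr_vals[g], 255 * meth_vals[g], 255 * cna_vals[g])
    for (ch in 1:3) {
      off <- (ch - 1L) * h * w
      if (blend == "max") {
        acc[off + idx] <- pmax(acc[off + idx], px[ch])
      } else {
        acc[off + idx] <- acc[off + idx] + px[ch]
      }
    }
    cover[idx] <- cover[idx] + 1L
  }
  covered <- cover > 0L
  for (ch in 1:3) {
    off <- (ch - 1L) * h * w
    chan <- acc[off + seq_len(h * w)]
    if (blend == "mean") chan[covered] <- chan[covered] / cover[covered]
    img[off + which(covered)] <- chan[covered]
  }
  img <- round(img)
  storage.mode(img) <- "integer"
  structure(img, class = c("gsn_image", "array"))
}

#' @export
print.gsn_image <- function(x, ...) {
  cat(sprintf("<gsn_image> %dx%d px RGB, channel means (%.1f, %.1f, %.1f)\n",
              dim(x)[1], dim(x)[2],
              mean(x[, , 1]), mean(x[, , 2]), mean(x[, , 3])))
  invisible(x)
}

#' Render every sample of a dataset and (optionally) write PNGs
#'
#' @param dataset A `multiomics_dataset` whose genes match the template.
#' @param template A [fit_template()] result.
#' @param blend Overlap blend rule, see [render_sample()].
#' @param out_dir If non-`NULL`, one 8-bit RGB PNG per sample is written as
#'   `<sample_id>.png` plus an `images_manifest.tsv` (sample, file, label).
#' @return Named list of `gsn_image` arrays, one per sample, in dataset
#'   sample order.
#' @export
render_dataset <- function(dataset, template, blend = c("max", "mean"),
                           out_dir = NULL) {
  blend <- match.arg(blend)
  if (!identical(dataset$gene_ids, template$gene_centers$gene)) {
    abort_validation("dataset gene order does not match the template.")
  }
  attr(template, "disc_cache") <- template_disc_indices(template)
  imgs <- lapply(dataset$sample_ids, function(s) {
    tryCatch(
      render_sample(template,
                    unclass(dataset$expression)[, s],
                    unclass(dataset$methylation)[, s],
                    unclass(dataset$cna)[, s],
                    blend = blend),
      error = function(e) {
        abort_runtime(sprintf("rendering sample '%s' failed: %s", s,
                              conditionMessage(e)))
      })
  })
  names(imgs) <- dataset$sample_ids
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- file.path(out_dir, paste0(dataset$sample_ids, ".png"))
    for (k in seq_along(imgs)) {
      png::writePNG(array(imgs[[k]] / 255, dim = dim(imgs[[k]])), files[k])
    }
    manifest <- tibble::tibble(
      sample_id = dataset$sample_ids,
      file = basename(files),
      class_index = unname(dataset$labels),
      class_name = dataset$class_names[unname(dataset$labels) + 1L])
    readr::write_tsv(manifest, file.path(out_dir, "images_manifest.tsv"),
                     progress = FALSE)
  }
  imgs
}

#' Serialize a template as JSON
#'
#' @param template A `gsn_template`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_template <- function(template, path) {
  jsonlite::write_json(list(
    width = template$width, height = template$height,
    radius = template$radius, margin = template$margin,
    background = template$background,
    gene_centers = template$gene_centers
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# Stack a list of gsn_images into an H x W x 3 x N numeric array scaled to
# [0, 1] for CNN input.
stack_images <- function(images) {
  d <- dim(images[[1L]])
  out <- array(0, dim = c(d, length(images)))
  for (k in seq_along(images)) out[, , , k] <- images[[k]] / 255
  out
}
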