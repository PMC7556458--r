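#' Extract lateral weight templates
#'
#' A layer with F feature maps and K x K lateral kernels holds F^2 weight
#' templates — one K x K patch for every ordered (source, target) pair of
#' feature maps, including self-connections. Templates are ordered
#' row-major over (source, target): source varies fastest.
#'
#' @param lateral_weights Array (K, K, F_source, F_target) of lateral
#'   convolution weights (e.g. `coef(net)[["b1.Wl"]]`).
#' @return List of class `weight_templates`: `templates` (matrix F^2 x
#'   K^2, one flattened patch per row), `source`, `target` (per-row map
#'   indices), and `k`.
#' @export
extract_templates <- function(lateral_weights) {
  d <- dim(lateral_weights)
  if (length(d) != 4L || d[1] != d[2]) stop("expected a K x K x F x F array")
  if (d[3] != d[4]) stop("non-square feature dimensions: ", d[3], " x ", d[4])
  k <- d[1]; f <- d[3]
  m <- matrix(lateral_weights, nrow = k * k)   # columns ordered (source, target), source fastest
  structure(list(templates = t(m),
                 source = rep(seq_len(f), times = f),
                 target = rep(seq_len(f), each = f),
                 k = k, f = f),
            class = "weight_templates")
}

#' Reassemble templates into the weight array (inverse of extraction)
#' @param tpl A `weight_templates` object.
#' @return Array (K, K, F, F).
#' @export
assemble_templates <- function(tpl) {
  array(t(tpl$templates), c(tpl$k, tpl$k, tpl$f, tpl$f))
}

#' Normalise templates to unit Euclidean length
#'
#' Each flattened template is scaled to norm 1. All-zero templates cannot
#' be normalised; they are excluded with a warning and the count is
#' recorded in `n_excluded`.
#'
#' @param tpl A `weight_templates` object.
#' @return The object with unit-norm templates (possibly fewer rows).
#' @export
normalize_templates <- function(tpl) {
  stopifnot(inherits(tpl, "weight_templates"))
  nrm <- sqrt(rowSums(tpl$templates^2))
  zero <- nrm == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero template(s) excluded from normalisation")
    tpl$templates <- tpl$templates[!zero, , drop = FALSE]
    tpl$source <- tpl$source[!zero]; tpl$target <- tpl$target[!zero]
    nrm <- nrm[!zero]
  }
  tpl$templates <- tpl$templates / nrm
  tpl$n_excluded <- sum(zero)
  tpl
}

#' Principal components of lateral weight templates
#'
#' Mean-centred PCA over the flattened (unit-normalised) templates, each
#' template one sample. The first `k` components summarise the lateral
#' connectivity; each component is reported in its positive form, and its
#' sign-flipped negative form is the same component viewed from templates
#' with negative loadings.
#'
#' @param tpl A (normalised) `weight_templates` object, or a samples x
#'   features matrix.
#' @param k Number of components (5).
#' @return Object of class `lateral_pca`: `components` (k x K^2 unit-norm
#'   rows), `variance_explained` (fractions of total variance,
#'   non-increasing), `loadings` (F^2 x k scores), `center`, plus the
#'   template bookkeeping.
#' @export
lateral_pca <- function(tpl, k = 5L) {
  x <- if (inherits(tpl, "weight_templates")) tpl$templates else as.matrix(tpl)
  if (nrow(x) < k) stop("k = ", k, " exceeds the number of templates")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  if (k > ncol(pc$rotation)) stop("k exceeds the rank of the template ensemble")
  total_var <- sum(pc$sdev^2)
  structure(list(components = t(pc$rotation[, seq_len(k), drop = FALSE]),
                 variance_explained = pc$sdev[seq_len(k)]^2 / total_var,
                 loadings = pc$x[, seq_len(k), drop = FALSE],
                 center = pc$center,
                 rank = sum(pc$sdev > pc$sdev[1] * 1e-12),
                 sdev = pc$sdev,
                 rotation = pc$rotation,
                 source = if (inherits(tpl, "weight_templates")) tpl$source,
                 target = if (inherits(tpl, "weight_templates")) tpl$target,
                 k_kernel = if (inherits(tpl, "weight_templates")) tpl$k),
            class = "lateral_pca")
}

#' @export
print.lateral_pca <- function(x, ...) {
  cat(sprintf("<lateral_pca> %d components over %d templates; variance explained: %s (sum %.1f%%)\n",
              nrow(x$components), nrow(x$loadings),
              paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "),
              100 * sum(x$variance_explained)))
  invisible(x)
}

#' @export
plot.lateral_pca <- function(x, which = seq_len(nrow(x$components)), ...) {
  k <- x$k_kernel %||% as.integer(sqrt(ncol(x$components)))
  old <- graphics::par(mfrow = c(1, length(which)), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(old))
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(64)
  for (i in which) {
    patch <- matrix(x$components[i, ], k, k)
    lim <- max(abs(patch))
    graphics::image(t(patch[k:1, ]), col = pal, zlim = c(-lim, lim),
                    axes = FALSE,
                    main = sprintf("PC%d (%.1f%%)", i, 100 * x$variance_explained[i]))
  }
  invisible(x)
}

#' Strongest-loading feature-map pairs for a component
#'
#' Returns the `m` templates with the largest positive and the `m` with
#' the largest negative loadings on a component, with the (source, target)
#' connection direction preserved. Exact ties resolve in (source, target)
#' index order.
#'
#' @param pca A [lateral_pca()] fitted from a `weight_templates` object.
#' @param component Component index.
#' @param m Pairs per sign.
#' @return List with data frames `positive` and `negative` (columns
#'   `source`, `target`, `loading`), each sorted by |loading| descending.
#' @export
top_loading_pairs <- function(pca, component = 1L, m = 5L) {
  stopifnot(inherits(pca, "lateral_pca"))
  if (component < 1L || component > nrow(pca$components)) stop("component does not exist")
  if (m > nrow(pca$loadings)) stop("m exceeds the number of templates")
  l <- pca$loadings[, component]
  src <- pca$source %||% seq_along(l)
  tgt <- pca$target %||% seq_along(l)
  ord_pos <- order(-l, src, tgt)[seq_len(m)]
  ord_neg <- order(l, src, tgt)[seq_len(m)]
  list(positive = data.frame(source = src[ord_pos], target = tgt[ord_pos],
                             loading = l[ord_pos]),
       negative = data.frame(source = src[ord_neg], target = tgt[ord_neg],
                             loading = l[ord_neg]))
}

#' Export components and loadings as CSV (and optional PNG heatmaps)
#'
#' @param pca A [lateral_pca()].
#' @param dir Output directory.
#' @param png_heatmaps Also write one small PNG heatmap per component.
#' @export
write_lateral_components <- function(pca, dir, png_heatmaps = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(component = seq_along(pca$variance_explained),
                              variance_explained = pca$variance_explained),
                   file.path(dir, "variance_explained.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(pca$components),
                   file.path(dir, "components.csv"), row.names = FALSE)
  ld <- data.frame(source = pca$source %||% NA, target = pca$target %||% NA,
                   pca$loadings)
  utils::write.csv(ld, file.path(dir, "loadings.csv"), row.names = FALSE)
  if (png_heatmaps) {
    k <- pca$k_kernel %||% as.integer(sqrt(ncol(pca$components)))
    for (i in seq_len(nrow(pca$components))) {
      patch <- matrix(pca$components[i, ], k, k)
      img <- (patch - min(patch)) / max(1e-12, diff(range(patch)))
      png::writePNG(img, file.path(dir, sprintf("component_%d.png", i)))
    }
  }
  invisible(dir)
}
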