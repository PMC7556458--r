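#' Architecture specifications for the B/BL model family
#'
#' `make_spec()` constructs a declarative description of one network of the
#' family: the feedforward baseline `B`, its parameter-matched controls
#' `B-K` (larger kernels), `B-F` (doubled feature maps), `B-D` (two
#' convolutions per block), the recurrent `BL` (bottom-up plus lateral
#' connections, unrolled over `n_timesteps`), and `B-U` (the unrolled BL
#' graph with unique parameters per time step, obtained via [build_bu()]).
#'
#' At `scale = "full"` the spec reproduces the published seven-block layout:
#' feature maps 96, 128, 192, 256, 512, 1024, 2048; kernels 7, 5, 3, 3, 3,
#' 3, 1; 2x2 max pooling (stride 2) after blocks 1-6; 128x128x3 input;
#' global average pooling and a dense softmax readout. `B-K` enlarges the
#' kernels to 11, 7, 5, 5, 5, 5, 3 (+4 in block 1, +2 elsewhere), `B-F`
#' doubles every feature-map count, `B-D` duplicates each block's
#' convolution (same F and K, so its extra convolutions are shaped exactly
#' like BL's lateral convolutions), and `BL` adds a lateral convolution of
#' the same F and K in every block.
#'
#' Reduced scales preserve those structural deltas so that the
#' parameter-matching logic is testable at desk size: pass a list with any
#' of `n_blocks`, `base_f` (feature maps double per block from this),
#' `kernels`, `input_size`, `n_classes`, `n_timesteps`.
#'
#' @param family_name One of `"B"`, `"B-K"`, `"B-F"`, `"B-D"`, `"BL"`.
#'   (`"B-U"` specs are derived from a BL spec with [build_bu()].)
#' @param scale `"full"` or a list of reduced-scale overrides (see Details).
#' @param n_classes Number of readout categories (default 1000 at full
#'   scale; 565 is the other full-scale variant in common use).
#' @param n_timesteps Number of time steps for `BL` (default 8 at full
#'   scale). Feedforward families always have `n_timesteps = 1`.
#' @return An object of class `rcnn_spec`: a list with `family`, `blocks`
#'   (each a list with `feature_maps`, `kernel_size`, `convs_per_block`,
#'   `has_lateral`, `followed_by_pool`), `n_classes`, `input_size`,
#'   `n_timesteps`, and `weight_sharing_across_time`.
#' @examples
#' make_spec("BL", scale = list(n_blocks = 2, base_f = 8, input_size = c(16, 16, 3),
#'                              n_classes = 10, n_timesteps = 4))
#' count_parameters(make_spec("B"))$total  # 11,037,768
#' @export
make_spec <- function(family_name, scale = "full", n_classes = NULL,
                      n_timesteps = NULL) {
  families <- c("B", "B-K", "B-F", "B-D", "BL")
  if (!is.character(family_name) || length(family_name) != 1L ||
      !(family_name %in% families)) {
    stop("unknown family tag: ", paste(family_name, collapse = ", "),
         " (expected one of ", paste(families, collapse = ", "),
         "; B-U is built from BL via build_bu())")
  }

  if (identical(scale, "full")) {
    f <- c(96L, 128L, 192L, 256L, 512L, 1024L, 2048L)
    k <- c(7L, 5L, 3L, 3L, 3L, 3L, 1L)
    input_size <- c(128L, 128L, 3L)
    if (is.null(n_classes)) n_classes <- 1000L
  } else if (is.list(scale)) {
    nb <- as.integer(scale$n_blocks %||% 2L)
    base_f <- as.integer(scale$base_f %||% 8L)
    f <- as.integer(base_f * 2^(seq_len(nb) - 1L))
    k <- if (!is.null(scale$kernels)) as.integer(scale$kernels) else rep(3L, nb)
    if (length(k) == 1L) k <- rep(k, nb)
    input_size <- as.integer(scale$input_size %||% c(16L, 16L, 3L))
    if (is.null(n_classes)) n_classes <- as.integer(scale$n_classes %||% 10L)
    if (is.null(n_timesteps) && !is.null(scale$n_timesteps))
      n_timesteps <- as.integer(scale$n_timesteps)
  } else {
    stop("scale must be \"full\" or a list of reduced-scale overrides")
  }
  if (length(k) != length(f)) stop("kernels and feature maps disagree in length")
  if (any(k %% 2L == 0L)) stop("even kernel size requested; kernels must be odd")
  if (any(k < 1L) || any(f < 1L)) stop("kernel sizes and feature maps must be >= 1")

  # family structural deltas
  if (family_name == "B-K") k <- k + ifelse(seq_along(k) == 1L, 4L, 2L)
  if (family_name == "B-F") f <- 2L * f
  convs_per_block <- if (family_name == "B-D") 2L else 1L
  has_lateral <- family_name == "BL"
  if (has_lateral) {
    if (is.null(n_timesteps)) n_timesteps <- if (identical(scale, "full")) 8L else 4L
  } else {
    if (!is.null(n_timesteps) && n_timesteps != 1L)
      stop("feedforward families have n_timesteps = 1")
    n_timesteps <- 1L
  }
  n_blocks <- length(f)
  pooled <- seq_len(n_blocks) < n_blocks  # 2x2 max pool after all but the last block

  blocks <- lapply(seq_len(n_blocks), function(i) {
    list(feature_maps = f[i], kernel_size = k[i],
         convs_per_block = convs_per_block, has_lateral = has_lateral,
         followed_by_pool = pooled[i])
  })
  structure(list(family = family_name, blocks = blocks,
                 n_classes = as.integer(n_classes),
                 input_size = as.integer(input_size),
                 n_timesteps = as.integer(n_timesteps),
                 weight_sharing_across_time = TRUE),
            class = "rcnn_spec")
}

#' Build the unrolled feedforward control (B-U) from a BL spec
#'
#' B-U has the identical computational graph to the BL spec unrolled for its
#' `n_timesteps`, but unique parameters for every convolution (no weight
#' sharing across time) and one dense readout per former time step.
#'
#' @param bl_spec An `rcnn_spec` of family `"BL"`.
#' @return An `rcnn_spec` with `family = "B-U"` and
#'   `weight_sharing_across_time = FALSE`.
#' @export
build_bu <- function(bl_spec) {
  stopifnot(inherits(bl_spec, "rcnn_spec"))
  if (bl_spec$family != "BL" || !any(vapply(bl_spec$blocks, `[[`, TRUE, "has_lateral")))
    stop("build_bu() requires a recurrent (BL) spec")
  spec <- bl_spec
  spec$family <- "B-U"
  spec$weight_sharing_across_time <- FALSE
  spec
}

spec_f <- function(spec) vapply(spec$blocks, `[[`, integer(1), "feature_maps")
spec_k <- function(spec) vapply(spec$blocks, `[[`, integer(1), "kernel_size")
spec_pooled <- function(spec) vapply(spec$blocks, `[[`, logical(1), "followed_by_pool")
spec_lateral <- function(spec) vapply(spec$blocks, `[[`, logical(1), "has_lateral")

is_recurrent <- function(spec) any(spec_lateral(spec)) || spec$family == "B-U"

#' Spatial size of every block's activations
#'
#' Convolutions are size-preserving (stride 1, zero "same" padding); each
#' 2x2 stride-2 max pool halves the spatial size, rounding up (odd inputs
#' are padded on the bottom/right).
#'
#' @param spec An `rcnn_spec`.
#' @return Integer matrix with one row per block, columns `height`, `width`
#'   (the size at which that block's convolutions run).
#' @export
spatial_sizes <- function(spec) {
  h <- spec$input_size[1]; w <- spec$input_size[2]
  out <- matrix(0L, nrow = length(spec$blocks), ncol = 2,
                dimnames = list(NULL, c("height", "width")))
  for (i in seq_along(spec$blocks)) {
    out[i, ] <- c(h, w)
    if (spec$blocks[[i]]$followed_by_pool) {
      h <- as.integer(ceiling(h / 2)); w <- as.integer(ceiling(w / 2))
    }
  }
  out
}

#' @export
print.rcnn_spec <- function(x, ...) {
  f <- spec_f(x); k <- spec_k(x)
  cat(sprintf("<rcnn_spec> family %s | %d blocks | input %s | %d classes | T = %d%s\n",
              x$family, length(x$blocks),
              paste(x$input_size, collapse = "x"), x$n_classes, x$n_timesteps,
              if (!x$weight_sharing_across_time) " | unshared across time" else ""))
  sz <- spatial_sizes(x)
  for (i in seq_along(f)) {
    tags <- c(if (x$blocks[[i]]$convs_per_block == 2L) "x2 conv",
              if (x$blocks[[i]]$has_lateral) "+lateral",
              if (x$blocks[[i]]$followed_by_pool) "pool")
    cat(sprintf("  block %d: F = %4d, K = %d @ %dx%d %s\n", i, f[i], k[i],
                sz[i, 1], sz[i, 2], paste(tags, collapse = " ")))
  }
  cat("  readout: global average pooling + dense softmax\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialise / restore an architecture spec as YAML
#'
#' @param spec An `rcnn_spec`.
#' @param path File path.
#' @return `read_spec` returns the restored `rcnn_spec`; `write_spec`
#'   returns `path` invisibly.
#' @export
write_spec <- function(spec, path) {
  stopifnot(inherits(spec, "rcnn_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_spec
#' @export
read_spec <- function(path) {
  x <- yaml::read_yaml(path)
  x$blocks <- lapply(x$blocks, function(b) {
    b$feature_maps <- as.integer(b$feature_maps)
    b$kernel_size <- as.integer(b$kernel_size)
    b$convs_per_block <- as.integer(b$convs_per_block)
    b
  })
  x$n_classes <- as.integer(x$n_classes)
  x$input_size <- as.integer(x$input_size)
  x$n_timesteps <- as.integer(x$n_timesteps)
  structure(x, class = "rcnn_spec")
}
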