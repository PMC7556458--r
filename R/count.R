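#' Count trainable parameters of an architecture
#'
#' Counts convolution weights, per-time-step batch-normalisation gain and
#' shift (2 per feature map per time step), and the dense readout weights
#' and bias. Convolutions carry no separate bias vector: each convolution is
#' immediately followed by batch normalisation, whose shift term is the
#' additive (bias) parameter for the layer, so a separate bias would be
#' redundant. Batch-norm running statistics are not trainable and are
#' excluded. For `B-U`, every convolution of the unrolled graph has unique
#' weights (`n_timesteps` copies of the bottom-up stack, `n_timesteps - 1`
#' copies of the lateral stack, since the lateral input at the first time
#' step is the zero stack) and there is one readout per time step.
#'
#' @param spec An `rcnn_spec`.
#' @return A list of class `parameter_count` with fields `bottom_up`,
#'   `lateral`, `biases`, `batchnorm`, `readout`, and `total`.
#' @examples
#' count_parameters(make_spec("BL"))$total  # 28,870,920
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "rcnn_spec"))
  f <- spec_f(spec); k <- spec_k(spec)
  f_in <- c(spec$input_size[3], f[-length(f)])
  t_steps <- spec$n_timesteps
  shared <- spec$weight_sharing_across_time

  bu_per_sweep <- sum(k^2 * f_in * f)
  if (any(vapply(spec$blocks, `[[`, integer(1), "convs_per_block") == 2L))
    bu_per_sweep <- bu_per_sweep + sum(k^2 * f * f)  # B-D: second conv F -> F, same K
  lat_per_sweep <- if (any(spec_lateral(spec)) || spec$family == "B-U")
    sum(k^2 * f * f) else 0

  # feature maps normalised per sweep; B-D has batch norm after each of its
  # two convolutions per block
  bn_maps <- sum(f * vapply(spec$blocks, `[[`, integer(1), "convs_per_block"))
  readout_one <- f[length(f)] * spec$n_classes + spec$n_classes

  if (shared) {
    bottom_up <- bu_per_sweep
    lateral <- lat_per_sweep
    batchnorm <- 2 * bn_maps * t_steps
    readout <- readout_one
  } else { # B-U: unique parameters per time step
    bottom_up <- bu_per_sweep * t_steps
    lateral <- lat_per_sweep * (t_steps - 1)
    batchnorm <- 2 * bn_maps * t_steps
    readout <- readout_one * t_steps
  }
  out <- list(bottom_up = bottom_up, lateral = lateral, biases = 0,
              batchnorm = batchnorm, readout = readout)
  out$total <- bottom_up + lateral + out$biases + batchnorm + readout
  structure(out, class = "parameter_count")
}

#' @export
print.parameter_count <- function(x, ...) {
  cat(sprintf("trainable parameters: %s (%.1f million)\n",
              format(x$total, big.mark = ","), x$total / 1e6))
  for (nm in c("bottom_up", "lateral", "biases", "batchnorm", "readout"))
    cat(sprintf("  %-10s %s\n", nm, format(x[[nm]], big.mark = ",")))
  invisible(x)
}

#' Count floating-point operations per time step
#'
#' Under the default convention only convolution and dense multiply-adds
#' are counted, one multiply-add = 2 floating-point operations. Pooling
#' comparisons, batch-norm arithmetic and the activation/softmax
#' element-wise work can be added via `include`. Lateral products with the
#' zero initial state at the first time step are counted by default
#' (`skip_zero_lateral = FALSE`), so per-time-step cost is constant in `t`
#' for BL.
#'
#' @param spec An `rcnn_spec`.
#' @param include Character vector of optional components to count, any of
#'   `"pooling"`, `"batchnorm"`, `"elementwise"`.
#' @param skip_zero_lateral If `TRUE`, lateral multiply-adds at t = 1
#'   (against the all-zero initial state) are not counted.
#' @return A list of class `cost_profile` with `flops_per_timestep`,
#'   `cumulative_flops` (both length `n_timesteps`), and `convention`.
#' @export
count_flops <- function(spec, include = character(0), skip_zero_lateral = FALSE) {
  stopifnot(inherits(spec, "rcnn_spec"))
  f <- spec_f(spec); k <- spec_k(spec)
  f_in <- c(spec$input_size[3], f[-length(f)])
  sz <- spatial_sizes(spec)
  hw <- as.numeric(sz[, 1]) * as.numeric(sz[, 2])
  convs2 <- vapply(spec$blocks, `[[`, integer(1), "convs_per_block") == 2L

  bu_mac <- sum(k^2 * f_in * f * hw) + if (any(convs2)) sum(k^2 * f * f * hw) else 0
  lat_mac <- if (is_recurrent(spec)) sum(k^2 * f * f * hw) else 0
  readout_mac <- f[length(f)] * spec$n_classes

  extra <- 0
  n_units <- sum(f * hw * ifelse(convs2, 2, 1))
  if ("pooling" %in% include) {
    pooled <- spec_pooled(spec)
    extra <- extra + 3 * sum(f[pooled] * ceiling(sz[pooled, 1] / 2) *
                               ceiling(sz[pooled, 2] / 2))  # 3 comparisons per 2x2 window
  }
  if ("batchnorm" %in% include) extra <- extra + 2 * n_units  # scale + shift per unit
  if ("elementwise" %in% include)
    extra <- extra + n_units + 3 * spec$n_classes  # relu per unit; exp/sum/divide readout

  per_t <- rep(2 * (bu_mac + lat_mac + readout_mac) + extra, spec$n_timesteps)
  if (skip_zero_lateral && spec$n_timesteps >= 1) per_t[1] <- per_t[1] - 2 * lat_mac
  structure(list(flops_per_timestep = per_t, cumulative_flops = cumsum(per_t),
                 convention = paste0("multiply-add = 2 flops; components: conv+dense",
                                     if (length(include)) paste0("+", paste(include, collapse = "+")))),
            class = "cost_profile")
}

#' @export
print.cost_profile <- function(x, ...) {
  cat(sprintf("cost profile (%s)\n", x$convention))
  cat("  per time step:", format(x$flops_per_timestep, big.mark = ","), "\n")
  cat("  cumulative:   ", format(x$cumulative_flops, big.mark = ","), "\n")
  invisible(x)
}
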