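test_that("full-scale family specs reproduce the published structural layout", {
  b <- make_spec("B")
  expect_equal(vapply(b$blocks, `[[`, integer(1), "feature_maps"),
               c(96L, 128L, 192L, 256L, 512L, 1024L, 2048L))
  expect_equal(vapply(b$blocks, `[[`, integer(1), "kernel_size"),
               c(7L, 5L, 3L, 3L, 3L, 3L, 1L))
  expect_equal(b$n_timesteps, 1L)
  expect_equal(b$input_size, c(128L, 128L, 3L))

  bk <- make_spec("B-K")
  expect_equal(vapply(bk$blocks, `[[`, integer(1), "kernel_size"),
               c(11L, 7L, 5L, 5L, 5L, 5L, 3L))
  bf <- make_spec("B-F")
  expect_equal(vapply(bf$blocks, `[[`, integer(1), "feature_maps"),
               2L * vapply(b$blocks, `[[`, integer(1), "feature_maps"))

  # B-D's extra convolution matches BL's lateral convolution block for block
  bd <- make_spec("B-D"); bl <- make_spec("BL")
  expect_equal(vapply(bd$blocks, `[[`, integer(1), "feature_maps"),
               vapply(bl$blocks, `[[`, integer(1), "feature_maps"))
  expect_equal(vapply(bd$blocks, `[[`, integer(1), "kernel_size"),
               vapply(bl$blocks, `[[`, integer(1), "kernel_size"))
  expect_true(all(vapply(bd$blocks, `[[`, integer(1), "convs_per_block") == 2L))
  expect_true(all(vapply(bl$blocks, `[[`, logical(1), "has_lateral")))
  expect_equal(bl$n_timesteps, 8L)

  # B and BL share the bottom-up skeleton
  expect_equal(lapply(b$blocks, `[`, c("feature_maps", "kernel_size")),
               lapply(bl$blocks, `[`, c("feature_maps", "kernel_size")))

  expect_error(make_spec("B-Z"), "unknown family")
  expect_error(make_spec("B", list(n_blocks = 1, kernels = 4)), "even kernel")
  expect_error(make_spec("B", n_timesteps = 3), "n_timesteps = 1")

  # minimal one-block instance is valid
  tiny <- make_spec("B", list(n_blocks = 1, base_f = 1, kernels = 1,
                              input_size = c(2, 2, 1), n_classes = 2))
  expect_equal(length(tiny$blocks), 1L)
  expect_s3_class(tiny, "rcnn_spec")
})

test_that("reduced-scale specs preserve the family deltas", {
  sc <- tiny_scale(n_blocks = 3, base_f = 4, input = 16)
  b <- make_spec("B", sc)
  expect_equal(vapply(make_spec("B-K", sc)$blocks, `[[`, integer(1), "kernel_size"),
               vapply(b$blocks, `[[`, integer(1), "kernel_size") + c(4L, 2L, 2L))
  expect_equal(vapply(make_spec("B-F", sc)$blocks, `[[`, integer(1), "feature_maps"),
               2L * vapply(b$blocks, `[[`, integer(1), "feature_maps"))
  expect_true(all(vapply(make_spec("B-D", sc)$blocks, `[[`, integer(1),
                         "convs_per_block") == 2L))
})

test_that("parameter counts match an independent allocation-based oracle", {
  # the oracle: initialise every trainable array and count its elements
  for (spec in list(tiny_bl(T = 3), make_spec("B-D", tiny_scale()),
                    make_spec("B", tiny_scale()),
                    build_bu(tiny_bl(T = 2)))) {
    net <- rcnn_init(spec, seed = 1)
    alloc <- sum(vapply(net$params, length, integer(1)))
    expect_equal(count_parameters(spec)$total, alloc,
                 label = paste("family", spec$family))
  }
})

test_that("parameter-count additivity across recurrence holds", {
  sc <- tiny_scale(n_blocks = 3, base_f = 4)
  bl <- make_spec("BL", c(sc, n_timesteps = 5))
  b <- make_spec("B", sc)
  cb <- count_parameters(b); cl <- count_parameters(bl)
  bn_per_step <- cb$batchnorm
  expect_equal(cl$total, cb$total + cl$lateral + (5 - 1) * bn_per_step)
  # breakdown sums to total
  expect_equal(cl$total, cl$bottom_up + cl$lateral + cl$biases +
                 cl$batchnorm + cl$readout)
})

test_that("B-U construction mirrors the unrolled BL graph", {
  bl <- tiny_bl(T = 4)
  bu <- build_bu(bl)
  expect_false(bu$weight_sharing_across_time)
  cb <- count_parameters(bl); cu <- count_parameters(bu)
  expect_equal(cu$bottom_up, 4 * cb$bottom_up)
  expect_equal(cu$lateral, 3 * cb$lateral)
  expect_equal(cu$readout, 4 * cb$readout)
  expect_equal(cu$batchnorm, cb$batchnorm)

  # T = 1: bottom-up skeleton plus a single readout
  bu1 <- build_bu(tiny_bl(T = 1))
  c1 <- count_parameters(bu1)
  expect_equal(c1$total, count_parameters(make_spec("B", tiny_scale()))$total)
  g <- unroll(build_bu(tiny_bl(T = 2)))
  expect_equal(sum(g$nodes$kind == "readout"), 2L)

  expect_error(build_bu(make_spec("B", tiny_scale())), "recurrent")
})

test_that("flop counts match a brute-force multiply-add enumeration", {
  # 1x1 conv, 1 -> 1 maps, 1x1 image: a single multiply-add = 2 flops
  one <- make_spec("B", list(n_blocks = 1, base_f = 1, kernels = 1,
                             input_size = c(1, 1, 1), n_classes = 1))
  cp <- count_flops(one)
  expect_equal(cp$flops_per_timestep[1], 2 * (1 + 1))  # conv + 1-class readout

  # brute-force enumeration over every output position of a tiny B
  spec <- make_spec("B", tiny_scale(n_blocks = 2, base_f = 3, input = 6, classes = 4))
  f <- c(3L, 6L); k <- c(3L, 3L); f_in <- c(3L, 3L)
  macs <- 0
  h <- 6
  for (n in 1:2) {
    for (i in seq_len(h)) for (j in seq_len(h))
      macs <- macs + k[n]^2 * f_in[n] * f[n]
    h <- h / 2
  }
  macs <- macs + 6 * 4   # dense readout
  expect_equal(count_flops(spec)$flops_per_timestep[1], 2 * macs)

  # BL cumulative cost is strictly increasing and constant per step
  bl <- tiny_bl(T = 4)
  cp <- count_flops(bl)
  expect_true(all(diff(cp$cumulative_flops) > 0))
  expect_equal(length(unique(cp$flops_per_timestep)), 1L)
  # skipping the zero-state lateral product reduces only t = 1
  cps <- count_flops(bl, skip_zero_lateral = TRUE)
  expect_lt(cps$flops_per_timestep[1], cps$flops_per_timestep[2])
  expect_equal(cps$flops_per_timestep[-1], cp$flops_per_timestep[-1])
})

test_that("spatial bookkeeping halves with ceiling after each pooled block", {
  spec <- make_spec("B", list(n_blocks = 4, base_f = 2, input_size = c(21, 13, 3),
                              n_classes = 3))
  sz <- spatial_sizes(spec)
  expect_equal(sz[, "height"], c(21, 11, 6, 3))
  expect_equal(sz[, "width"], c(13, 7, 4, 2))
})

test_that("specs serialise to YAML and back unchanged", {
  spec <- tiny_bl(T = 4)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_spec(spec, path)
  expect_equal(read_spec(path), spec)
})

test_that("weight initialisation is seed-controlled and shape-correct", {
  spec <- tiny_bl(T = 2)
  n1 <- rcnn_init(spec, seed = 5); n2 <- rcnn_init(spec, seed = 5)
  expect_identical(n1$params, n2$params)
  n3 <- rcnn_init(spec, seed = 6)
  expect_false(identical(n1$params, n3$params))
  expect_equal(dim(n1$params[["b1.Wb"]]), c(3, 3, 3, 4))
  expect_equal(dim(n1$params[["b2.Wl"]]), c(3, 3, 8, 8))
  expect_equal(dim(n1$params[["readout.W"]]), c(8, 5))
})
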