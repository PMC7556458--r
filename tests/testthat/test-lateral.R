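test_that("templates extract, count, and reassemble exactly", {
  set.seed(2)
  w <- array(rnorm(3 * 3 * 4 * 4), c(3, 3, 4, 4))
  tpl <- extract_templates(w)
  expect_equal(nrow(tpl$templates), 16L)           # F^2 ordered pairs
  expect_equal(ncol(tpl$templates), 9L)
  expect_identical(assemble_templates(tpl), w)
  # the (source, target) ordering convention: source varies fastest
  expect_equal(tpl$templates[2, ], as.vector(w[, , 2, 1]))
  expect_equal(tpl$source[1:5], c(1L, 2L, 3L, 4L, 1L))
  expect_error(extract_templates(array(0, c(3, 3, 4, 5))), "non-square")
  expect_error(extract_templates(matrix(0, 3, 3)), "K x K x F x F")
})

test_that("normalisation yields unit vectors and excludes zero templates", {
  set.seed(3)
  w <- array(rnorm(3 * 3 * 3 * 3), c(3, 3, 3, 3))
  tpl <- normalize_templates(extract_templates(w))
  expect_equal(sqrt(rowSums(tpl$templates^2)), rep(1, 9), tolerance = 1e-9)
  # already unit-norm templates pass through unchanged
  tpl2 <- normalize_templates(tpl)
  expect_equal(tpl2$templates, tpl$templates, tolerance = 1e-12)
  # zero template flagged and dropped with its count reported
  w[, , 2, 2] <- 0
  expect_warning(tplz <- normalize_templates(extract_templates(w)), "all-zero")
  expect_equal(tplz$n_excluded, 1L)
  expect_equal(nrow(tplz$templates), 8L)
})

test_that("a balanced rank-1 ensemble is fully captured by the first component", {
  set.seed(4)
  c0 <- rnorm(9); c0 <- c0 / sqrt(sum(c0^2))
  tpl <- rbind(matrix(rep(c0, 10), 10, byrow = TRUE),
               matrix(rep(-c0, 10), 10, byrow = TRUE))
  pca <- lateral_pca(tpl, k = 1)
  expect_gt(abs(sum(pca$components[1, ] * c0)), 1 - 1e-9)
  expect_equal(pca$variance_explained[1], 1)
})

test_that("planted orthogonal generators are recovered from noisy mixtures", {
  set.seed(5)
  base <- qr.Q(qr(matrix(rnorm(49 * 3), 49, 3)))
  n <- 400
  coefs <- cbind(rnorm(n, sd = 1), rnorm(n, sd = 0.5), rnorm(n, sd = 0.25))
  tpl <- coefs %*% t(base) + matrix(rnorm(n * 49, sd = 0.01), n, 49)
  pca <- lateral_pca(tpl, k = 5)
  for (j in 1:3)
    expect_gt(abs(stats::cor(pca$components[j, ], base[, j])), 0.99)
  expect_lte(sum(pca$variance_explained), 1)
  expect_true(all(diff(pca$variance_explained) <= 1e-12))
  # components are mutually orthogonal unit vectors
  g <- unname(pca$components %*% t(pca$components))
  expect_equal(g, diag(5), tolerance = 1e-9)
})

test_that("projection onto all components reconstructs the centred templates", {
  set.seed(6)
  w <- array(rnorm(3 * 3 * 4 * 4, sd = 0.3), c(3, 3, 4, 4))
  tpl <- normalize_templates(extract_templates(w))
  pca <- lateral_pca(tpl, k = 5)
  centred <- sweep(tpl$templates, 2, pca$center)
  rest <- pca$rotation[, -(1:5), drop = FALSE]
  recon <- pca$loadings %*% pca$components + (centred %*% rest) %*% t(rest)
  expect_lt(max(abs(recon - centred)), 1e-6)
})

test_that("flipping every template's sign flips loadings, not variance", {
  set.seed(7)
  tpl <- matrix(rnorm(60 * 9), 60, 9)
  p1 <- lateral_pca(tpl, k = 3)
  p2 <- lateral_pca(-tpl, k = 3)
  expect_equal(p2$variance_explained, p1$variance_explained, tolerance = 1e-9)
  for (j in 1:3) {
    flip <- sign(sum(p1$components[j, ] * p2$components[j, ]))
    expect_equal(p2$loadings[, j] * flip, -p1$loadings[, j], tolerance = 1e-6)
  }
})

test_that("top-loading pairs rank by signed loading with index tie-breaks", {
  set.seed(8)
  c0 <- rnorm(9); c0 <- c0 / sqrt(sum(c0^2))
  w <- array(0, c(3, 3, 4, 4))
  for (s in 1:4) for (t in 1:4)
    w[, , s, t] <- ((s + t) %% 3 - 1) * c0 + rnorm(9, sd = 0.01)
  pca <- lateral_pca(normalize_templates(extract_templates(w)), k = 2)
  tp <- top_loading_pairs(pca, component = 1, m = 3)
  expect_equal(nrow(tp$positive), 3L)
  l <- pca$loadings[, 1]
  expect_equal(tp$positive$loading, sort(l, decreasing = TRUE)[1:3])
  expect_equal(tp$negative$loading, sort(l)[1:3])
  # m = F^2 returns every pair, fully sorted
  allp <- top_loading_pairs(pca, 1, m = 16)
  expect_equal(nrow(allp$positive), 16L)
  expect_equal(allp$positive$loading, sort(l, decreasing = TRUE))
  # equal loadings: ties resolved in (source, target) index order
  pca_tie <- pca
  pca_tie$loadings[, 1] <- 1
  tie <- top_loading_pairs(pca_tie, 1, m = 4)
  expect_equal(tie$positive$source, rep(1L, 4))
  expect_equal(tie$positive$target, c(1L, 2L, 3L, 4L))
  expect_error(top_loading_pairs(pca, 1, m = 17), "exceeds")
  expect_error(top_loading_pairs(pca, 5), "does not exist")
})

test_that("component exports write CSV and PNG artifacts", {
  set.seed(9)
  w <- array(rnorm(3 * 3 * 3 * 3), c(3, 3, 3, 3))
  pca <- lateral_pca(normalize_templates(extract_templates(w)), k = 2)
  dir <- withr::local_tempdir()
  write_lateral_components(pca, dir)
  expect_true(file.exists(file.path(dir, "variance_explained.csv")))
  expect_true(file.exists(file.path(dir, "loadings.csv")))
  expect_true(file.exists(file.path(dir, "component_2.png")))
  ve <- utils::read.csv(file.path(dir, "variance_explained.csv"))
  expect_equal(ve$variance_explained, pca$variance_explained, tolerance = 1e-9)
})
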