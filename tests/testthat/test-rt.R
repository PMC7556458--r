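test_that("readout sites fall on the existing readouts for multi-readout models", {
  spec <- make_spec("BL", list(n_blocks = 2, base_f = 4, input_size = c(16, 16, 3),
                               n_classes = 5, n_timesteps = 8))
  sites <- place_readout_sites(spec)
  expect_equal(sites$candidate, 1:8)
  expect_equal(sites$cumulative_cost, count_flops(spec)$cumulative_flops)
  expect_true(all(diff(sites$cumulative_cost) > 0))
})

test_that("site placement on candidate lists matches the exhaustive-subset oracle", {
  costs <- 1:16
  sel <- place_readout_sites(candidate_costs = costs)
  expect_equal(sel$cumulative_cost, seq(2, 16, by = 2))
  # exhaustive oracle on an irregular list
  set.seed(21)
  costs2 <- sort(sample(1:200, 12))
  anchors <- max(costs2) * (1:8) / 8
  best <- Inf
  for (sub in utils::combn(12, 8, simplify = FALSE)) {
    dev <- max(abs(costs2[sub] - anchors))
    if (dev < best) best <- dev
  }
  got <- place_readout_sites(candidate_costs = costs2)
  expect_equal(max(abs(got$cumulative_cost - anchors)), best)
  expect_true(all(diff(got$cumulative_cost) > 0))
  expect_error(place_readout_sites(candidate_costs = 1:5), "fewer than 8")
})

test_that("the projection step preserves structure and is reproducible", {
  set.seed(5)
  x <- matrix(rnorm(40 * 6), 40, 6)
  pr <- fit_projection(x, d = 10)                  # ambient <= d: identity + padding
  z <- predict(pr, x)
  expect_equal(as.vector(stats::dist(z)), as.vector(stats::dist(x)))
  # rank-1 data + tiny noise: first component dominates
  u <- rnorm(50); v <- rnorm(30)
  x1 <- u %*% t(v) + matrix(rnorm(1500, sd = 1e-3), 50, 30)
  pr1 <- fit_projection(x1, d = 5)
  z1 <- predict(pr1, x1)
  expect_gt(stats::var(z1[, 1]) / sum(apply(z1, 2, stats::var)), 0.99)
  # same seed: identical loadings
  expect_identical(fit_projection(x1, d = 5, seed = 3)$rotation,
                   fit_projection(x1, d = 5, seed = 3)$rotation)
  expect_error(fit_projection(x, d = 0), "d must be")
})

test_that("the recurrent sigmoid readout trains and degenerates correctly", {
  set.seed(3)
  n <- 60; d <- 10; s <- 4
  lab <- rep(c(0, 1), each = n / 2)
  load <- array(rnorm(n * s * d), c(n, s, d))
  load[, , 1] <- load[, , 1] + 3 * (2 * lab - 1)     # linearly separable
  br <- train_binary_readout(load, lab, recurrent = TRUE, seed = 1)
  y <- predict(br, load)
  expect_gte(mean((y[, s] > 0.5) == lab), 0.99)
  expect_true(all(y > 0 & y < 1))
  # balanced labels: equal class weights
  expect_equal(unname(br$class_weights[1]), unname(br$class_weights[2]))
  # alpha = 0 collapses to independent static logistic readouts
  br0 <- br; br0$alpha <- 0
  y0 <- predict(br0, load)
  for (t in seq_len(s)) {
    ystatic <- 1 / (1 + exp(-(matrix(load[, t, ], n) %*% br0$w + br0$b)))
    expect_equal(y0[, t], ystatic[, 1])
  }
  # per-site feedforward variant has no recurrence parameter
  brf <- train_binary_readout(load, lab, recurrent = FALSE, seed = 1, n_iter = 200)
  expect_null(brf$alpha)
  expect_equal(dim(brf$W), c(d, s))
  expect_error(train_binary_readout(load, rep(1, n)), "single-class")
})

test_that("network reaction times follow the first-crossing rule", {
  # scan oracle: y = 0.5, 0.6, 0.95; H = 0.693, 0.673, 0.199; theta = 0.3
  expect_equal(network_rt(c(0.5, 0.6, 0.95), 0.3), 3L)
  expect_equal(round(binary_entropy(0.6), 3), 0.673)
  expect_equal(round(binary_entropy(0.95), 3), 0.199)
  # theta >= log 2: site 1 always
  set.seed(4)
  y <- matrix(runif(50 * 8, 0.01, 0.99), 50, 8)
  expect_true(all(network_rt(y, log(2)) == 1L))
  # never reached: final site
  expect_equal(network_rt(matrix(0.5, 3, 8), 0.1), rep(8L, 3))
  # monotone in theta: larger threshold, earlier or equal site
  rt_prev <- rep(0L, 50)
  for (th in seq(log(2), 0.01, length.out = 12)) {
    rt <- network_rt(y, th)
    if (any(rt_prev > 0)) expect_true(all(rt >= rt_prev))
    rt_prev <- rt
  }
})

test_that("double leave-one-out fitting recovers a planted threshold", {
  # replicated difficulty levels make exact recovery possible
  ent <- synth_entropy_trajectories(rep(seq(0.05, 0.95, length.out = 8), each = 5),
                                    jitter_sd = 0)
  theta_star <- 0.3
  subj <- synth_subject_rts(ent, theta_star, n_subjects = 6, trial_noise_sd = 0,
                            gain_sd = 0, offset_sd = 0, seed = 1)
  fit <- rt_fit(ent, subj$rt)
  gi <- findInterval(theta_star, fit$theta_grid)
  expect_true(all(abs(match(fit$thresholds, fit$theta_grid) - gi) <= 1))
  expect_equal(unname(fit$per_subject_r), rep(1, 6), tolerance = 1e-12)
  expect_equal(fit$flagged_folds, 0)
})

test_that("fold hygiene: the held-out cell never influences its own prediction", {
  set.seed(6)
  ent <- synth_entropy_trajectories(runif(20), seed = 2)
  subj <- synth_subject_rts(ent, 0.35, n_subjects = 5, seed = 3)
  fit <- rt_fit(ent, subj$rt)
  hv <- unclass(as.matrix(subj$rt))
  for (cell in list(c(2, 7), c(5, 13))) {
    hv2 <- hv; hv2[cell[1], cell[2]] <- hv2[cell[1], cell[2]] + 700
    fit2 <- rt_fit(ent, rt_matrix(hv2))
    expect_identical(fit2$predicted[cell[1], cell[2]],
                     fit$predicted[cell[1], cell[2]])
    expect_identical(fit2$thresholds[cell[1], cell[2]],
                     fit$thresholds[cell[1], cell[2]])
  }
})

test_that("degenerate reaction-time matrices are rejected", {
  ent <- synth_entropy_trajectories(runif(10, 0.2, 0.8), seed = 4)
  const <- rt_matrix(matrix(500, 4, 10))
  expect_error(rt_fit(ent, const), "constant")
  expect_error(rt_fit(ent, rt_matrix(matrix(500, 4, 10)[, 1:2])), "at least 3")
  expect_error(rt_matrix(matrix(c(-1, 2, 3, 4), 2)), "positive")
})

test_that("held-out correlations and human consistency behave at their limits", {
  set.seed(8)
  hv <- matrix(rep(runif(12, 400, 900), each = 3), 3, 12)  # identical subjects
  expect_equal(unname(human_consistency(rt_matrix(hv))), rep(1, 3))
  expect_equal(unname(evaluate_correlations(hv, rt_matrix(hv))), rep(1, 3))
  # affine decreasing predictions: r = -1
  pred <- 1000 - hv
  expect_equal(unname(evaluate_correlations(pred, rt_matrix(hv))), rep(-1, 3))
  # two anti-correlated subjects
  a <- runif(10, 400, 900)
  anti <- rt_matrix(rbind(a, 1300 - a))
  expect_equal(unname(human_consistency(anti)), c(-1, -1))
  # shared signal + independent noise: consistency strictly inside (0, 1)
  sig <- runif(30, 400, 900)
  noisy <- rt_matrix(t(replicate(8, sig + rnorm(30, sd = 60))))
  r <- human_consistency(noisy)
  expect_true(all(r > 0 & r < 1))
  # random predictions stay near zero on average (null simulation)
  rs <- replicate(100, {
    p <- matrix(runif(2 * 30, 300, 900), 2, 30)
    mean(evaluate_correlations(p, noisy[1:2, , drop = FALSE]))
  })
  expect_lt(abs(mean(rs)), 0.3)
})

test_that("the paired sign-flip permutation test matches exact enumeration", {
  a <- rep(0.6, 10); b <- rep(0.5, 10)
  expect_equal(paired_permutation_test(a, b, exact = TRUE), 2 / 2^10)
  # identical vectors: p = 1
  expect_equal(paired_permutation_test(a, a, n_perm = 500, seed = 1), 1)
  # symmetry in the arguments
  set.seed(9)
  x <- runif(12); y <- runif(12)
  expect_equal(paired_permutation_test(x, y, n_perm = 2000, seed = 7),
               paired_permutation_test(y, x, n_perm = 2000, seed = 7))
  # sampled p-value is reproducible given the seed and bounded below
  p1 <- paired_permutation_test(a, b, n_perm = 1000, seed = 3)
  p2 <- paired_permutation_test(a, b, n_perm = 1000, seed = 3)
  expect_identical(p1, p2)
  expect_gte(p1, 1 / 1001)
  # exact agrees with sampling within Monte Carlo error on a mixed case
  d_exact <- paired_permutation_test(x, y, exact = TRUE)
  d_mc <- paired_permutation_test(x, y, n_perm = 4000, seed = 11)
  expect_lt(abs(d_exact - d_mc), 0.05)
})

test_that("Benjamini-Hochberg step-up matches p.adjust", {
  p <- c(0.01, 0.02, 0.04, 0.8)
  res <- bh_fdr(p, q = 0.05)
  expect_equal(res$adjusted, stats::p.adjust(p, "BH"))
  expect_equal(res$reject, stats::p.adjust(p, "BH") <= 0.05)
  expect_equal(res$adjusted, c(0.04, 0.04, 0.04 * 4 / 3, 0.8))
  expect_true(bh_fdr(0.01)$reject)
  expect_false(any(bh_fdr(rep(1, 5))$reject))
  # adjusted p-values are monotone after sorting
  set.seed(12)
  pr <- runif(20)
  expect_true(all(diff(sort(bh_fdr(pr)$adjusted)) >= -1e-15))
})

test_that("rt_fit residuals and simulate behave like model methods", {
  set.seed(15)
  ent <- synth_entropy_trajectories(runif(24), seed = 16)
  subj <- synth_subject_rts(ent, 0.3, n_subjects = 5, seed = 17)
  fit <- rt_fit(ent, subj$rt)
  res <- residuals(fit)
  expect_equal(dim(res), dim(fit$predicted))
  expect_equal(unname(rowMeans(res)), rep(0, 5), tolerance = 1e-9)
  sims <- simulate(fit, nsim = 2, seed = 4)
  expect_length(sims, 2)
  expect_equal(dim(sims[[1]]), dim(unclass(subj$rt)))
  expect_identical(unclass(simulate(fit, seed = 4)[[1]]), unclass(sims[[1]]))
})

test_that("reaction-time matrices round-trip through CSV", {
  m <- rt_matrix(matrix(runif(12, 300, 900), 3, 4),
                 subject_ids = c("s1", "s2", "s3"),
                 image_ids = paste0("im", 1:4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_rt_matrix(m, path)
  back <- read_rt_matrix(path)
  expect_equal(unclass(back), unclass(m), tolerance = 1e-12)
})
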