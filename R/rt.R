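#' Subject-by-image reaction-time matrices
#'
#' @param values Numeric matrix, subjects in rows, images in columns; all
#'   entries positive (ms for humans, readout-site index 1..8 for
#'   networks). Repeat presentations are averaged per cell before
#'   construction.
#' @param subject_ids,image_ids Optional identifiers.
#' @return An object of class `rt_matrix` (a matrix with id attributes).
#' @export
rt_matrix <- function(values, subject_ids = NULL, image_ids = NULL) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("reaction-time matrix has missing cells")
  if (any(values <= 0)) stop("reaction times must be positive")
  rownames(values) <- subject_ids %||% rownames(values) %||%
    paste0("s", seq_len(nrow(values)))
  colnames(values) <- image_ids %||% colnames(values) %||%
    paste0("img", seq_len(ncol(values)))
  structure(values, class = c("rt_matrix", "matrix"))
}

#' Read / write reaction-time matrices as CSV (rows = subjects)
#' @param path CSV path; first column holds subject ids.
#' @param x An [rt_matrix()].
#' @return `read_rt_matrix` returns an `rt_matrix`.
#' @export
read_rt_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  rt_matrix(as.matrix(df[, -1, drop = FALSE]), subject_ids = df[[1]],
            image_ids = colnames(df)[-1])
}

#' @rdname read_rt_matrix
#' @export
write_rt_matrix <- function(x, path) {
  df <- data.frame(subject = rownames(x), unclass(x), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Place eight readout sites along a network
#'
#' For multi-readout models (BL, B-U) the sites are the existing
#' per-time-step readouts. For single-readout feedforward models a
#' candidate list of (rectifier-output) layers with their cumulative costs
#' is supplied, and the eight candidates minimising the maximum deviation
#' of the cumulative costs from ideal even spacing (anchors j/8 of the
#' total cost, j = 1..8) are selected by dynamic programming; ties resolve
#' toward earlier candidates.
#'
#' @param spec An `rcnn_spec`, or `NULL` when only `candidate_costs` is
#'   given.
#' @param candidate_costs Strictly increasing cumulative costs of candidate
#'   readout layers (required for feedforward single-readout models).
#' @param n_sites Number of sites (8).
#' @return Data frame with `site_index`, `candidate` (index into the
#'   candidate list, or time step for multi-readout models), and
#'   `cumulative_cost`, sorted by cost.
#' @export
place_readout_sites <- function(spec = NULL, candidate_costs = NULL, n_sites = 8L) {
  if (!is.null(spec) && is_recurrent(spec) && spec$n_timesteps > 1L) {
    costs <- count_flops(spec)$cumulative_flops
    if (length(costs) < n_sites)
      stop("fewer than ", n_sites, " readouts available")
    return(data.frame(site_index = seq_len(spec$n_timesteps),
                      candidate = seq_len(spec$n_timesteps),
                      cumulative_cost = costs)[seq_len(n_sites), ])
  }
  if (is.null(candidate_costs))
    stop("feedforward single-readout models need a candidate_costs list")
  costs <- as.numeric(candidate_costs)
  m <- length(costs)
  if (m < n_sites) stop("fewer than ", n_sites, " candidates")
  if (m > 1L && any(diff(costs) <= 0)) stop("candidate costs must be strictly increasing")
  anchors <- max(costs) * seq_len(n_sites) / n_sites
  # minimax assignment: f[j, i] = best achievable max deviation using
  # candidates ending with candidate i in slot j
  dev <- abs(outer(costs, anchors, "-"))          # m x n_sites
  f <- matrix(Inf, m, n_sites)
  from <- matrix(NA_integer_, m, n_sites)
  f[, 1] <- dev[, 1]
  for (j in 2:n_sites) {
    best <- Inf; arg <- NA_integer_
    for (i in seq_len(m)) {
      if (i > 1L && f[i - 1L, j - 1L] < best) { best <- f[i - 1L, j - 1L]; arg <- i - 1L }
      if (i >= j) { f[i, j] <- max(best, dev[i, j]); from[i, j] <- arg }
    }
  }
  end <- which.min(f[, n_sites])
  sel <- integer(n_sites); sel[n_sites] <- end
  for (j in n_sites:2) sel[j - 1L] <- from[sel[j], j]
  data.frame(site_index = seq_len(n_sites), candidate = sel,
             cumulative_cost = costs[sel])
}

#' Fit a linear projection to d dimensions (PCA)
#'
#' Principal components analysis fitted on training activations, used to
#' project readout-site activations into a `d`-dimensional space. For
#' recurrent models the samples from all time steps are pooled into a
#' single fit before calling this. If the ambient dimension is <= `d` the
#' map is the identity (padded with zeros), which preserves pairwise
#' distances exactly.
#'
#' @param x Matrix (samples, ambient dimension).
#' @param d Target dimension (512 in the full-scale pipeline).
#' @param seed Seed (the decomposition here is exact, so the seed only
#'   pins reproducibility of any downstream randomised use).
#' @return Object of class `rt_projection` with `center` and `rotation`.
#' @export
fit_projection <- function(x, d = 512L, seed = 1L) {
  if (d < 1L) stop("d must be >= 1")
  x <- as.matrix(x)
  set.seed(seed)
  if (ncol(x) <= d) {
    rot <- diag(1, nrow = ncol(x), ncol = d)
    return(structure(list(center = rep(0, ncol(x)), rotation = rot,
                          d = as.integer(d), identity = TRUE),
                     class = "rt_projection"))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = d)
  structure(list(center = pc$center, rotation = pc$rotation,
                 d = as.integer(d), identity = FALSE),
            class = "rt_projection")
}

#' @export
predict.rt_projection <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  sweep(newdata, 2, object$center) %*% object$rotation
}

#' Train the binary (super-category) discrimination readout
#'
#' Fits the recurrent sigmoid readout
#' `y_t = sigmoid(alpha * y_{t-1} + w . p_t + b)`, `y_0 = 0.5`, over all
#' sites jointly (one shared `(alpha, w, b)`), or — for feedforward models
#' without weight sharing — an independent static logistic readout
#' `(w_s, b_s)` per site with no recurrence term. Optimised by full-batch
#' Adam (learning rate 0.001, 1000 iterations) on the class-weighted
#' binary cross-entropy, weights inversely proportional to class
#' frequency.
#'
#' @param loadings Array (n_images, n_sites, d) of projected activations.
#' @param labels Binary labels (0/1), one per image.
#' @param recurrent Shared recurrent readout (`TRUE`) or per-site static
#'   readouts (`FALSE`).
#' @param learning_rate,n_iter Optimisation settings.
#' @param seed Seed for the weight initialisation.
#' @return Object of class `binary_readout`; `predict()` returns the
#'   (n_images, n_sites) matrix of sigmoid outputs.
#' @export
train_binary_readout <- function(loadings, labels, recurrent = TRUE,
                                 learning_rate = 0.001, n_iter = 1000L,
                                 seed = 1L) {
  stopifnot(length(dim(loadings)) == 3L)
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2L) stop("single-class training set")
  stopifnot(all(labels %in% c(0, 1)), dim(loadings)[1] == length(labels))
  n <- dim(loadings)[1]; s <- dim(loadings)[2]; d <- dim(loadings)[3]
  cw <- ifelse(labels == 1, n / (2 * sum(labels == 1)), n / (2 * sum(labels == 0)))
  set.seed(seed)
  sig <- function(z) 1 / (1 + exp(-z))

  if (recurrent) {
    theta <- list(alpha = 0, w = stats::rnorm(d, sd = 0.01), b = 0)
    opt <- list(t = 0L, m = list(), v = list())
    P <- lapply(seq_len(s), function(t) matrix(loadings[, t, ], n, d))
    for (it in seq_len(n_iter)) {
      y <- matrix(0, n, s); a <- matrix(0, n, s)
      yprev <- rep(0.5, n)
      for (t in seq_len(s)) {
        a[, t] <- theta$alpha * yprev + P[[t]] %*% theta$w + theta$b
        y[, t] <- sig(a[, t])
        yprev <- y[, t]
      }
      # backward through time; loss = mean over sites of weighted BCE
      dy_next <- rep(0, n)
      g <- list(alpha = 0, w = rep(0, d), b = 0)
      for (t in rev(seq_len(s))) {
        dy <- cw * (y[, t] - labels) / (n * s)     # d(weighted BCE)/da via sigmoid
        da <- dy + dy_next * y[, t] * (1 - y[, t]) # dy_next arrives as dL/dy_t
        yprev <- if (t == 1L) rep(0.5, n) else y[, t - 1L]
        g$alpha <- g$alpha + sum(da * yprev)
        g$w <- g$w + crossprod(P[[t]], da)[, 1]
        g$b <- g$b + sum(da)
        dy_next <- da * theta$alpha
      }
      upd <- adam_update(theta, g, opt, learning_rate, 1e-8)
      theta <- upd$params; opt <- upd$opt
    }
    out <- structure(list(alpha = theta$alpha, w = theta$w, b = theta$b,
                          recurrent = TRUE, d = d, n_sites = s, seed = seed),
                     class = "binary_readout")
  } else {
    W <- matrix(stats::rnorm(d * s, sd = 0.01), d, s)
    bb <- rep(0, s)
    opt <- list(t = 0L, m = list(), v = list())
    P <- lapply(seq_len(s), function(t) matrix(loadings[, t, ], n, d))
    for (it in seq_len(n_iter)) {
      g <- list(W = matrix(0, d, s), b = rep(0, s))
      for (t in seq_len(s)) {
        y <- sig(P[[t]] %*% W[, t] + bb[t])[, 1]
        da <- cw * (y - labels) / (n * s)
        g$W[, t] <- crossprod(P[[t]], da)[, 1]
        g$b[t] <- sum(da)
      }
      upd <- adam_update(list(W = W, b = bb), g, opt, learning_rate, 1e-8)
      W <- upd$params$W; bb <- upd$params$b; opt <- upd$opt
    }
    out <- structure(list(W = W, b = bb, recurrent = FALSE, d = d,
                          n_sites = s, seed = seed),
                     class = "binary_readout")
  }
  out$class_weights <- c(class0 = n / (2 * sum(labels == 0)),
                         class1 = n / (2 * sum(labels == 1)))
  out
}

#' @export
predict.binary_readout <- function(object, loadings, ...) {
  stopifnot(length(dim(loadings)) == 3L, dim(loadings)[2] == object$n_sites)
  n <- dim(loadings)[1]; s <- object$n_sites
  sig <- function(z) 1 / (1 + exp(-z))
  y <- matrix(0, n, s)
  if (object$recurrent) {
    yprev <- rep(0.5, n)
    for (t in seq_len(s)) {
      y[, t] <- sig(object$alpha * yprev +
                      matrix(loadings[, t, ], n) %*% object$w + object$b)
      yprev <- y[, t]
    }
  } else {
    for (t in seq_len(s))
      y[, t] <- sig(matrix(loadings[, t, ], n) %*% object$W[, t] + object$b[t])
  }
  y
}

#' Binary entropy of sigmoid outputs, in nats
#' @param y Values in \[0, 1\].
#' @return `-y log y - (1 - y) log(1 - y)`, elementwise; 0 at y = 0 or 1.
#' @export
binary_entropy <- function(y) {
  h <- -y * log(y) - (1 - y) * log1p(-y)
  h[y %in% c(0, 1)] <- 0
  h
}

#' Network reaction time under an entropy threshold
#'
#' The reaction time for an image is the index of the first readout site
#' whose binary entropy falls to or below `theta`; the final site if the
#' threshold is never reached.
#'
#' @param y Matrix (n_images, n_sites) of sigmoid outputs in (0, 1), or a
#'   single image's vector.
#' @param theta Entropy threshold in nats.
#' @return Integer site indices, one per image.
#' @export
network_rt <- function(y, theta) {
  if (is.null(dim(y))) y <- matrix(y, nrow = 1)
  rt_from_entropy(binary_entropy(y), theta)
}

rt_from_entropy <- function(ent, theta) {
  s <- ncol(ent)
  mp <- t(apply(ent, 1, cummin))
  if (s == 1L) return(rep(1L, nrow(ent)))
  as.integer(rowSums(mp[, -s, drop = FALSE] > theta) + 1L)
}

make_theta_grid <- function(ent) sort(unique(c(0, as.vector(ent), log(2))))

#' Fit an entropy threshold to human reaction times (double leave-one-out)
#'
#' For every (subject, image) cell, the entropy threshold is fitted on the
#' remaining (subjects - 1) x (images - 1) cells: the threshold maximising
#' the Pearson correlation between network reaction times (site index of
#' the first readout at or below threshold) and the mean human reaction
#' time over the training subjects, over the training images. The held-out
#' cell's prediction uses only that fold's threshold, so every prediction
#' is independent of the held-out subject and image. The threshold grid is
#' all unique site entropies plus the endpoints 0 and log(2), which makes
#' the per-fold maximiser exact; ties resolve to the largest threshold
#' (earliest decisions). Folds whose training fold has a constant network
#' or human vector are flagged and fall back to the global median of the
#' fitted thresholds.
#'
#' @param entropies Matrix (n_images, n_sites) of per-site binary
#'   entropies, already averaged across model seeds (average the sigmoid
#'   outputs, then take entropies; see [binary_entropy()]).
#' @param human An [rt_matrix()] (subjects x images), repeats per cell
#'   already averaged.
#' @param theta_grid Optional threshold grid; defaults to the observed
#'   entropies plus endpoints.
#' @return Object of class `rt_fit`: per-fold `thresholds` (subjects x
#'   images), `predicted` network reaction times (subjects x images),
#'   `per_subject_r` (held-out Pearson correlations), `noise_ceiling`
#'   (leave-one-subject-out human consistency), `theta_grid`, and
#'   `flagged_folds`.
#' @export
rt_fit <- function(entropies, human, theta_grid = NULL) {
  stopifnot(inherits(human, "rt_matrix") || is.matrix(human))
  hv <- unclass(as.matrix(human))
  ns <- nrow(hv); ni <- ncol(hv)
  if (ns < 3L || ni < 3L) stop("need at least 3 subjects and 3 images")
  stopifnot(nrow(entropies) == ni)
  if (stats::sd(as.vector(hv)) == 0)
    stop("constant human reaction-time matrix: correlation undefined")
  grid <- theta_grid %||% make_theta_grid(entropies)
  ng <- length(grid)
  rt_grid <- vapply(grid, function(th) rt_from_entropy(entropies, th),
                    integer(ni))                   # (images, grid)

  thr_idx <- matrix(NA_integer_, ns, ni)
  flagged <- matrix(FALSE, ns, ni)
  X <- rt_grid * 1.0
  Sx <- colSums(X); Sxx <- colSums(X * X)
  for (s in seq_len(ns)) {
    h <- colMeans(hv[-s, , drop = FALSE])          # training subjects' mean RT
    Sxy <- crossprod(X, h)[, 1]
    Sy <- sum(h); Syy <- sum(h * h)
    n1 <- ni - 1
    for (i in seq_len(ni)) {
      sx <- Sx - X[i, ]; sxx <- Sxx - X[i, ]^2
      sxy <- Sxy - X[i, ] * h[i]
      sy <- Sy - h[i]; syy <- Syy - h[i]^2
      vx <- sxx - sx^2 / n1
      vy <- syy - sy^2 / n1
      if (vy <= 1e-12 || all(vx <= 1e-12)) { flagged[s, i] <- TRUE; next }
      r <- (sxy - sx * sy / n1) / sqrt(pmax(vx, 0) * vy)
      r[vx <= 1e-12] <- -Inf
      best <- max(r)
      thr_idx[s, i] <- max(which(r >= best - 1e-12)) # largest theta among maximisers
    }
  }
  if (all(flagged)) stop("all folds degenerate: constant training vectors")
  if (any(flagged)) {
    fallback <- stats::median(grid[thr_idx[!flagged]])
    gi <- which.min(abs(grid - fallback))
    thr_idx[flagged] <- gi
  }
  predicted <- matrix(rt_grid[cbind(rep(seq_len(ni), each = ns),
                                    as.vector(thr_idx))], ns, ni)
  fit <- structure(list(thresholds = matrix(grid[thr_idx], ns, ni),
                        predicted = predicted,
                        theta_grid = grid,
                        flagged_folds = sum(flagged),
                        human = hv,
                        entropies = entropies),
                   class = "rt_fit")
  fit$per_subject_r <- evaluate_correlations(fit, hv)
  fit$noise_ceiling <- human_consistency(hv)
  fit
}

#' Held-out correlation between predicted and observed reaction times
#'
#' One Pearson correlation per subject across images. Constant vectors
#' yield `NA`.
#'
#' @param result An `rt_fit` (or a subjects x images prediction matrix).
#' @param human The human [rt_matrix()].
#' @return Named numeric vector of per-subject correlations.
#' @export
evaluate_correlations <- function(result, human) {
  pred <- if (inherits(result, "rt_fit")) result$predicted else as.matrix(result)
  hv <- unclass(as.matrix(human))
  stopifnot(all(dim(pred) == dim(hv)))
  r <- vapply(seq_len(nrow(hv)), function(s) {
    if (stats::sd(pred[s, ]) == 0 || stats::sd(hv[s, ]) == 0) return(NA_real_)
    stats::cor(pred[s, ], hv[s, ])
  }, numeric(1))
  names(r) <- rownames(hv) %||% paste0("s", seq_len(nrow(hv)))
  r
}

#' Human consistency (lower bound on the noise ceiling)
#'
#' Correlates each subject's reaction times with the average reaction time
#' of all other subjects. This leave-one-subject-out correlation bounds
#' from below the correlation the true model could achieve given
#' inter-subject variability.
#'
#' @param human An [rt_matrix()] with at least 2 subjects.
#' @return Per-subject correlations.
#' @export
human_consistency <- function(human) {
  hv <- unclass(as.matrix(human))
  if (nrow(hv) < 2L) stop("need at least 2 subjects")
  r <- vapply(seq_len(nrow(hv)), function(s) {
    others <- colMeans(hv[-s, , drop = FALSE])
    if (stats::sd(hv[s, ]) == 0 || stats::sd(others) == 0) return(NA_real_)
    stats::cor(hv[s, ], others)
  }, numeric(1))
  names(r) <- rownames(hv) %||% paste0("s", seq_len(nrow(hv)))
  r
}

#' Paired sign-flip permutation test for a difference in means
#'
#' Two-tailed test of mean(a - b) = 0 by randomly flipping the sign of
#' each paired difference. The identity permutation is included, so the
#' p-value is at least 1/(n_perm + 1). With `exact = TRUE` (n <= 16) all
#' 2^n sign assignments are enumerated.
#'
#' @param r_a,r_b Paired per-subject values (e.g. model-human
#'   correlations for two models).
#' @param n_perm Number of random permutations (10,000 by default).
#' @param seed Seed for the sign draws.
#' @param exact Enumerate all sign assignments instead of sampling.
#' @return Two-tailed p-value.
#' @export
paired_permutation_test <- function(r_a, r_b, n_perm = 10000L, seed = 1L,
                                    exact = FALSE) {
  stopifnot(length(r_a) == length(r_b))
  d <- r_a - r_b
  d <- d[is.finite(d)]
  n <- length(d)
  obs <- abs(mean(d))
  if (exact) {
    if (n > 16L) stop("exact enumeration limited to n <= 16")
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    stat <- abs(signs %*% d) / n
    return(mean(stat >= obs - 1e-15))
  }
  set.seed(seed)
  hits <- 0L
  for (p in seq_len(n_perm)) {
    s <- sample(c(-1, 1), n, replace = TRUE)
    if (abs(mean(s * d)) >= obs - 1e-15) hits <- hits + 1L
  }
  (1 + hits) / (n_perm + 1)
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Standard step-up procedure at rate `q` (adjusted p-values via
#' `stats::p.adjust(method = "BH")`).
#'
#' @param p_values Numeric vector in \[0, 1\].
#' @param q False-discovery rate (0.05).
#' @return List with `adjusted` p-values and logical `reject` flags.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  adj <- stats::p.adjust(p_values, method = "BH")
  list(adjusted = adj, reject = adj <= q)
}

#' @export
print.rt_fit <- function(x, ...) {
  cat(sprintf("<rt_fit> %d subjects x %d images | grid size %d | %d flagged folds\n",
              nrow(x$predicted), ncol(x$predicted), length(x$theta_grid),
              x$flagged_folds))
  cat(sprintf("  mean held-out r = %.3f | noise ceiling (lower bound) = %.3f\n",
              mean(x$per_subject_r, na.rm = TRUE),
              mean(x$noise_ceiling, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.rt_fit <- function(object, ...) {
  out <- data.frame(subject = names(object$per_subject_r),
                    r = object$per_subject_r,
                    noise_ceiling = object$noise_ceiling,
                    median_threshold = apply(object$thresholds, 1, stats::median))
  rownames(out) <- NULL
  out
}

#' @export
predict.rt_fit <- function(object, ...) object$predicted

#' @export
coef.rt_fit <- function(object, ...) {
  c(median_threshold = stats::median(as.vector(object$thresholds)))
}

#' @export
residuals.rt_fit <- function(object, ...) {
  # residual millisecond RT after per-subject affine calibration of the
  # predicted site indices (Pearson fitting is scale-free, so residuals are
  # reported on the calibrated scale)
  hv <- object$human; pred <- object$predicted
  res <- hv * NA_real_
  for (s in seq_len(nrow(hv))) {
    if (stats::sd(pred[s, ]) == 0) next
    res[s, ] <- stats::resid(stats::lm(hv[s, ] ~ pred[s, ]))
  }
  res
}

#' Simulate subject reaction-time matrices from a fitted threshold
#'
#' Draws synthetic subject groups of the same size as the fitted data,
#' planted at the fit's median threshold, using the stored entropy
#' trajectories and the default subject-noise model.
#'
#' @param object An [rt_fit()].
#' @param nsim Number of simulated groups.
#' @param seed Seed for the draws.
#' @param ... Unused.
#' @return List of `nsim` [rt_matrix()] objects.
#' @export
simulate.rt_fit <- function(object, nsim = 1, seed = 1L, ...) {
  theta <- stats::median(as.vector(object$thresholds))
  theta <- min(max(theta, 1e-6), log(2) - 1e-6)
  lapply(seq_len(nsim), function(i)
    synth_subject_rts(object$entropies, theta,
                      n_subjects = nrow(object$predicted),
                      seed = seed + i - 1L)$rt)
}

#' @export
plot.rt_fit <- function(x, ...) {
  r <- x$per_subject_r; nc <- x$noise_ceiling
  graphics::plot(rep(1, length(r)), r, xlim = c(0.5, 2.5),
                 ylim = range(c(r, nc, 0), na.rm = TRUE), xaxt = "n",
                 xlab = "", ylab = "Pearson r", main = "model vs noise ceiling")
  graphics::points(rep(2, length(nc)), nc)
  graphics::axis(1, at = c(1, 2), labels = c("model", "consistency"))
  graphics::segments(0.8, mean(r, na.rm = TRUE), 1.2, mean(r, na.rm = TRUE))
  graphics::segments(1.8, mean(nc, na.rm = TRUE), 2.2, mean(nc, na.rm = TRUE))
  invisible(x)
}
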