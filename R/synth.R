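#' Synthetic image-classification task
#'
#' Generates a multi-class image task with graded per-image difficulty and
#' a binary super-category partition, standing in for a large natural-image
#' task so that every pipeline stage runs at desk scale. Each class has a
#' procedural prototype (a distinct shape drawn in a distinct colour on a
#' mid-grey background); each image is its class prototype corrupted by
#' additive Gaussian pixel noise whose standard deviation (the image's
#' difficulty) is drawn uniformly from \[0, sigma_max\]. At difficulty 0 a
#' nearest-prototype classifier is perfect; accuracy decreases as
#' difficulty grows, so entropy-threshold reaction times vary across
#' images. Classes are split into two super-categories (even/odd class
#' index), the analogue of an animate/inanimate partition.
#'
#' @param n_classes Number of classes (>= 2; default 10).
#' @param image_size Image side in pixels (default 32; minimum 8).
#' @param n_per_class Images generated per class (training and evaluation
#'   subsets are split downstream).
#' @param sigma_max Maximum difficulty (noise standard deviation on
#'   \[0, 1\]-scaled pixels; default 0.8).
#' @param seed Seed; the same seed reproduces the dataset exactly.
#' @return List of class `synth_task`: `x` (image_size, image_size, 3, n),
#'   `y` (class labels), `supercategory` (0/1 per image), `difficulty`
#'   (per-image noise sd), `prototypes` (image_size, image_size, 3,
#'   n_classes), `supercategory_map` (0/1 per class), and the config.
#' @export
synth_task <- function(n_classes = 10L, image_size = 32L, n_per_class = 50L,
                       sigma_max = 0.8, seed = 1L) {
  if (n_classes < 2L) stop("need at least 2 classes")
  if (image_size < 8L) stop("image_size too small to draw prototypes (< 8)")
  set.seed(seed)
  protos <- array(0, c(image_size, image_size, 3L, n_classes))
  for (c in seq_len(n_classes)) protos[, , , c] <- class_prototype(c, image_size)
  supercategory_map <- (seq_len(n_classes) - 1L) %% 2L   # even/odd class split
  n <- n_classes * n_per_class
  y <- rep(seq_len(n_classes), each = n_per_class)
  y <- y[sample.int(n)]
  difficulty <- stats::runif(n, 0, sigma_max)
  x <- array(0, c(image_size, image_size, 3L, n))
  for (i in seq_len(n)) {
    img <- protos[, , , y[i]] +
      stats::rnorm(image_size * image_size * 3L, sd = difficulty[i])
    img[img < 0] <- 0; img[img > 1] <- 1
    x[, , , i] <- img
  }
  structure(list(x = x, y = y, supercategory = supercategory_map[y],
                 difficulty = difficulty, prototypes = protos,
                 supercategory_map = supercategory_map,
                 config = list(n_classes = n_classes, image_size = image_size,
                               n_per_class = n_per_class, sigma_max = sigma_max,
                               seed = seed)),
            class = "synth_task")
}

# deterministic per-class prototype: one shape + one colour per class
class_prototype <- function(class_id, s) {
  shapes <- c("disk", "square", "hbar", "vbar", "cross")
  colours <- rbind(c(1, 0.2, 0.2), c(0.2, 1, 0.2), c(0.2, 0.4, 1),
                   c(1, 1, 0.2), c(1, 0.3, 1), c(0.3, 1, 1))
  shape <- shapes[(class_id - 1L) %% length(shapes) + 1L]
  col <- colours[(class_id - 1L) %/% length(shapes) %% nrow(colours) + 1L, ]
  cx <- (s + 1) / 2
  gx <- matrix(seq_len(s), s, s)         # row coordinate
  gy <- matrix(seq_len(s), s, s, byrow = TRUE)
  r <- s / 4
  mask <- switch(shape,
    disk = (gx - cx)^2 + (gy - cx)^2 <= r^2,
    square = abs(gx - cx) <= r & abs(gy - cx) <= r,
    hbar = abs(gx - cx) <= r / 2 & abs(gy - cx) <= 1.6 * r,
    vbar = abs(gy - cx) <= r / 2 & abs(gx - cx) <= 1.6 * r,
    cross = (abs(gx - cx) <= r / 2 & abs(gy - cx) <= 1.6 * r) |
            (abs(gy - cx) <= r / 2 & abs(gx - cx) <= 1.6 * r))
  img <- array(0.5, c(s, s, 3L))         # mid-grey background
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- col[ch]
    img[, , ch] <- plane
  }
  img
}

#' Nearest-prototype reference classifier
#'
#' Assigns each image to the class whose prototype is closest in Euclidean
#' pixel distance. Used to verify the difficulty gradient of the synthetic
#' task.
#'
#' @param task A [synth_task()] (or its prototypes) providing prototypes.
#' @param x Image array (h, w, 3, n); defaults to the task's own images.
#' @return Integer class labels.
#' @export
nearest_prototype <- function(task, x = task$x) {
  protos <- task$prototypes
  np <- dim(protos)[4]
  pm <- matrix(protos, ncol = np)
  xm <- matrix(x, ncol = dim(x)[4])
  d2 <- -2 * crossprod(pm, xm) + colSums(pm^2)
  apply(d2, 2, which.min)
}

#' Write a synthetic task to disk as PNG files + label CSV
#'
#' @param task A [synth_task()].
#' @param dir Output directory; images as `img_<i>.png`, labels in
#'   `labels.csv` (columns `file`, `class`, `supercategory`, `difficulty`).
#' @export
write_synth_task <- function(task, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(task$x)[4]
  files <- sprintf("img_%04d.png", seq_len(n))
  for (i in seq_len(n))
    png::writePNG(task$x[, , , i], file.path(dir, files[i]))
  utils::write.csv(data.frame(file = files, class = task$y,
                              supercategory = task$supercategory,
                              difficulty = task$difficulty),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' Synthetic subject reaction-time matrices with a planted threshold
#'
#' Emulates a group of subjects performing a binary discrimination task:
#' the "true" reaction time for an image is the readout-site index at
#' which a reference model's binary entropy first falls below a planted
#' threshold theta*. Each subject s responds with
#' `gain_s * site + offset_s + noise`, noise Gaussian per trial, averaged
#' over `repeats` presentations per image. Subject gains and offsets are
#' drawn once per subject. Defaults mirror a 20-subject, 96-image, 6-repeat
#' design with reaction times on a millisecond scale.
#'
#' @param entropies Matrix (n_images, n_sites) of reference-model binary
#'   entropies per readout site.
#' @param planted_threshold theta* in (0, log 2).
#' @param n_subjects Number of subjects (20).
#' @param gain_mean,gain_sd Per-subject gain distribution (ms per site;
#'   default 70 +- 10).
#' @param offset_mean,offset_sd Per-subject offset distribution (ms;
#'   default 450 +- 50).
#' @param trial_noise_sd Per-trial Gaussian noise (ms; default 200,
#'   which after averaging 6 repeats yields subject-consistency
#'   correlations around 0.8, in the range typical of speeded
#'   categorisation groups).
#' @param repeats Presentations per image averaged into each cell (6).
#' @param seed Seed.
#' @return List of class `synth_subjects`: `rt` (an [rt_matrix()]),
#'   `true_sites` (planted per-image site indices), `gains`, `offsets`,
#'   and the config.
#' @export
synth_subject_rts <- function(entropies, planted_threshold,
                              n_subjects = 20L, gain_mean = 70, gain_sd = 10,
                              offset_mean = 450, offset_sd = 50,
                              trial_noise_sd = 200, repeats = 6L, seed = 1L) {
  if (planted_threshold <= 0 || planted_threshold >= log(2))
    stop("planted_threshold must lie in (0, log 2)")
  set.seed(seed)
  sites <- rt_from_entropy(entropies, planted_threshold)
  ni <- length(sites)
  gains <- stats::rnorm(n_subjects, gain_mean, gain_sd)
  offsets <- stats::rnorm(n_subjects, offset_mean, offset_sd)
  vals <- matrix(0, n_subjects, ni)
  for (s in seq_len(n_subjects)) {
    trials <- matrix(gains[s] * sites + offsets[s], repeats, ni, byrow = TRUE) +
      stats::rnorm(repeats * ni, sd = trial_noise_sd)
    vals[s, ] <- colMeans(trials)
  }
  vals[vals <= 0] <- 1e-3        # reaction times are positive by construction
  structure(list(rt = rt_matrix(vals), true_sites = sites, gains = gains,
                 offsets = offsets,
                 config = list(planted_threshold = planted_threshold,
                               n_subjects = n_subjects, repeats = repeats,
                               trial_noise_sd = trial_noise_sd, seed = seed)),
            class = "synth_subjects")
}

#' Reference entropy trajectories for synthetic images
#'
#' Produces per-image, per-site binary-entropy trajectories that fall over
#' sites at a rate governed by each image's difficulty: confidence of a
#' reference discriminator grows as evidence accumulates, more slowly for
#' harder images. Used to exercise the reaction-time pipeline without
#' training a network.
#'
#' @param difficulty Per-image difficulty in \[0, 1\] (e.g. a
#'   [synth_task()]'s `difficulty` divided by its `sigma_max`).
#' @param n_sites Number of readout sites (8).
#' @param rate Confidence growth per site for the easiest image.
#' @param seed Seed for small trajectory jitter.
#' @param jitter_sd Standard deviation of the per-site log-odds jitter.
#' @return Matrix (n_images, n_sites) of binary entropies in (0, log 2\].
#' @export
synth_entropy_trajectories <- function(difficulty, n_sites = 8L, rate = 1.2,
                                       seed = 1L, jitter_sd = 0.05) {
  set.seed(seed)
  ni <- length(difficulty)
  ent <- matrix(0, ni, n_sites)
  for (i in seq_len(ni)) {
    speed <- rate * (1.05 - difficulty[i])     # harder images gain evidence slower
    logodds <- speed * seq_len(n_sites) +
      stats::rnorm(n_sites, sd = jitter_sd)
    y <- 1 / (1 + exp(-pmax(logodds, 1e-4)))
    ent[i, ] <- binary_entropy(pmin(y, 1 - 1e-12))
  }
  ent
}
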