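# shared fixtures, built in code at test time

tiny_scale <- function(n_blocks = 2, base_f = 4, input = 8, classes = 5)
  list(n_blocks = n_blocks, base_f = base_f,
       input_size = c(input, input, 3L), n_classes = classes)

tiny_bl <- function(T = 3, ...) make_spec("BL", c(tiny_scale(...), n_timesteps = T))

# random valid readout sequence (softmax of gaussian logits)
rand_seq <- function(n = 10, T = 4, C = 5, seed = 1, costs = NULL) {
  set.seed(seed)
  p <- array(exp(rnorm(n * T * C)), c(n, T, C))
  p <- p / array(rep(apply(p, c(1, 2), sum), C), c(n, T, C))
  readout_sequence(p, site_costs = costs)
}

# binary distribution with a prescribed entropy (numeric inversion)
dist_with_entropy <- function(h) {
  if (h >= log(2)) return(c(0.5, 0.5))
  p <- stats::uniroot(function(p) -p * log(p) - (1 - p) * log(1 - p) - h,
                      c(0.5 + 1e-12, 1 - 1e-12))$root
  c(p, 1 - p)
}

# desk-scale training conditions used throughout the heavier tests
desk_train_config <- function(seed, epochs = 14)
  train_config(epochs = epochs, batch_size = 20, learning_rate = 0.01,
               adam_epsilon = 1e-3, seed = seed, augment = FALSE)

desk_bl_spec <- function(classes = 10)
  make_spec("BL", list(n_blocks = 2, base_f = 8, input_size = c(16, 16, 3),
                       n_classes = classes, n_timesteps = 4))
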