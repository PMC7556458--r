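#' Initialise a network from a spec
#'
#' Convolution weights use variance-scaling fan-in (He) initialisation,
#' batch-norm gain starts at 1 and shift at 0 (the shift is the layer's
#' additive term; convolutions carry no separate bias), and the dense
#' readout uses fan-in scaling with a zero bias. All draws are controlled
#' by `seed`.
#'
#' @param spec An `rcnn_spec`.
#' @param seed Integer seed for the weight draws.
#' @return An object of class `rcnn_net`: a list with `spec`, `params`
#'   (flat named list of arrays), and `state` (batch-norm running
#'   statistics, initialised to mean 0 / variance 1).
#' @export
rcnn_init <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "rcnn_spec"))
  set.seed(seed)
  f <- spec_f(spec); k <- spec_k(spec)
  f_in <- c(spec$input_size[3], f[-length(f)])
  t_steps <- spec$n_timesteps
  shared <- spec$weight_sharing_across_time
  params <- list(); state <- list()

  he <- function(k, ci, co) array(stats::rnorm(k * k * ci * co,
                                               sd = sqrt(2 / (k * k * ci))),
                                  c(k, k, ci, co))
  for (n in seq_along(f)) {
    bu_ts <- if (shared) 0L else seq_len(t_steps)   # 0 = shared tag
    for (t in bu_ts)
      params[[wb_key(n, t)]] <- he(k[n], f_in[n], f[n])
    if (spec$blocks[[n]]$convs_per_block == 2L)
      params[[paste0("b", n, ".Wb2")]] <- he(k[n], f[n], f[n])
    if (spec_lateral(spec)[n] || spec$family == "B-U") {
      lat_ts <- if (shared) 0L else seq.int(2L, t_steps)
      for (t in lat_ts)
        params[[wl_key(n, t)]] <- he(k[n], f[n], f[n])
    }
    for (t in seq_len(t_steps)) {
      for (sub in seq_len(spec$blocks[[n]]$convs_per_block)) {
        bk <- bn_key(n, t, sub)
        params[[paste0(bk, ".gamma")]] <- rep(1, f[n])
        params[[paste0(bk, ".beta")]] <- rep(0, f[n])
        state[[paste0(bk, ".mean")]] <- rep(0, f[n])
        state[[paste0(bk, ".var")]] <- rep(1, f[n])
      }
    }
  }
  ro_ts <- if (shared) 0L else seq_len(t_steps)
  for (t in ro_ts) {
    params[[ro_key("W", t)]] <- matrix(stats::rnorm(f[length(f)] * spec$n_classes,
                                                    sd = sqrt(1 / f[length(f)])),
                                       f[length(f)], spec$n_classes)
    params[[ro_key("b", t)]] <- rep(0, spec$n_classes)
  }
  structure(list(spec = spec, params = params, state = state),
            class = "rcnn_net")
}

wb_key <- function(n, t = 0L) if (t == 0L) paste0("b", n, ".Wb") else paste0("b", n, ".Wb.t", t)
wl_key <- function(n, t = 0L) if (t == 0L) paste0("b", n, ".Wl") else paste0("b", n, ".Wl.t", t)
bn_key <- function(n, t, sub = 1L)
  paste0("b", n, if (sub == 2L) ".bn2" else ".bn", ".t", t)
ro_key <- function(which, t = 0L)
  if (t == 0L) paste0("readout.", which) else paste0("readout.", which, ".t", t)

# resolve the parameter key for time step t given the sharing mode
p_wb <- function(spec, n, t) if (spec$weight_sharing_across_time) wb_key(n) else wb_key(n, t)
p_wl <- function(spec, n, t) if (spec$weight_sharing_across_time) wl_key(n) else wl_key(n, t)
p_ro <- function(spec, which, t) if (spec$weight_sharing_across_time) ro_key(which) else ro_key(which, t)

#' @export
print.rcnn_net <- function(x, ...) {
  pc <- count_parameters(x$spec)
  cat(sprintf("<rcnn_net> %s | %d blocks | T = %d | %s trainable parameters\n",
              x$spec$family, length(x$spec$blocks), x$spec$n_timesteps,
              format(pc$total, big.mark = ",")))
  invisible(x)
}

#' @export
coef.rcnn_net <- function(object, ...) object$params

net_geoms <- function(spec) {
  f <- spec_f(spec); k <- spec_k(spec)
  f_in <- c(spec$input_size[3], f[-length(f)])
  sz <- spatial_sizes(spec)
  lapply(seq_along(f), function(n) {
    list(bu = conv_geom(sz[n, 1], sz[n, 2], f_in[n], k[n]),
         bu2 = if (spec$blocks[[n]]$convs_per_block == 2L)
           conv_geom(sz[n, 1], sz[n, 2], f[n], k[n]) else NULL,
         lat = if (spec_lateral(spec)[n] || spec$family == "B-U")
           conv_geom(sz[n, 1], sz[n, 2], f[n], k[n]) else NULL)
  })
}

# One block evaluation: conv (+ lateral) -> batch norm -> relu, possibly a
# second conv/bn/relu stage (B-D). Returns output, caches, bn stats.
block_forward <- function(spec, params, state, n, t, x_in, h_prev, geoms,
                          mode, keep_cache) {
  g <- geoms[[n]]
  cv <- conv_forward(x_in, params[[p_wb(spec, n, t)]], g$bu)
  z <- cv$y
  lat_cache <- NULL
  use_lat <- !is.null(g$lat) && !is.null(h_prev)
  if (use_lat) {
    wl <- params[[p_wl(spec, n, t)]]
    if (!is.null(wl)) {
      cl <- conv_forward(h_prev, wl, g$lat)
      z <- z + cl$y
      lat_cache <- cl$a
    }
  }
  stage <- function(z, sub, a_bu, a_lat) {
    bk <- bn_key(n, t, sub)
    if (mode == "train") {
      bn <- bn_forward(z, params[[paste0(bk, ".gamma")]], params[[paste0(bk, ".beta")]],
                       mode = "batch")
    } else {
      bn <- bn_forward(z, params[[paste0(bk, ".gamma")]], params[[paste0(bk, ".beta")]],
                       mode = "running", rmean = state[[paste0(bk, ".mean")]],
                       rvar = state[[paste0(bk, ".var")]])
    }
    h <- bn$y; h[h < 0] <- 0
    cache <- if (keep_cache) list(a_bu = a_bu, a_lat = a_lat, bn = bn,
                                  relu_mask = bn$y > 0) else NULL
    list(h = h, bn = bn, cache = cache)
  }
  s1 <- stage(z, 1L, cv$a, lat_cache)
  out <- s1$h; c2 <- NULL; bn2 <- NULL
  if (!is.null(g$bu2)) {
    cv2 <- conv_forward(s1$h, params[[paste0("b", n, ".Wb2")]], g$bu2)
    s2 <- stage(cv2$y, 2L, cv2$a, NULL)
    out <- s2$h
    c2 <- s2$cache
    if (!is.null(c2)) c2$h_mid <- s1$h
    bn2 <- s2$bn
  }
  list(h = out, cache1 = s1$cache, cache2 = c2, bn1 = s1$bn, bn2 = bn2)
}

BN_MOMENTUM <- 0.9

update_running <- function(state, n, t, sub, bn) {
  bk <- bn_key(n, t, sub)
  state[[paste0(bk, ".mean")]] <- BN_MOMENTUM * state[[paste0(bk, ".mean")]] +
    (1 - BN_MOMENTUM) * bn$mu
  state[[paste0(bk, ".var")]] <- BN_MOMENTUM * state[[paste0(bk, ".var")]] +
    (1 - BN_MOMENTUM) * bn$va
  state
}

# Full forward pass in engineering time. x: (h, w, c, batch).
# Returns probs (batch, T, classes), per-(t, n) caches when requested, and
# updated running statistics when mode = "train".
rcnn_forward <- function(net, x, mode = c("eval", "train"), keep_cache = FALSE,
                         geoms = NULL) {
  mode <- match.arg(mode)
  spec <- net$spec; params <- net$params; state <- net$state
  if (is.null(geoms)) geoms <- net_geoms(spec)
  nb <- length(spec$blocks); tt <- spec$n_timesteps
  n_img <- dim(x)[4]
  stopifnot(all(dim(x)[1:3] == spec$input_size))
  probs <- array(NA_real_, c(n_img, tt, spec$n_classes))
  h_prev <- vector("list", nb)
  caches <- if (keep_cache) vector("list", tt) else NULL
  ro_caches <- if (keep_cache) vector("list", tt) else NULL
  h_state_all <- if (keep_cache) vector("list", tt) else NULL

  for (t in seq_len(tt)) {
    inp <- x
    h_new <- vector("list", nb)
    t_caches <- if (keep_cache) vector("list", nb) else NULL
    pool_caches <- if (keep_cache) vector("list", nb) else NULL
    for (n in seq_len(nb)) {
      bf <- block_forward(spec, params, state, n, t, inp, h_prev[[n]], geoms,
                          mode, keep_cache)
      if (mode == "train") {
        state <- update_running(state, n, t, 1L, bf$bn1)
        if (!is.null(bf$bn2)) state <- update_running(state, n, t, 2L, bf$bn2)
      }
      h_new[[n]] <- bf$h
      if (keep_cache) t_caches[[n]] <- bf[c("cache1", "cache2")]
      if (spec$blocks[[n]]$followed_by_pool) {
        mp <- maxpool_forward(bf$h)
        inp <- mp$y
        if (keep_cache) pool_caches[[n]] <- mp[c("masks", "in_dim")]
      } else {
        inp <- bf$h
      }
    }
    gap <- global_avg_pool(h_new[[nb]])            # (F_last, batch)
    logits <- crossprod(params[[p_ro(spec, "W", t)]], gap) +
      params[[p_ro(spec, "b", t)]]
    pr <- softmax_cols(logits)                     # (classes, batch)
    probs[, t, ] <- t(pr)
    if (keep_cache) {
      caches[[t]] <- list(blocks = t_caches, pools = pool_caches)
      ro_caches[[t]] <- list(gap = gap, probs = pr, h_dim = dim(h_new[[nb]]))
      h_state_all[[t]] <- h_new
    }
    h_prev <- h_new
  }
  list(probs = probs, state = state, caches = caches, ro_caches = ro_caches,
       h_all = h_state_all)
}

# Biological-time forward for lateral-only recurrent specs: every
# connection takes one tick. The node at tick tau, layer n corresponds to
# the engineering node (t = tau - n + 1, n); the readout of engineering
# time step t is taken at tick t + n_blocks - 1. Only evaluation mode.
rcnn_forward_bio <- function(net, x, geoms = NULL) {
  spec <- net$spec
  if (!any(spec_lateral(spec)) && spec$n_timesteps > 1L)
    stop("biological-time unrolling is only defined for lateral recurrence")
  params <- net$params; state <- net$state
  if (is.null(geoms)) geoms <- net_geoms(spec)
  nb <- length(spec$blocks); tt <- spec$n_timesteps
  n_img <- dim(x)[4]
  probs <- array(NA_real_, c(n_img, tt, spec$n_classes))
  h_cur <- vector("list", nb)   # H'_{tau - 1, n}
  for (tau in seq_len(tt + nb - 1L)) {
    h_next <- vector("list", nb)
    below <- x                   # input is clamped at every tick
    for (n in seq_len(nb)) {
      t_eng <- tau - n + 1L
      if (t_eng >= 1L && t_eng <= tt) {
        bf <- block_forward(spec, params, state, n, t_eng, below,
                            h_cur[[n]], geoms, "eval", FALSE)
        h_next[[n]] <- bf$h
      }
      nxt <- h_cur[[n]]          # layer n + 1 reads the previous tick
      if (!is.null(nxt) && spec$blocks[[n]]$followed_by_pool)
        nxt <- maxpool_forward(nxt)$y
      below <- nxt
      if (is.null(below)) break  # deeper layers have no input yet
    }
    t_read <- tau - nb + 1L
    if (t_read >= 1L && t_read <= tt) {
      gap <- global_avg_pool(h_next[[nb]])
      logits <- crossprod(params[[p_ro(spec, "W", t_read)]], gap) +
        params[[p_ro(spec, "b", t_read)]]
      probs[, t_read, ] <- t(softmax_cols(logits))
    }
    h_cur <- h_next
  }
  list(probs = probs)
}

#' Run a network on an image batch
#'
#' Produces one probability distribution over classes per time step per
#' image (the readout sequence), using stored batch-norm running statistics
#' (evaluation mode).
#'
#' @param object An `rcnn_net` (or fitted `rcnn_fit`).
#' @param images 4-d array (height, width, channels, batch) or a single
#'   image (height, width, channels), with values on the scale the network
#'   was trained on (\[-1, 1\] after [preprocess()]).
#' @param time_mode `"engineering"` (default) or `"biological"` unrolling;
#'   both produce identical readouts for lateral-only recurrence.
#' @param ... Unused.
#' @return A [readout_sequence()] object.
#' @export
predict.rcnn_net <- function(object, images, time_mode = c("engineering", "biological"),
                             ...) {
  time_mode <- match.arg(time_mode)
  if (length(dim(images)) == 3L) dim(images) <- c(dim(images), 1L)
  fw <- if (time_mode == "engineering") rcnn_forward(object, images, mode = "eval")
        else rcnn_forward_bio(object, images)
  readout_sequence(fw$probs, site_costs = count_flops(object$spec)$cumulative_flops)
}

#' Unroll an architecture into an explicit computational graph
#'
#' Returns the node-and-edge structure of the unrolled network. In
#' engineering mode, layer n at time t receives bottom-up input from layer
#' n - 1 at time t and lateral input from layer n at time t - 1 (the t = 0
#' lateral state is the all-zero stack, so lateral edges exist for t >= 2
#' only); one readout node follows the final layer at every time step. In
#' biological mode every connection takes one tick; node (tau, n) maps onto
#' engineering node (t = tau - n + 1, n), and nodes that cannot reach a
#' readout are omitted.
#'
#' @param spec An `rcnn_spec`.
#' @param mode `"engineering"` or `"biological"`.
#' @return A list of class `rcnn_graph` with data frames `nodes` (columns
#'   `id`, `kind`, `layer`, `time` — engineering time — and, in biological
#'   mode, `tick`) and `edges` (columns `from`, `to`, `type`).
#' @export
unroll <- function(spec, mode = c("engineering", "biological")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "rcnn_spec"))
  nb <- length(spec$blocks); tt <- spec$n_timesteps
  lateral <- spec_lateral(spec) | spec$family == "B-U"
  if (mode == "biological" && !any(lateral) && tt > 1L)
    stop("biological-time unrolling is only defined for lateral recurrence")
  lid <- function(t, n) paste0("L", n, ".t", t)
  rid <- function(t) paste0("readout.t", t)
  nodes <- list(); edges <- list()
  for (t in seq_len(tt)) {
    for (n in seq_len(nb)) {
      tick <- t + n - 1L
      nodes[[length(nodes) + 1L]] <- data.frame(
        id = lid(t, n), kind = "layer", layer = n, time = t, tick = tick)
      from <- if (n == 1L) paste0("input.t", t) else lid(t, n - 1L)
      if (n == 1L)
        nodes[[length(nodes) + 1L]] <- data.frame(
          id = from, kind = "input", layer = 0L, time = t, tick = tick - 1L)
      edges[[length(edges) + 1L]] <- data.frame(from = from, to = lid(t, n),
                                                type = "bottom_up")
      if (lateral[n] && t >= 2L)
        edges[[length(edges) + 1L]] <- data.frame(from = lid(t - 1L, n),
                                                  to = lid(t, n), type = "lateral")
    }
    nodes[[length(nodes) + 1L]] <- data.frame(
      id = rid(t), kind = "readout", layer = nb + 1L, time = t, tick = t + nb - 1L)
    edges[[length(edges) + 1L]] <- data.frame(from = lid(t, nb), to = rid(t),
                                              type = "readout")
  }
  nodes <- do.call(rbind, nodes)
  edges <- do.call(rbind, edges)
  if (mode == "engineering") nodes$tick <- NULL
  structure(list(nodes = nodes, edges = edges, mode = mode),
            class = "rcnn_graph")
}

#' @export
print.rcnn_graph <- function(x, ...) {
  cat(sprintf("<rcnn_graph> %s time: %d nodes (%d readouts), %d edges (%d lateral)\n",
              x$mode, nrow(x$nodes), sum(x$nodes$kind == "readout"),
              nrow(x$edges), sum(x$edges$type == "lateral")))
  invisible(x)
}

#' Save / load network checkpoints
#'
#' A checkpoint is an RDS file holding the spec, parameters, and batch-norm
#' running statistics, accompanied by a JSON manifest (`<path>.manifest.json`)
#' naming every parameter array by block, convolution, and time step with
#' its dimensions, plus the input channel order and the \[-1, 1\] input
#' scaling convention.
#'
#' @param net An `rcnn_net`.
#' @param path Checkpoint file path.
#' @return `load_checkpoint` returns the restored `rcnn_net`.
#' @export
save_checkpoint <- function(net, path) {
  stopifnot(inherits(net, "rcnn_net"))
  saveRDS(net[c("spec", "params", "state")], path)
  manifest <- list(
    format = "rvt-checkpoint-1",
    family = net$spec$family,
    channel_order = "height,width,channel,batch",
    input_scaling = "[-1,1]",
    parameters = lapply(net$params, function(p) dim(p) %||% length(p)))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  structure(list(spec = x$spec, params = x$params, state = x$state),
            class = "rcnn_net")
}
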