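#' Readout sequences
#'
#' A readout sequence holds one probability distribution over classes per
#' time step per image, together with the cumulative computational cost at
#' each readout (floating-point operations, from [count_flops()]).
#'
#' @param probs Array (n_images, n_timesteps, n_classes); every
#'   `probs[i, t, ]` row must sum to 1 (tolerance 1e-6).
#' @param site_costs Strictly increasing numeric vector of cumulative cost
#'   at each readout; defaults to readout index 1..T.
#' @return An object of class `readout_sequence`.
#' @export
readout_sequence <- function(probs, site_costs = NULL) {
  stopifnot(length(dim(probs)) == 3L)
  tt <- dim(probs)[2]
  if (is.null(site_costs)) site_costs <- seq_len(tt)
  stopifnot(length(site_costs) == tt)
  if (tt > 1L && any(diff(site_costs) <= 0))
    stop("site_costs must be strictly increasing")
  sums <- apply(probs, c(1, 2), sum)
  if (any(abs(sums - 1) > 1e-6)) stop("probability rows must sum to 1")
  if (any(probs < 0)) stop("negative probabilities")
  structure(list(probs = probs, site_costs = as.numeric(site_costs)),
            class = "readout_sequence")
}

#' @export
print.readout_sequence <- function(x, ...) {
  d <- dim(x$probs)
  cat(sprintf("<readout_sequence> %d images x %d time steps x %d classes\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Shannon entropy of a probability distribution, in nats
#'
#' `0 * log 0` is taken as 0. A one-hot distribution has entropy 0
#' (complete certainty); the uniform distribution over C classes has
#' entropy `log(C)`.
#'
#' @param dist Numeric probability vector (entries >= 0, summing to 1), or
#'   a matrix with one distribution per row.
#' @return Entropy in nats (vector of length `nrow` for matrix input).
#' @export
entropy <- function(dist) {
  if (is.matrix(dist)) {
    if (any(dist < 0)) stop("negative probabilities")
    x <- dist * log(dist)
    x[dist == 0] <- 0
    return(-rowSums(x))
  }
  if (any(dist < 0)) stop("negative probabilities")
  x <- dist * log(dist)
  x[dist == 0] <- 0
  -sum(x)
}

#' Cumulative readout at a time step
#'
#' The arithmetic mean of the per-time-step distributions for steps 1..t —
#' itself a valid distribution (no renormalisation needed). At t = 1 it
#' equals the instantaneous readout.
#'
#' @param seq A [readout_sequence()].
#' @param t Time step in 1..T.
#' @return Matrix (n_images, n_classes).
#' @export
cumulative_readout <- function(seq, t) {
  stopifnot(inherits(seq, "readout_sequence"))
  tt <- dim(seq$probs)[2]
  if (t < 1L || t > tt) stop("t out of range 1..", tt)
  m <- seq$probs[, seq_len(t), , drop = FALSE]
  apply(m, c(1, 3), mean)
}

readout_at <- function(seq, t, readout_mode) {
  if (readout_mode == "cumulative") cumulative_readout(seq, t)
  else {
    m <- seq$probs[, t, , drop = FALSE]
    dim(m) <- dim(seq$probs)[c(1, 3)]
    m
  }
}

#' Decision policies
#'
#' A decision policy maps a readout sequence to one prediction per image:
#' either at a fixed time step (`time_based`) or at the first step whose
#' readout entropy falls to or below an entropy threshold theta
#' (`threshold_based`; the comparison is inclusive, so theta = log(C)
#' always stops at t = 1). If the threshold is never reached the final
#' time step is used. The readout a decision is based on is either the
#' `instantaneous` per-step distribution or the `cumulative` mean up to the
#' step (the default, which is also how accuracies are reported for the
#' recurrent models).
#'
#' @param mode `"threshold_based"` or `"time_based"`.
#' @param entropy_threshold Threshold in nats (>= 0); threshold mode only.
#' @param fixed_time Readout time step; time-based mode only.
#' @param readout_mode `"cumulative"` (default) or `"instantaneous"`.
#' @return A list of class `decision_policy`.
#' @export
decision_policy <- function(mode = c("threshold_based", "time_based"),
                            entropy_threshold = NULL, fixed_time = NULL,
                            readout_mode = c("cumulative", "instantaneous")) {
  mode <- match.arg(mode)
  readout_mode <- match.arg(readout_mode)
  if (mode == "threshold_based") {
    if (is.null(entropy_threshold) || entropy_threshold < 0)
      stop("threshold mode needs entropy_threshold >= 0 (nats)")
    fixed_time <- NULL
  } else {
    if (is.null(fixed_time) || fixed_time < 1)
      stop("time-based mode needs fixed_time >= 1")
    entropy_threshold <- NULL
  }
  structure(list(mode = mode, entropy_threshold = entropy_threshold,
                 fixed_time = as.integer(fixed_time %||% NA_integer_),
                 readout_mode = readout_mode, entropy_base = "nats"),
            class = "decision_policy")
}

#' Apply a decision policy to a readout sequence
#'
#' Threshold mode: the reaction time is the first time step at which the
#' readout entropy is <= theta, or T if the threshold is never reached.
#' The predicted class is the argmax of the readout (per `readout_mode`)
#' at the reaction time, ties broken toward the lowest class index. A pure
#' function: identical inputs give identical outputs.
#'
#' @param seq A [readout_sequence()].
#' @param policy A [decision_policy()].
#' @return Data frame of class `rcnn_decisions` with one row per image:
#'   `predicted_class`, `reaction_time`, `entropy` (at the decision, nats),
#'   `cost` (cumulative floating-point operations at the decision).
#' @export
decide <- function(seq, policy) {
  stopifnot(inherits(seq, "readout_sequence"), inherits(policy, "decision_policy"))
  tt <- dim(seq$probs)[2]
  n <- dim(seq$probs)[1]
  ent <- vapply(seq_len(tt),
                function(t) entropy(readout_at(seq, t, policy$readout_mode)),
                numeric(n))
  if (n == 1L) ent <- matrix(ent, nrow = 1L)        # (images, T)
  if (policy$mode == "time_based") {
    rt <- rep(min(policy$fixed_time, tt), n)
  } else {
    hit <- ent <= policy$entropy_threshold
    rt <- apply(hit, 1, function(z) if (any(z)) which(z)[1] else tt)
  }
  pred <- integer(n); edec <- numeric(n)
  for (t in sort(unique(rt))) {
    sel <- rt == t
    ro <- readout_at(seq, t, policy$readout_mode)
    pred[sel] <- apply(ro[sel, , drop = FALSE], 1, which.max)
    edec[sel] <- ent[sel, t]
  }
  structure(data.frame(predicted_class = pred, reaction_time = rt,
                       entropy = edec, cost = seq$site_costs[rt]),
            class = c("rcnn_decisions", "data.frame"))
}

#' Accuracy of a list of readout sequences under a policy
#'
#' @param seqs A single [readout_sequence()] covering all images.
#' @param labels Integer class labels, one per image.
#' @param policy A [decision_policy()].
#' @return Proportion of images whose decided class equals the label.
#' @export
evaluate_policy <- function(seqs, labels, policy) {
  stopifnot(inherits(seqs, "readout_sequence"))
  if (dim(seqs$probs)[1] != length(labels)) stop("labels and sequences disagree in length")
  d <- decide(seqs, policy)
  mean(d$predicted_class == labels)
}

#' Export decisions as CSV with a policy sidecar
#'
#' Writes one row per image (`image_id`, `predicted_class`,
#' `reaction_time`, `entropy`, `cost`) and the policy as
#' `<path>.policy.json`.
#'
#' @param decisions Output of [decide()].
#' @param policy The [decision_policy()] used.
#' @param path CSV output path.
#' @export
write_decisions <- function(decisions, policy, path) {
  df <- cbind(image_id = seq_len(nrow(decisions)), as.data.frame(decisions))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(policy[c("mode", "entropy_threshold", "fixed_time",
                                "readout_mode", "entropy_base")],
                       paste0(path, ".policy.json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(path)
}
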