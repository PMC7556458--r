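#' Speed-accuracy trade-off curve
#'
#' For each entropy threshold, applies the threshold-based decision policy,
#' records the top-1 accuracy and the mean computational cost at the
#' decision, and tabulates the per-image cost distribution (fraction of
#' images deciding at each cost, with the accuracy at that cost). The
#' default threshold grid is the sorted unique decision-relevant entropies
#' observed in the evaluation set plus log(C) and 0, so every achievable
#' operating point appears.
#'
#' @param seqs A [readout_sequence()] for the evaluation images.
#' @param labels Integer class labels.
#' @param thresholds Numeric vector of entropy thresholds (nats); `NULL`
#'   for the default grid.
#' @param readout_mode `"cumulative"` (default) or `"instantaneous"`.
#' @return An object of class `sat_curve`: `points` (data frame with
#'   `threshold`, `mean_cost`, `accuracy`) and `histograms` (long-format
#'   data frame with `threshold`, `cost`, `fraction`, `accuracy`).
#' @export
sat_curve <- function(seqs, labels, thresholds = NULL,
                      readout_mode = c("cumulative", "instantaneous")) {
  stopifnot(inherits(seqs, "readout_sequence"))
  readout_mode <- match.arg(readout_mode)
  tt <- dim(seqs$probs)[2]
  n_classes <- dim(seqs$probs)[3]
  if (is.null(thresholds)) {
    ent <- unlist(lapply(seq_len(tt), function(t)
      entropy(readout_at(seqs, t, readout_mode))))
    thresholds <- sort(unique(c(0, ent, log(n_classes))), decreasing = TRUE)
  }
  if (!length(thresholds)) stop("thresholds must be non-empty")
  pts <- vector("list", length(thresholds))
  hist_rows <- vector("list", length(thresholds))
  for (i in seq_along(thresholds)) {
    pol <- decision_policy("threshold_based", entropy_threshold = thresholds[i],
                           readout_mode = readout_mode)
    d <- decide(seqs, pol)
    correct <- d$predicted_class == labels
    pts[[i]] <- data.frame(threshold = thresholds[i], mean_cost = mean(d$cost),
                           accuracy = mean(correct))
    agg_n <- tapply(correct, d$cost, length)
    agg_acc <- tapply(correct, d$cost, mean)
    hist_rows[[i]] <- data.frame(threshold = thresholds[i],
                                 cost = as.numeric(names(agg_n)),
                                 fraction = as.numeric(agg_n) / length(correct),
                                 accuracy = as.numeric(agg_acc))
  }
  structure(list(points = do.call(rbind, pts),
                 histograms = do.call(rbind, hist_rows),
                 readout_mode = readout_mode, entropy_base = "nats"),
            class = "sat_curve")
}

#' @export
print.sat_curve <- function(x, ...) {
  cat(sprintf("<sat_curve> %d thresholds (nats), accuracy %.3f-%.3f, mean cost %.3g-%.3g\n",
              nrow(x$points), min(x$points$accuracy), max(x$points$accuracy),
              min(x$points$mean_cost), max(x$points$mean_cost)))
  invisible(x)
}

#' @export
plot.sat_curve <- function(x, ...) {
  p <- x$points[order(x$points$mean_cost), ]
  graphics::plot(p$mean_cost, p$accuracy, type = "b", pch = 16,
                 xlab = "mean floating-point operations",
                 ylab = "accuracy", main = "speed-accuracy trade-off", ...)
  invisible(x)
}

#' Threshold matching a target computational cost
#'
#' Returns the entropy threshold whose mean cost is closest (in absolute
#' difference) to `target_cost`; ties are broken toward the larger
#' (cheaper) threshold. Used to compare a recurrent model against a
#' feedforward model at matched computational budget.
#'
#' @param curve A [sat_curve()].
#' @param target_cost Target mean cost in floating-point operations.
#' @return The selected entropy threshold (nats).
#' @export
matched_cost_threshold <- function(curve, target_cost) {
  stopifnot(inherits(curve, "sat_curve"), nrow(curve$points) > 0)
  p <- curve$points
  dev <- abs(p$mean_cost - target_cost)
  cand <- which(dev == min(dev))
  max(p$threshold[cand])
}

#' McNemar test for paired classifier comparison
#'
#' Builds the discordant-pair counts b (A correct, B wrong) and c (A wrong,
#' B correct). When b + c < 25 the exact two-sided binomial test
#' (p = 1/2) is used; otherwise the continuity-corrected chi-square
#' statistic (|b - c| - 1)^2 / (b + c) on 1 degree of freedom. If
#' b + c = 0 the classifiers are indistinguishable and p = 1 by
#' convention.
#'
#' @param preds_a,preds_b Predicted classes from the two models.
#' @param labels True classes.
#' @param variant `"auto"` (the b + c < 25 switch), `"exact"`, or
#'   `"chisq"`.
#' @return List with `b`, `c`, `statistic` (chi-square branch, else `NA`),
#'   `p_value`, and `method`.
#' @export
mcnemar_test <- function(preds_a, preds_b, labels,
                         variant = c("auto", "exact", "chisq")) {
  variant <- match.arg(variant)
  if (length(preds_a) != length(labels) || length(preds_b) != length(labels))
    stop("prediction and label vectors must be aligned")
  ca <- preds_a == labels; cb <- preds_b == labels
  b <- sum(ca & !cb); cc <- sum(!ca & cb)
  n <- b + cc
  if (n == 0)
    return(list(b = b, c = cc, statistic = NA_real_, p_value = 1,
                method = "degenerate (no discordant pairs)"))
  use_exact <- switch(variant, auto = n < 25, exact = TRUE, chisq = FALSE)
  if (use_exact) {
    k <- min(b, cc)
    p <- min(1, 2 * stats::pbinom(k, n, 0.5))
    list(b = b, c = cc, statistic = NA_real_, p_value = p,
         method = "exact binomial, two-sided")
  } else {
    stat <- (abs(b - cc) - 1)^2 / n
    list(b = b, c = cc, statistic = stat,
         p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
         method = "continuity-corrected chi-square")
  }
}

#' Bonferroni adjustment
#'
#' `min(1, p * family_size)` elementwise — the family-wise error-rate
#' correction used for the pairwise model comparisons.
#'
#' @param p_values Numeric vector in \[0, 1\].
#' @param family_size Number of comparisons in the family (defaults to
#'   `length(p_values)`).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p_values, family_size = length(p_values)) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  pmin(1, p_values * family_size)
}
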