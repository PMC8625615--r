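# Training objective: three cross-entropies (anchor / positive / negative)
# plus an anchor-positive pull and a hinged anchor-negative push on the
# final clip features, with subject-aware triplet sampling. Within one
# subject, different stress states look nearly alike; within one class,
# different subjects look very different. The sampler therefore pairs the
# anchor with a same-class clip from a DIFFERENT subject (pull) and a
# different-class clip from the SAME subject (push up to the margin).

#' Cross-entropy of class scores against a ground-truth class
#'
#' `-log(score of the true class)`, with an epsilon floor (1e-12) on the
#' score for numerical safety.
#'
#' @param scores numeric vector of class scores on the simplex.
#' @param truth 1-based index of the true class.
#' @return nonnegative scalar loss.
#' @export
cross_entropy <- function(scores, truth) {
  stopifnot(truth >= 1, truth <= length(scores))
  -log(max(scores[truth], 1e-12))
}

#' Mean squared distance between two feature vectors
#'
#' `(1/N) * sum_i (f1_i - f2_i)^2`.
#'
#' @param f1,f2 numeric vectors of equal length.
#' @return nonnegative scalar.
#' @export
mse_distance <- function(f1, f2) {
  if (length(f1) != length(f2)) stop("length mismatch between feature vectors")
  mean((f1 - f2)^2)
}

#' Combined triplet objective
#'
#' Total loss for one (anchor, positive, negative) triplet:
#' the three cross-entropies, the anchor-positive mean squared distance
#' (pulled toward zero) and the hinged anchor-negative term
#' `max(0, m - MSE(f_anchor, f_negative))` (pushed out to the margin).
#' Distances are computed on the final clip features (the vectors the
#' classifier consumes).
#'
#' @param anchor,positive,negative lists with elements `scores` (class
#'   scores) and `feature` (final feature vector).
#' @param truths integer vector of the three 1-based true classes
#'   (anchor, positive, negative).
#' @param margin hinge margin m (> 0; the reference setting is 2).
#' @return a `loss_breakdown` list with components `ce_anchor`, `ce_pos`,
#'   `ce_neg`, `pull`, `push` and their sum `total`.
#' @export
final_loss <- function(anchor, positive, negative, truths, margin = 2) {
  stopifnot(margin > 0, length(truths) == 3)
  if (truths[2] != truths[1] || truths[3] == truths[1]) {
    stop("triplet constraint violation: positive must share the anchor class, ",
         "negative must differ")
  }
  out <- list(
    ce_anchor = cross_entropy(anchor$scores, truths[1]),
    ce_pos = cross_entropy(positive$scores, truths[2]),
    ce_neg = cross_entropy(negative$scores, truths[3]),
    pull = mse_distance(anchor$feature, positive$feature),
    push = max(0, margin - mse_distance(anchor$feature, negative$feature))
  )
  out$total <- out$ce_anchor + out$ce_pos + out$ce_neg + out$pull + out$push
  class(out) <- "loss_breakdown"
  out
}

#' Index a clip collection by subject and class for triplet sampling
#'
#' @param manifest data frame with columns `subject_id` and `label` (one
#'   row per clip, row order defining clip indices).
#' @return a `triplet_index` object.
#' @export
triplet_index <- function(manifest) {
  stopifnot(all(c("subject_id", "label") %in% names(manifest)))
  idx <- list(
    subject = as.character(manifest$subject_id),
    label = as.character(manifest$label),
    n = nrow(manifest)
  )
  class(idx) <- "triplet_index"
  idx
}

#' Sample a subject-aware triplet for an anchor clip
#'
#' The positive is drawn uniformly from clips of the anchor's class
#' belonging to a different subject; the negative uniformly from clips of
#' the anchor's subject belonging to a different class.
#'
#' @param index a [triplet_index()].
#' @param anchor integer clip index of the anchor.
#' @param seed optional integer; fixes the draw.
#' @return list with integer elements `anchor`, `positive`, `negative`.
#' @export
sample_triplet <- function(index, anchor, seed = NULL) {
  stopifnot(inherits(index, "triplet_index"), anchor >= 1, anchor <= index$n)
  pos_pool <- which(index$label == index$label[anchor] &
                    index$subject != index$subject[anchor])
  if (length(pos_pool) == 0) {
    stop("no eligible positive: no other subject has clips of class '",
         index$label[anchor], "'")
  }
  neg_pool <- which(index$subject == index$subject[anchor] &
                    index$label != index$label[anchor])
  if (length(neg_pool) == 0) {
    stop("no eligible negative: subject '", index$subject[anchor],
         "' has clips of a single class only")
  }
  draw <- function() list(
    anchor = as.integer(anchor),
    positive = pos_pool[sample.int(length(pos_pool), 1)],
    negative = neg_pool[sample.int(length(neg_pool), 1)]
  )
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# gradient of the metric terms w.r.t. the three final features.
# pull = MSE(fa, fp); push = max(0, m - MSE(fa, fn)).
metric_grads <- function(fa, fp, fn, margin) {
  N <- length(fa)
  d_pull <- 2 / N * (fa - fp)
  hinge_active <- mse_distance(fa, fn) < margin
  d_push <- if (hinge_active) -2 / N * (fa - fn) else numeric(N)
  list(
    anchor = d_pull + d_push,
    positive = -d_pull,
    negative = if (hinge_active) 2 / N * (fa - fn) else numeric(N)
  )
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(
    "<loss_breakdown> total %.4f = ce(a) %.4f + ce(p) %.4f + ce(n) %.4f + pull %.4f + push %.4f\n",
    x$total, x$ce_anchor, x$ce_pos, x$ce_neg, x$pull, x$push))
  invisible(x)
}
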