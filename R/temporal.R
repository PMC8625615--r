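# Temporal attention over per-frame features and the final classifier.
#
# Per clip: the T per-frame concatenated features (facial 512 + landmark
# 256 = 768 by default) are averaged into a clip descriptor; each frame
# feature is extended by that average (768 -> 1536), passed through three
# fully connected layers (1536 -> 1536 -> 1536 -> 1) to yield one scalar
# attention weight per frame -- weights are computed per frame, never
# jointly over a stacked (T+1)-slice input. The weighted frame features are
# averaged into the final feature, and a single fully connected layer +
# softmax produces the class scores.

#' Build the temporal attention + classifier module
#'
#' @param d_concat per-frame concatenated feature length (768 with the
#'   landmark branch, 512 without).
#' @param n_classes number of output classes (default 3).
#' @param hidden_act activation between the three weight layers
#'   (`"relu"`, default, or `"linear"`).
#' @param weight_head activation on the scalar weight head (`"sigmoid"`,
#'   default, bounding weights to (0, 1), or `"linear"`).
#' @param seed optional integer fixing initialization.
#' @return a `temporal_module`.
#' @export
build_temporal_module <- function(d_concat = 768L, n_classes = 3L,
                                  hidden_act = c("relu", "linear"),
                                  weight_head = c("sigmoid", "linear"),
                                  seed = NULL) {
  hidden_act <- match.arg(hidden_act)
  weight_head <- match.arg(weight_head)
  builder <- function() {
    d2 <- 2L * d_concat
    tm <- list(
      d = as.integer(d_concat), d2 = d2, n_classes = as.integer(n_classes),
      hidden_act = hidden_act, weight_head = weight_head,
      fc1 = new_fc(d2, d2),
      fc2 = new_fc(d2, d2),
      fc3 = new_fc(d2, 1L, init = "small"),
      cls = new_fc(d_concat, n_classes, init = "xavier")
    )
    class(tm) <- "temporal_module"
    tm
  }
  if (is.null(seed)) builder() else with_seed(seed, builder())
}

temporal_params <- function(tm) {
  c(fc_params(tm$fc1, "ta.fc1"), fc_params(tm$fc2, "ta.fc2"),
    fc_params(tm$fc3, "ta.fc3"), fc_params(tm$cls, "cls"))
}

#' Concatenate facial and landmark features frame by frame
#'
#' @param facial `T x 512` matrix of facial image features.
#' @param landmark `T x 256` matrix of facial landmark features, or NULL
#'   when the landmark branch is disabled.
#' @return `T x 768` (or `T x 512`) matrix, facial block first.
#' @export
concat_features <- function(facial, landmark = NULL) {
  facial <- as.matrix(facial)
  if (is.null(landmark)) return(facial)
  landmark <- as.matrix(landmark)
  if (nrow(facial) != nrow(landmark)) {
    stop("length mismatch: facial and landmark sequences differ in frames")
  }
  cbind(facial, landmark)
}

ta_act <- function(tm, x) if (tm$hidden_act == "relu") relu(x) else x

#' Temporal attention weights for one clip
#'
#' Appends the clip-average feature to every frame feature and maps each
#' extended feature through the three weight layers, yielding one scalar
#' weight per frame.
#'
#' @param tm a `temporal_module`.
#' @param concat `T x d` matrix of per-frame concatenated features.
#' @return numeric vector of `T` attention weights (in (0, 1) with the
#'   default sigmoid head).
#' @export
temporal_weights <- function(tm, concat) {
  temporal_weights_fwd(tm, as.matrix(concat))$w
}

temporal_weights_fwd <- function(tm, f) {
  stopifnot(ncol(f) == tm$d)
  Tn <- nrow(f)
  A <- .colMeans(f, Tn, tm$d)
  G <- cbind(f, matrix(A, Tn, tm$d, byrow = TRUE))
  H1 <- ta_act(tm, fc_forward(tm$fc1, G))
  H2 <- ta_act(tm, fc_forward(tm$fc2, H1))
  z <- fc_forward(tm$fc3, H2)
  w <- if (tm$weight_head == "sigmoid") sigmoid(as.numeric(z)) else as.numeric(z)
  list(w = w, G = G, H1 = H1, H2 = H2, Tn = Tn)
}

#' Fuse per-frame features with temporal attention weights
#'
#' Computes the final clip feature `(1/T) * sum_i w_i * f_i`: the
#' weight-modulated frame features averaged over the time axis.
#'
#' @param concat `T x d` matrix of per-frame features.
#' @param w numeric vector of `T` weights.
#' @return numeric vector of length `d`.
#' @export
fuse_frames <- function(concat, w) {
  concat <- as.matrix(concat)
  if (nrow(concat) != length(w)) stop("length mismatch: frames vs weights")
  .colMeans(concat * w, nrow(concat), ncol(concat))
}

#' Class scores from a final clip feature
#'
#' One fully connected layer followed by the softmax, producing scores on
#' the probability simplex.
#'
#' @param tm a `temporal_module`.
#' @param f final feature vector (length `d`).
#' @return numeric vector of `n_classes` scores summing to 1.
#' @export
classify_feature <- function(tm, f) {
  stopifnot(length(f) == tm$d)
  as.numeric(softmax_rows(fc_forward(tm$cls, matrix(f, 1))))
}

# Batched module forward over several clips at once: `feats` stacks the
# per-frame features of all clips ((sum Ts) x d, clip blocks in order).
# One gemm per layer instead of one per clip.
temporal_forward_batch <- function(tm, feats, Ts, train = FALSE) {
  n <- length(Ts)
  idx <- rep(seq_len(n), Ts)         # clip index per row
  Trep <- rep(Ts, Ts)
  A <- rowsum(feats, idx, reorder = FALSE) / Ts   # n x d clip averages
  G <- cbind(feats, A[idx, , drop = FALSE])
  H1 <- ta_act(tm, fc_forward(tm$fc1, G))
  H2 <- ta_act(tm, fc_forward(tm$fc2, H1))
  z <- fc_forward(tm$fc3, H2)
  w <- if (tm$weight_head == "sigmoid") sigmoid(as.numeric(z)) else as.numeric(z)
  ffinal <- rowsum(feats * w, idx, reorder = FALSE) / Ts  # n x d
  logits <- fc_forward(tm$cls, ffinal)
  scores <- softmax_rows(logits)
  out <- list(w = w, wlogit = as.numeric(z), ffinal = ffinal,
              scores = scores, Ts = Ts)
  if (train) {
    out$cache <- list(feats = feats, idx = idx, Trep = Trep, Ts = Ts,
                      G = G, H1 = H1, H2 = H2, w = w, ffinal = ffinal, n = n)
  }
  out
}

# batched backward: dlogits (n x classes), dffinal_extra (n x d or NULL).
# Returns dfeats ((sum Ts) x d).
temporal_backward_batch <- function(tm, cache, dlogits, dffinal_extra = NULL) {
  dffinal <- fc_backward(tm$cls, cache$ffinal, dlogits)
  if (!is.null(dffinal_extra)) dffinal <- dffinal + dffinal_extra
  feats <- cache$feats
  idx <- cache$idx
  Trep <- cache$Trep
  w <- cache$w
  dff_rows <- dffinal[idx, , drop = FALSE]
  dfeats <- dff_rows * (w / Trep)
  dw <- rowSums(feats * dff_rows) / Trep
  dz <- if (tm$weight_head == "sigmoid") dw * w * (1 - w) else dw
  dH2 <- fc_backward(tm$fc3, cache$H2, matrix(dz, ncol = 1))
  if (tm$hidden_act == "relu") dH2 <- dH2 * (cache$H2 > 0)
  dH1 <- fc_backward(tm$fc2, cache$H1, dH2)
  if (tm$hidden_act == "relu") dH1 <- dH1 * (cache$H1 > 0)
  dG <- fc_backward(tm$fc1, cache$G, dH1)
  d <- tm$d
  dfeats <- dfeats + dG[, seq_len(d), drop = FALSE]
  dA <- rowsum(dG[, d + seq_len(d), drop = FALSE], idx, reorder = FALSE)
  dfeats + (dA / cache$Ts)[idx, , drop = FALSE]
}

# full module forward for one clip; caches for backward
temporal_forward <- function(tm, f, train = FALSE) {
  wf <- temporal_weights_fwd(tm, f)
  ffinal <- fuse_frames(f, wf$w)
  logits <- fc_forward(tm$cls, matrix(ffinal, 1))
  scores <- softmax_rows(logits)
  list(w = wf$w, ffinal = ffinal, logits = as.numeric(logits),
       scores = as.numeric(scores),
       cache = if (train) c(wf, list(f = f, ffinal = ffinal)) else NULL)
}

# backward for one clip: dlogits (length n_classes) from the cross-entropy,
# dffinal_extra (length d) from the metric loss terms. Returns df (T x d).
temporal_backward <- function(tm, cache, dlogits, dffinal_extra = NULL) {
  Tn <- cache$Tn
  dffinal <- as.numeric(
    fc_backward(tm$cls, matrix(cache$ffinal, 1), matrix(dlogits, 1)))
  if (!is.null(dffinal_extra)) dffinal <- dffinal + dffinal_extra
  f <- cache$f
  w <- cache$w
  df <- (w / Tn) %o% dffinal
  dw <- as.numeric(f %*% dffinal) / Tn
  dz <- if (tm$weight_head == "sigmoid") dw * w * (1 - w) else dw
  dH2 <- fc_backward(tm$fc3, cache$H2, matrix(dz, ncol = 1))
  if (tm$hidden_act == "relu") dH2 <- dH2 * (cache$H2 > 0)
  dH1 <- fc_backward(tm$fc2, cache$H1, dH2)
  if (tm$hidden_act == "relu") dH1 <- dH1 * (cache$H1 > 0)
  dG <- fc_backward(tm$fc1, cache$G, dH1)
  df <- df + dG[, seq_len(tm$d), drop = FALSE]
  dA <- .colSums(dG[, tm$d + seq_len(tm$d), drop = FALSE], Tn, tm$d)
  df + matrix(dA / Tn, Tn, tm$d, byrow = TRUE)
}

#' @export
print.temporal_module <- function(x, ...) {
  cat(sprintf(
    "<temporal_module> %d -> %d/%d/1 weight layers (%s hidden, %s head), %d classes\n",
    x$d, x$d2, x$d2, x$hidden_act, x$weight_head, x$n_classes))
  invisible(x)
}
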