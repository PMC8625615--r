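# End-to-end training (SGD + momentum with a step learning-rate schedule),
# subject-disjoint k-fold splitting, and clip-/video-level metrics.

#' Subject-disjoint cross-validation folds
#'
#' Shuffles the subjects once (seeded) and rotates k equal groups:
#' fold i uses group i as the test set, the next group for validation and
#' the remaining groups for training -- a 3:1:1 subject ratio at k = 5. A
#' subject never appears in two sets of one fold, and each subject is in
#' exactly one test set across the k folds.
#'
#' @param subject_ids character vector of subject identifiers.
#' @param k number of folds (>= 2, default 5).
#' @param seed shuffle seed.
#' @return list of k folds, each with `train_subjects`, `val_subjects`,
#'   `test_subjects`.
#' @export
make_subject_folds <- function(subject_ids, k = 5L, seed = 1L) {
  if (k < 2) stop("k must be at least 2")
  subjects <- unique(as.character(subject_ids))
  if (length(subjects) < k) stop("fewer subjects than folds")
  shuffled <- with_seed(seed, sample(subjects))
  groups <- split(shuffled, rep(seq_len(k), length.out = length(shuffled)))
  lapply(seq_len(k), function(i) {
    vi <- i %% k + 1L
    list(test_subjects = groups[[i]],
         val_subjects = groups[[vi]],
         train_subjects = unlist(groups[-c(i, vi)], use.names = FALSE))
  })
}

#' Step learning-rate schedule
#'
#' The reference schedule: initial rate 1e-3 multiplied by 0.1 every 15
#' epochs over 45 epochs, i.e. 1e-3 / 1e-4 / 1e-5 for 15 epochs each.
#'
#' @param epochs number of epochs.
#' @param initial initial learning rate.
#' @param drop multiplicative factor applied every `every` epochs.
#' @param every epochs between drops.
#' @return numeric vector of per-epoch learning rates.
#' @export
lr_schedule <- function(epochs = 45L, initial = 1e-3, drop = 0.1,
                        every = 15L) {
  initial * drop^((seq_len(epochs) - 1L) %/% every)
}

# softmax + cross-entropy gradient w.r.t. logits
ce_logit_grad <- function(scores, truth) {
  g <- scores
  g[truth] <- g[truth] - 1
  g
}

# relaxed sampler for the standard contrastive/triplet loss variants
# (class-constrained only, no subject constraint)
sample_triplet_relaxed <- function(index, anchor) {
  pos_pool <- setdiff(which(index$label == index$label[anchor]), anchor)
  neg_pool <- which(index$label != index$label[anchor])
  if (length(pos_pool) == 0) stop("no eligible positive")
  if (length(neg_pool) == 0) stop("no eligible negative")
  list(anchor = as.integer(anchor),
       positive = pos_pool[sample.int(length(pos_pool), 1)],
       negative = neg_pool[sample.int(length(neg_pool), 1)])
}

#' Train a stress model
#'
#' SGD with momentum 0.9 and weight decay 1e-4 over triplet batches drawn
#' from the training subjects only (a batch of `batch_clips` clips holds
#' `batch_clips / 3` triplets). Per-epoch loss components and validation
#' accuracy are recorded; with `select_best = TRUE` the parameters of the
#' best validation epoch are restored at the end. The whole run is
#' deterministic for a fixed seed.
#'
#' @param model a `stress_model` (modified in place).
#' @param clips list of clips.
#' @param manifest data frame with one row per clip (`subject_id`,
#'   `video_id`, `label`), rows matching `clips`.
#' @param fold list with `train_subjects` and optionally `val_subjects`
#'   (see [make_subject_folds()]).
#' @param epochs training epochs.
#' @param schedule per-epoch learning rates (defaults to
#'   [lr_schedule()] of length `epochs`).
#' @param batch_clips clips per batch (multiple of 3; the reference memory
#'   budget allows 6).
#' @param momentum,weight_decay SGD settings.
#' @param margin hinge margin of the objective.
#' @param loss_variant `"ce+proposed"` (default: subject-aware pull/push),
#'   `"ce"` (cross-entropies only), `"ce+contrastive"` or `"ce+triplet"`
#'   (standard definitions on the same features, class-constrained
#'   sampling).
#' @param seed seed for triplet sampling and shuffling.
#' @param select_best restore the best-validation-epoch parameters.
#' @param batch_scheme `"triplet"` (default): batches of
#'   `batch_clips / 3` subject-aware triplets with the combined objective.
#'   `"stratified"`: class-balanced batches of `batch_clips` clips trained
#'   with plain cross-entropy (no metric terms) -- a deterministic,
#'   class-stratified curriculum useful for small focused experiments
#'   where the randomized triplet composition makes batches too noisy.
#' @param head_warmup_epochs epochs during which the temporal weight head
#'   is held fixed (weights stay at their near-neutral 0.5 initialization,
#'   i.e. uniform frame pooling) while the rest of the network trains.
#'   Guards short training runs against early attention collapse, where
#'   shrinking all frame weights toward zero is the cheapest way to reduce
#'   the cross-entropy before the features carry class signal -- and kills
#'   every upstream gradient. Default 0 (the reference schedule).
#' @param verbose print per-epoch progress.
#' @return list with `model`, `history` (data frame: epoch, lr, loss
#'   components, validation accuracy) and `best_epoch`.
#' @export
train_model <- function(model, clips, manifest, fold, epochs = 45L,
                        schedule = NULL, batch_clips = 6L, momentum = 0.9,
                        weight_decay = 1e-4, margin = 2,
                        loss_variant = c("ce+proposed", "ce",
                                         "ce+contrastive", "ce+triplet"),
                        batch_scheme = c("triplet", "stratified"),
                        seed = 1L, select_best = TRUE,
                        head_warmup_epochs = 0L, verbose = FALSE) {
  loss_variant <- match.arg(loss_variant)
  batch_scheme <- match.arg(batch_scheme)
  stopifnot(batch_clips %% 3 == 0)
  if (is.null(schedule)) schedule <- lr_schedule(epochs)
  stopifnot(length(schedule) >= epochs)
  train_idx <- which(manifest$subject_id %in% fold$train_subjects)
  if (length(train_idx) == 0) stop("empty training partition")
  val_idx <- if (!is.null(fold$val_subjects)) {
    which(manifest$subject_id %in% fold$val_subjects)
  } else {
    integer(0)
  }
  tidx <- triplet_index(manifest[train_idx, , drop = FALSE])
  params <- model_params(model)
  history <- list()
  best <- list(acc = -Inf, snap = NULL, bn = NULL, epoch = 0L)
  bn_stats <- model_bn_stats(model)

  with_seed(seed, for (ep in seq_len(epochs)) {
    lr <- schedule[ep]
    comp <- c(ce = 0, pull = 0, push = 0, total = 0)
    n_trip <- 0L
    if (batch_scheme == "triplet") {
      order <- sample(length(train_idx))
      per_batch <- batch_clips %/% 3L
      batches <- split(order, ceiling(seq_along(order) / per_batch))
    } else {
      # class-balanced batches: batch_clips/3 clips of every class
      labs <- manifest$label[train_idx]
      per_class <- batch_clips %/% 3L
      by_class <- lapply(CLASS_LEVELS, function(cl) sample(which(labs == cl)))
      nb <- max(1L, min(vapply(by_class, length, integer(1))) %/% per_class)
      batches <- lapply(seq_len(nb), function(k) {
        unlist(lapply(by_class, function(v) {
          sel <- (k - 1L) * per_class + seq_len(per_class)
          v[sel[sel <= length(v)]]
        }))
      })
    }
    for (batch in batches) {
      if (batch_scheme == "triplet") {
        triplets <- lapply(batch, function(a) {
          if (loss_variant %in% c("ce+proposed", "ce")) {
            sample_triplet(tidx, a)
          } else {
            sample_triplet_relaxed(tidx, a)
          }
        })
        local_ids <- unlist(lapply(triplets, function(tr) {
          c(tr$anchor, tr$positive, tr$negative)
        }))
      } else {
        local_ids <- batch
      }
      global_ids <- train_idx[local_ids]
      stopifnot(all(manifest$subject_id[global_ids] %in% fold$train_subjects))
      batch_clip_list <- clips[global_ids]
      fwd <- model_forward(model, batch_clip_list, train = TRUE)
      truths <- match(manifest$label[global_ids], CLASS_LEVELS)
      grads <- vector("list", length(global_ids))
      if (batch_scheme == "stratified") {
        nb_ <- length(global_ids)
        ce_batch <- 0
        for (i in seq_len(nb_)) {
          ce_batch <- ce_batch + cross_entropy(fwd$scores[i, ], truths[i])
          grads[[i]] <- list(
            dlogits = ce_logit_grad(fwd$scores[i, ], truths[i]) / nb_,
            dffinal = NULL)
        }
        comp <- comp + c(ce = ce_batch / nb_, pull = 0, push = 0,
                         total = ce_batch / nb_)
        n_trip <- n_trip + 1L
      } else {
      scale <- 1 / length(triplets)  # mean gradient over the batch triplets
      for (t in seq_along(triplets)) {
        ia <- 3L * (t - 1L) + 1L
        f <- list(a = fwd$features[ia, ], p = fwd$features[ia + 1L, ],
                  n = fwd$features[ia + 2L, ])
        ce <- sum(vapply(0:2, function(j) {
          cross_entropy(fwd$scores[ia + j, ], truths[ia + j])
        }, numeric(1)))
        mg <- switch(loss_variant,
          "ce" = NULL,
          "ce+proposed" = ,
          "ce+contrastive" = metric_grads(f$a, f$p, f$n, margin),
          "ce+triplet" = triplet_metric_grads(f$a, f$p, f$n, margin))
        pull <- push <- 0
        if (loss_variant %in% c("ce+proposed", "ce+contrastive")) {
          pull <- mse_distance(f$a, f$p)
          push <- max(0, margin - mse_distance(f$a, f$n))
        } else if (loss_variant == "ce+triplet") {
          push <- max(0, mse_distance(f$a, f$p) - mse_distance(f$a, f$n) + margin)
        }
        comp <- comp + c(ce = ce, pull = pull, push = push,
                         total = ce + pull + push)
        n_trip <- n_trip + 1L
        for (j in 0:2) {
          grads[[ia + j]] <- list(
            dlogits = scale * ce_logit_grad(fwd$scores[ia + j, ], truths[ia + j]),
            dffinal = if (is.null(mg)) NULL else {
              scale * mg[[c("anchor", "positive", "negative")[j + 1L]]]
            })
        }
      }
      }
      model_backward(model, fwd, grads)
      if (ep <= head_warmup_epochs) {
        for (nm in grep("^ta\\.fc3\\.", names(params), value = TRUE)) {
          params[[nm]]$g <- NULL
        }
      }
      sgd_step(params, lr, momentum, weight_decay)
      zero_grads(params)
      rm(fwd, grads)
      gc(FALSE)  # large activation caches; keep the heap compact
    }
    comp <- comp / max(n_trip, 1L)
    val_acc <- NA_real_
    if (length(val_idx) > 0) {
      pred <- predict_clips(model, clips[val_idx])
      val_acc <- 100 * mean(pred$pred == pred$label)
      if (select_best && val_acc >= best$acc) {
        best <- list(acc = val_acc, snap = params_snapshot(params),
                     bn = lapply(bn_stats, function(s) list(rm = s$rm, rv = s$rv)),
                     epoch = ep)
      }
    }
    history[[ep]] <- data.frame(
      epoch = ep, lr = lr, ce = comp["ce"], pull = comp["pull"],
      push = comp["push"], total = comp["total"], val_accuracy = val_acc,
      row.names = NULL)
    if (verbose) {
      message(sprintf("epoch %d lr %.0e loss %.3f val %.1f%%",
                      ep, lr, comp["total"], val_acc))
    }
  })
  if (select_best && !is.null(best$snap)) {
    params_restore(params, best$snap)
    for (nm in names(best$bn)) {
      bn_stats[[nm]]$rm <- best$bn[[nm]]$rm
      bn_stats[[nm]]$rv <- best$bn[[nm]]$rv
    }
  }
  list(model = model,
       history = if (length(history)) do.call(rbind, history) else
         data.frame(),
       best_epoch = if (select_best && best$epoch > 0) best$epoch else epochs)
}

# gradient of the standard triplet loss max(0, d_ap - d_an + m)
triplet_metric_grads <- function(fa, fp, fn, margin) {
  N <- length(fa)
  active <- (mse_distance(fa, fp) - mse_distance(fa, fn) + margin) > 0
  if (!active) {
    z <- numeric(N)
    return(list(anchor = z, positive = z, negative = z))
  }
  list(anchor = 2 / N * ((fa - fp) - (fa - fn)),
       positive = -2 / N * (fa - fp),
       negative = 2 / N * (fa - fn))
}

#' Clip-level evaluation metrics
#'
#' Argmax prediction per clip; reports overall accuracy, per-class
#' accuracy, macro one-vs-rest sensitivity and specificity, and the 3x3
#' confusion matrix (rows = truth, columns = prediction).
#'
#' @param model a `stress_model`.
#' @param clips test clips (from held-out subjects).
#' @param chunk clips per forward batch.
#' @return a `metrics_report` list.
#' @export
evaluate_clips <- function(model, clips, chunk = 8L) {
  if (length(clips) == 0) stop("empty test set")
  pred <- predict_clips(model, clips, chunk = chunk)
  conf <- table(factor(pred$label, CLASS_LEVELS),
                factor(pred$pred, CLASS_LEVELS))
  rep <- confusion_metrics(unclass(conf))
  rep$predictions <- pred
  rep
}

#' Metrics from a confusion matrix
#'
#' @param conf square count matrix, rows = truth, columns = prediction.
#' @return a `metrics_report`: clip accuracy (%), per-class accuracy (%),
#'   macro one-vs-rest sensitivity and specificity (%), and the matrix.
#' @export
confusion_metrics <- function(conf) {
  conf <- as.matrix(conf)
  total <- sum(conf)
  per_class <- 100 * diag(conf) / pmax(rowSums(conf), 1)
  sens <- mean(diag(conf) / pmax(rowSums(conf), 1)) * 100
  spec <- mean(vapply(seq_len(nrow(conf)), function(c) {
    tn <- sum(conf[-c, -c])
    fp <- sum(conf[-c, c])
    tn / max(tn + fp, 1)
  }, numeric(1))) * 100
  structure(list(
    clip_accuracy = 100 * sum(diag(conf)) / max(total, 1),
    per_class_accuracy = per_class,
    sensitivity = sens, specificity = spec,
    confusion = conf, n = total
  ), class = "metrics_report")
}

#' Video-level accuracy by threshold voting
#'
#' A video counts as correctly classified when the fraction of its
#' correctly classified clips strictly exceeds the threshold. Videos with
#' zero clips are excluded.
#'
#' @param predictions data frame with columns `video_id`, `label`, `pred`
#'   (as returned in a `metrics_report`).
#' @param thresholds numeric vector of vote thresholds (fractions).
#' @return data frame: one row per threshold with per-class and total
#'   video accuracy (%).
#' @export
evaluate_videos <- function(predictions, thresholds = c(0.4, 0.5, 0.6)) {
  stopifnot(all(c("video_id", "label", "pred") %in% names(predictions)))
  vids <- split(predictions, predictions$video_id)
  vids <- Filter(function(v) nrow(v) > 0, vids)
  frac <- vapply(vids, function(v) mean(v$pred == v$label), numeric(1))
  vlabel <- vapply(vids, function(v) v$label[1], character(1))
  do.call(rbind, lapply(thresholds, function(th) {
    correct <- frac > th
    per_class <- vapply(CLASS_LEVELS, function(cl) {
      sel <- vlabel == cl
      if (!any(sel)) NA_real_ else 100 * mean(correct[sel])
    }, numeric(1))
    data.frame(threshold = th,
               neutral = per_class["neutral"], low = per_class["low"],
               high = per_class["high"], total = 100 * mean(correct),
               row.names = NULL)
  }))
}

#' Subject-disjoint cross-validation
#'
#' Trains and evaluates one model per fold and averages the clip accuracy
#' over folds.
#'
#' @param config a [model_config()].
#' @param clips,manifest the dataset.
#' @param k number of folds.
#' @param seed fold shuffle / training seed.
#' @param ... passed to [train_model()] (epochs, schedule, ...).
#' @return list with per-fold `reports` and `mean_accuracy` (%).
#' @export
cross_validate <- function(config, clips, manifest, k = 5L, seed = 1L, ...) {
  folds <- make_subject_folds(manifest$subject_id, k = k, seed = seed)
  reports <- lapply(seq_along(folds), function(i) {
    model <- build_stress_model(config)
    fit <- train_model(model, clips, manifest, folds[[i]],
                       seed = seed + i, ...)
    test_idx <- which(manifest$subject_id %in% folds[[i]]$test_subjects)
    evaluate_clips(fit$model, clips[test_idx])
  })
  list(reports = reports,
       mean_accuracy = mean(vapply(reports, `[[`, numeric(1),
                                   "clip_accuracy")))
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d clips, accuracy %.2f%%\n", x$n,
              x$clip_accuracy))
  cat(sprintf("  per-class: %s\n", paste(sprintf(
    "%s %.1f%%", names(x$per_class_accuracy), x$per_class_accuracy),
    collapse = ", ")))
  cat(sprintf("  macro sensitivity %.2f%%, specificity %.2f%%\n",
              x$sensitivity, x$specificity))
  invisible(x)
}
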