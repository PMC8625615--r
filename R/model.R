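# Full clip-level stress recognition model: facial backbone + landmark
# branch + temporal attention fusion + classifier, assembled from a single
# configuration list and trained end-to-end.

#' Default model configuration
#'
#' @param frames_per_clip frames per input clip (default 48).
#' @param n_classes output classes (default 3).
#' @param spatial_attention,channel_attention,landmark_branch module toggles
#'   (the ablation grid).
#' @param margin_px,sigma_px,normalize,blur,joint landmark-image
#'   preprocessing settings (see [landmark_image_pipeline()]).
#' @param hidden_act,weight_head temporal-module activations (see
#'   [build_temporal_module()]).
#' @param seed integer used for weight initialization.
#' @return configuration list for [build_stress_model()].
#' @export
model_config <- function(frames_per_clip = 48L, n_classes = 3L,
                         spatial_attention = TRUE, channel_attention = FALSE,
                         landmark_branch = TRUE, margin_px = 4L,
                         sigma_px = 2, normalize = TRUE, blur = TRUE,
                         joint = FALSE, hidden_act = "relu",
                         weight_head = "sigmoid", seed = 1L) {
  list(frames_per_clip = as.integer(frames_per_clip),
       n_classes = as.integer(n_classes),
       spatial_attention = spatial_attention,
       channel_attention = channel_attention,
       landmark_branch = landmark_branch,
       margin_px = as.integer(margin_px), sigma_px = sigma_px,
       normalize = normalize, blur = blur, joint = joint,
       hidden_act = hidden_act, weight_head = weight_head,
       seed = as.integer(seed))
}

#' Build the full stress recognition model
#'
#' @param config a [model_config()] list.
#' @return a `stress_model` holding the facial backbone, the optional
#'   landmark network, and the temporal attention + classifier module.
#' @export
build_stress_model <- function(config = model_config()) {
  backbone <- build_backbone(
    seed = substream_seed(config$seed, "backbone"),
    use_spatial_attention = config$spatial_attention,
    use_channel_attention = config$channel_attention)
  lmnet <- if (config$landmark_branch) {
    build_landmark_net(seed = substream_seed(config$seed, "landmark"))
  }
  d <- backbone$feat_dim + if (config$landmark_branch) lmnet$feat_dim else 0L
  temporal <- build_temporal_module(
    d_concat = d, n_classes = config$n_classes,
    hidden_act = config$hidden_act, weight_head = config$weight_head,
    seed = substream_seed(config$seed, "temporal"))
  m <- list(config = config, backbone = backbone, lmnet = lmnet,
            temporal = temporal, d_concat = d)
  class(m) <- "stress_model"
  m
}

model_params <- function(model) {
  out <- backbone_params(model$backbone)
  if (!is.null(model$lmnet)) out <- c(out, landmark_net_params(model$lmnet))
  c(out, temporal_params(model$temporal))
}

# all batch-norm stat environments, keyed like the parameter names
model_bn_stats <- function(model) {
  grab <- function(cl, prefix) {
    if (is.null(cl$bn)) list() else setNames(list(cl$bn$stats), prefix)
  }
  out <- grab(model$backbone$conv1, "bb.conv1")
  for (i in seq_along(model$backbone$stages)) {
    st <- model$backbone$stages[[i]]
    out <- c(out, grab(st$c1, sprintf("bb.s%d.c1", i)),
             grab(st$c2, sprintf("bb.s%d.c2", i)))
    if (!is.null(st$shortcut)) out <- c(out, grab(st$shortcut, sprintf("bb.s%d.sc", i)))
  }
  if (!is.null(model$lmnet)) {
    out <- c(out, grab(model$lmnet$c1, "lm.c1"), grab(model$lmnet$c2, "lm.c2"),
             grab(model$lmnet$c3, "lm.c3"))
  }
  out
}

# stack clip frames into the engine layout (H*W*T_total rows x 3)
stack_frames <- function(clips) {
  mats <- lapply(clips, function(cl) {
    matrix(aperm(cl$frames, c(1, 2, 4, 3)), ncol = dim(cl$frames)[3])
  })
  do.call(rbind, mats)
}

# render + stack landmark images (112*112*T_total x 1)
stack_landmark_images <- function(clips, config) {
  mats <- lapply(clips, function(cl) {
    imgs <- vapply(cl$landmarks, function(p) {
      landmark_image_pipeline(p, canvas = 112L, margin_px = config$margin_px,
                              sigma_px = config$sigma_px,
                              normalize = config$normalize,
                              blur = config$blur, joint = config$joint)
    }, matrix(0, 112, 112))
    matrix(imgs, ncol = 1)
  })
  do.call(rbind, mats)
}

#' Run the model forward over a list of clips
#'
#' All frames of all clips pass through the backbone (and landmark branch)
#' as one batch; temporal attention and classification are applied per
#' clip.
#'
#' @param model a `stress_model`.
#' @param clips list of [new_clip()] objects.
#' @param train logical; training mode (batch statistics, caches kept).
#' @return list with per-clip elements `scores` (matrix n x classes),
#'   `features` (final clip features), `weights` (temporal weights per
#'   clip), `amap` (spatial attention values per frame), and caches when
#'   `train = TRUE`.
#' @export
model_forward <- function(model, clips, train = FALSE) {
  cfg <- model$config
  Ts <- vapply(clips, n_frames, integer(1))
  N <- sum(Ts)
  X <- stack_frames(clips)
  bf <- backbone_forward(model$backbone, X, N, train = train)
  lf <- NULL
  if (cfg$landmark_branch) {
    XL <- stack_landmark_images(clips, cfg)
    lf <- landmark_net_forward(model$lmnet, XL, N, train = train)
  }
  feats <- if (is.null(lf)) bf$feat else cbind(bf$feat, lf$feat)
  tb <- temporal_forward_batch(model$temporal, feats, Ts, train = train)
  amap <- if (!is.null(bf$amap)) matrix(bf$amap, ncol = bf$hw, byrow = TRUE)
  out <- list(
    scores = tb$scores,
    features = tb$ffinal,
    weights = split(tb$w, rep(seq_along(Ts), Ts)),
    wlogits = split(tb$wlogit, rep(seq_along(Ts), Ts)),
    amap = amap, Ts = Ts
  )
  if (train) {
    out$bf <- bf
    out$lf <- lf
    out$tb_cache <- tb$cache
  }
  out
}

# backward: grads is a list per clip with dlogits and optional dffinal
model_backward <- function(model, fwd, grads) {
  d <- model$d_concat
  bdim <- model$backbone$feat_dim
  dlogits <- do.call(rbind, lapply(grads, `[[`, "dlogits"))
  extras <- lapply(grads, `[[`, "dffinal")
  dff_extra <- if (all(vapply(extras, is.null, logical(1)))) {
    NULL
  } else {
    do.call(rbind, lapply(extras, function(e) {
      if (is.null(e)) numeric(d) else e
    }))
  }
  dfeats <- temporal_backward_batch(model$temporal, fwd$tb_cache,
                                    dlogits, dff_extra)
  backbone_backward(model$backbone, fwd$bf, dfeats[, seq_len(bdim), drop = FALSE])
  if (!is.null(fwd$lf)) {
    landmark_net_backward(model$lmnet, fwd$lf,
                          dfeats[, bdim + seq_len(d - bdim), drop = FALSE])
  }
  invisible(NULL)
}

#' Predict stress classes for clips
#'
#' @param model a `stress_model`.
#' @param clips list of clips.
#' @param chunk clips per forward batch (memory control).
#' @return data frame with one row per clip: subject_id, video_id, label,
#'   predicted label, and the class scores.
#' @export
predict_clips <- function(model, clips, chunk = 8L) {
  res <- list()
  for (start in seq(1, length(clips), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(clips))
    fwd <- model_forward(model, clips[idx], train = FALSE)
    scores <- fwd$scores
    res[[length(res) + 1L]] <- data.frame(
      subject_id = vapply(clips[idx], `[[`, "", "subject_id"),
      video_id = vapply(clips[idx], `[[`, "", "video_id"),
      label = vapply(clips[idx], `[[`, "", "label"),
      pred = CLASS_LEVELS[max.col(scores)],
      setNames(as.data.frame(scores), paste0("score_", CLASS_LEVELS)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' Export attention weights for inspection
#'
#' Writes, for one clip, the temporal attention weights (CSV:
#' `frame_index, weight`) and the per-frame spatial attention map (CSV:
#' `frame_index` plus one column per map cell, 16 for a 4x4 map).
#'
#' @param model a `stress_model`.
#' @param clip a clip.
#' @param dir output directory.
#' @return paths of the two files, invisibly.
#' @export
export_attention <- function(model, clip, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fwd <- model_forward(model, list(clip), train = FALSE)
  tw <- data.frame(frame_index = seq_len(n_frames(clip)),
                   weight = fwd$weights[[1]])
  tw_path <- file.path(dir, "temporal_weights.csv")
  write.csv(tw, tw_path, row.names = FALSE)
  sa_path <- file.path(dir, "spatial_attention.csv")
  if (!is.null(fwd$amap)) {
    sa <- cbind(frame_index = seq_len(nrow(fwd$amap)),
                as.data.frame(fwd$amap))
    names(sa)[-1] <- paste0("cell_", seq_len(ncol(fwd$amap)))
    write.csv(sa, sa_path, row.names = FALSE)
  }
  invisible(c(tw_path, sa_path))
}

#' Save / load a model checkpoint
#'
#' The checkpoint is an RDS file with all parameter values, batch-norm
#' running statistics and the model configuration, plus a JSON metadata
#' sidecar (config, seed, epoch).
#'
#' @param model a `stress_model`.
#' @param path checkpoint path (`.rds`).
#' @param meta list of metadata stored in the JSON sidecar.
#' @return `load_checkpoint()` returns the restored `stress_model`.
#' @export
save_checkpoint <- function(model, path, meta = list()) {
  params <- model_params(model)
  bn <- lapply(model_bn_stats(model), function(s) list(rm = s$rm, rv = s$rv))
  saveRDS(list(config = model$config, params = params_snapshot(params),
               bn = bn, meta = meta), path)
  jsonlite::write_json(
    c(list(config = model$config), meta),
    paste0(sub("\\.rds$", "", path), ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  st <- readRDS(path)
  model <- build_stress_model(st$config)
  params_restore(model_params(model), st$params)
  stats <- model_bn_stats(model)
  for (nm in names(st$bn)) {
    stats[[nm]]$rm <- st$bn[[nm]]$rm
    stats[[nm]]$rv <- st$bn[[nm]]$rv
  }
  model
}

#' @export
print.stress_model <- function(x, ...) {
  cat("<stress_model>\n")
  cat(sprintf("  frames/clip %d, concat dim %d, %d classes\n",
              x$config$frames_per_clip, x$d_concat, x$config$n_classes))
  cat(sprintf("  spatial attention %s | channel attention %s | landmark branch %s\n",
              x$config$spatial_attention, x$config$channel_attention,
              x$config$landmark_branch))
  cat("  trainable parameters:", count_parameters(x), "\n")
  invisible(x)
}
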