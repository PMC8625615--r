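# ResNet-18 facial backbone with spatial (and optional channel) attention.
#
# The residual stack follows the printed architecture: 7x7/2 stem conv,
# 3x3/2 max pooling, then four residual stages producing 28x28x64,
# 14x14x128, 7x7x256 and 4x4x512 maps for a 112x112x3 input. Stages 3-5
# downsample on both the main path (first 3x3 conv, stride 2) and the
# shortcut (1x1 conv, stride 2). No pretrained weights are ever loaded.

#' Spatial attention map from convolutional feature maps
#'
#' Computes the attention map `sigma(conv7x7([AvgPool(F); MaxPool(F)]))`:
#' channel-wise mean and max maps are concatenated on the channel axis,
#' convolved with a single 7x7 filter (zero same-padding, one output
#' channel) and squashed through the sigmoid, giving one weight in (0, 1)
#' per spatial location.
#'
#' @param fmap numeric array `h x w x C` of feature maps.
#' @param kernel numeric array `kh x kw x 2` convolution filter
#'   (first channel applies to the mean map, second to the max map).
#' @param bias scalar bias.
#' @return numeric matrix `h x w` with entries strictly in (0, 1).
#' @seealso [attend_and_pool()]
#' @export
spatial_attention <- function(fmap, kernel, bias = 0) {
  stopifnot(length(dim(fmap)) == 3, length(dim(kernel)) == 3,
            dim(kernel)[3] == 2)
  avg <- rowMeans(fmap, dims = 2)
  mx <- apply(fmap, c(1, 2), max)
  pre <- conv2d_same(array(c(avg, mx), c(dim(fmap)[1:2], 2)), kernel) + bias
  sigmoid(pre)
}

#' Attention-weighted global average pooling with identity mapping
#'
#' Implements `GAP(F + M o F)`: the attention map rescales every channel of
#' the feature maps, the rescaled maps are added back onto the originals
#' (identity mapping), and each channel is averaged over the spatial grid.
#'
#' @param fmap numeric array `h x w x C`.
#' @param amap numeric matrix `h x w` of attention weights.
#' @return numeric vector of length `C`.
#' @export
attend_and_pool <- function(fmap, amap) {
  stopifnot(all(dim(fmap)[1:2] == dim(amap)))
  colMeans(matrix(as.numeric(fmap) * as.numeric(1 + amap),
                  ncol = dim(fmap)[3]))
}

#' Channel attention over convolutional feature maps
#'
#' Squeeze-style channel attention: spatial average- and max-pooled channel
#' descriptors pass through a shared two-layer bottleneck MLP, the two
#' outputs are summed and squashed through the sigmoid, giving one weight
#' per channel. Composed with the feature maps by identity mapping,
#' `F + M_ca o F`, mirroring the spatial module.
#'
#' @param fmap numeric array `h x w x C`.
#' @param w1,b1 first bottleneck layer, `C/r x C` weight and length-`C/r` bias.
#' @param w2,b2 second layer, `C x C/r` weight and length-`C` bias.
#' @return numeric vector of `C` channel weights in (0, 1).
#' @export
channel_attention <- function(fmap, w1, b1, w2, b2) {
  stopifnot(length(dim(fmap)) == 3)
  C <- dim(fmap)[3]
  flat <- matrix(fmap, ncol = C)
  s_avg <- colMeans(flat)
  s_max <- apply(flat, 2, max)
  mlp <- function(s) as.numeric(w2 %*% relu(w1 %*% s + b1) + b2)
  sigmoid(mlp(s_avg) + mlp(s_max))
}

# same-padded 2-D convolution, double precision (small inputs only)
conv2d_same <- function(x, k) {
  h <- dim(x)[1]; w <- dim(x)[2]
  kh <- dim(k)[1]; kw <- dim(k)[2]
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  out <- matrix(0, h, w)
  xp <- array(0, c(h + 2 * ph, w + 2 * pw, dim(x)[3]))
  xp[ph + seq_len(h), pw + seq_len(w), ] <- x
  for (ch in seq_len(dim(x)[3])) {
    for (dj in seq_len(kw)) {
      for (di in seq_len(kh)) {
        out <- out + k[di, dj, ch] *
          xp[di + seq_len(h) - 1L, dj + seq_len(w) - 1L, ch]
      }
    }
  }
  out
}

# gradient of conv2d_same w.r.t. input and kernel
conv2d_same_bw <- function(x, k, dout) {
  h <- dim(x)[1]; w <- dim(x)[2]
  kh <- dim(k)[1]; kw <- dim(k)[2]
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  xp <- array(0, c(h + 2 * ph, w + 2 * pw, dim(x)[3]))
  xp[ph + seq_len(h), pw + seq_len(w), ] <- x
  dxp <- array(0, dim(xp))
  dk <- array(0, dim(k))
  for (ch in seq_len(dim(x)[3])) {
    for (dj in seq_len(kw)) {
      for (di in seq_len(kh)) {
        win_r <- di + seq_len(h) - 1L
        win_c <- dj + seq_len(w) - 1L
        dk[di, dj, ch] <- sum(dout * xp[win_r, win_c, ch])
        dxp[win_r, win_c, ch] <- dxp[win_r, win_c, ch] + k[di, dj, ch] * dout
      }
    }
  }
  list(dx = dxp[ph + seq_len(h), pw + seq_len(w), , drop = FALSE], dk = dk)
}

#' Build the facial backbone
#'
#' Constructs the from-scratch ResNet-18 feature extractor (randomly
#' initialized, fan-in scaled) together with its attention modules. For a
#' 112x112x3 input the stack produces 4x4x512 feature maps which the
#' spatial attention + identity-mapped global average pooling turn into a
#' 512-length facial image feature.
#'
#' @param seed optional integer; fixes the weight initialization.
#' @param use_spatial_attention,use_channel_attention logical toggles for the
#'   attention ablation grid.
#' @param in_channels input channels (3 for RGB face crops).
#' @return a `facial_backbone` object.
#' @export
build_backbone <- function(seed = NULL, use_spatial_attention = TRUE,
                           use_channel_attention = FALSE, in_channels = 3) {
  builder <- function() {
    stages <- list(
      list(cin = 64, cout = 64, s = 1),
      list(cin = 64, cout = 128, s = 2),
      list(cin = 128, cout = 256, s = 2),
      list(cin = 256, cout = 512, s = 2)
    )
    bb <- list(
      conv1 = new_conv(7, 7, in_channels, 64, 2, 3),
      stages = lapply(stages, function(st) {
        list(
          c1 = new_conv(3, 3, st$cin, st$cout, st$s, 1, act = "relu"),
          c2 = new_conv(3, 3, st$cout, st$cout, 1, 1, act = "none"),
          shortcut = if (st$s == 2) new_conv(1, 1, st$cin, st$cout, 2, 0, act = "none")
        )
      }),
      use_spatial_attention = use_spatial_attention,
      use_channel_attention = use_channel_attention,
      feat_dim = 512L
    )
    if (use_spatial_attention) {
      bb$sa <- list(
        K = new_param(array(rnorm(98, sd = sqrt(2 / 98)), c(7, 7, 2))),
        b = new_param(0, decay = FALSE)
      )
    }
    if (use_channel_attention) {
      r <- 16L
      bb$ca <- list(
        fc1 = new_fc(512L, 512L %/% r),
        fc2 = new_fc(512L %/% r, 512L, init = "xavier")
      )
    }
    class(bb) <- "facial_backbone"
    bb
  }
  if (is.null(seed)) builder() else with_seed(seed, builder())
}

backbone_params <- function(bb) {
  out <- conv_params(bb$conv1, "bb.conv1")
  for (i in seq_along(bb$stages)) {
    st <- bb$stages[[i]]
    out <- c(out, conv_params(st$c1, sprintf("bb.s%d.c1", i)),
             conv_params(st$c2, sprintf("bb.s%d.c2", i)))
    if (!is.null(st$shortcut)) {
      out <- c(out, conv_params(st$shortcut, sprintf("bb.s%d.sc", i)))
    }
  }
  if (!is.null(bb$sa)) {
    out <- c(out, setNames(list(bb$sa$K, bb$sa$b), c("bb.sa.K", "bb.sa.b")))
  }
  if (!is.null(bb$ca)) {
    out <- c(out, fc_params(bb$ca$fc1, "bb.ca.fc1"),
             fc_params(bb$ca$fc2, "bb.ca.fc2"))
  }
  out
}

#' Number of trainable parameters
#'
#' @param x a `facial_backbone`, `landmark_net` or `stress_model`.
#' @return integer count of trainable scalar parameters.
#' @export
count_parameters <- function(x) {
  params <- if (inherits(x, "facial_backbone")) {
    backbone_params(x)
  } else if (inherits(x, "landmark_net")) {
    landmark_net_params(x)
  } else if (inherits(x, "stress_model")) {
    model_params(x)
  } else {
    stop("unsupported object")
  }
  sum(vapply(params, function(p) length(p$v), integer(1)))
}

residual_stage_forward <- function(st, X, H, W, N, train) {
  r1 <- conv_forward(st$c1, X, H, W, N, train)
  r2 <- conv_forward(st$c2, r1$Y, r1$H, r1$W, N, train)
  if (is.null(st$shortcut)) {
    sc_y <- X
    sc_cache <- NULL
  } else {
    rs <- conv_forward(st$shortcut, X, H, W, N, train)
    sc_y <- rs$Y
    sc_cache <- rs$cache
  }
  out <- relu(r2$Y + sc_y)
  list(Y = out, H = r2$H, W = r2$W,
       cache = list(c1 = r1$cache, c2 = r2$cache, sc = sc_cache, out = out))
}

residual_stage_backward <- function(st, cache, dY, need_dx = TRUE) {
  d <- dY * (cache$out > 0)
  d2 <- conv_backward(st$c2, cache$c2, d)
  d1 <- conv_backward(st$c1, cache$c1, d2, need_dx = need_dx)
  if (is.null(st$shortcut)) {
    dsc <- d
  } else {
    dsc <- conv_backward(st$shortcut, cache$sc, d, need_dx = need_dx)
  }
  if (need_dx) d1 + dsc else NULL
}

# batched spatial attention over the engine layout (hw*N x C)
sa_forward_batch <- function(sa, F, hw, N) {
  avg <- rowMeans(F)
  mx <- .rowmax_fw(F)
  P <- cbind(avg, mx$value)
  side <- as.integer(sqrt(hw))
  pre <- numeric(hw * N)
  for (n in seq_len(N)) {
    rows <- (n - 1L) * hw + seq_len(hw)
    pre[rows] <- conv2d_same(array(P[rows, ], c(side, side, 2)), sa$K$v) +
      sa$b$v
  }
  M <- sigmoid(pre)
  list(M = M, out = F * (1 + M), P = P, arg = mx$arg, side = side)
}

sa_backward_batch <- function(sa, F, cache, dout, hw, N) {
  dF <- dout * (1 + cache$M)
  dM <- rowSums(dout * F)
  dpre <- dM * cache$M * (1 - cache$M)
  dP <- matrix(0, hw * N, 2)
  dK <- array(0, dim(sa$K$v))
  db <- 0
  side <- cache$side
  for (n in seq_len(N)) {
    rows <- (n - 1L) * hw + seq_len(hw)
    g <- conv2d_same_bw(array(cache$P[rows, ], c(side, side, 2)), sa$K$v,
                        matrix(dpre[rows], side, side))
    dP[rows, ] <- matrix(g$dx, ncol = 2)
    dK <- dK + g$dk
    db <- db + sum(dpre[rows])
  }
  acc_grad(sa$K, dK)
  acc_grad(sa$b, db)
  dF <- dF + dP[, 1] / ncol(F)
  idx <- cbind(seq_len(hw * N), cache$arg)
  dF[idx] <- dF[idx] + dP[, 2]
  dF
}

# batched channel attention (hw*N x C); weights shape (N x C)
ca_forward_batch <- function(ca, F, hw, N) {
  C <- ncol(F)
  s_avg <- gap_forward(F, hw, N)
  m <- .rowmax_fw(t(matrix(F, nrow = hw)))  # (N*C) maxima, image-major rows
  s_max <- matrix(m$value, nrow = N)
  h_avg <- relu(fc_forward(ca$fc1, s_avg))
  h_max <- relu(fc_forward(ca$fc1, s_max))
  a <- fc_forward(ca$fc2, h_avg) + fc_forward(ca$fc2, h_max)
  M <- sigmoid(a)
  Mrow <- M[rep(seq_len(N), each = hw), , drop = FALSE]
  list(M = M, Mrow = Mrow, out = F * (1 + Mrow),
       s_avg = s_avg, s_max = s_max, h_avg = h_avg, h_max = h_max,
       arg = m$arg)
}

ca_backward_batch <- function(ca, F, cache, dout, hw, N) {
  dF <- dout * (1 + cache$Mrow)
  dM_rows <- dout * F
  dM <- gap_forward(dM_rows, hw, N) * hw  # per-image colSums
  da <- dM * cache$M * (1 - cache$M)
  dh_avg <- fc_backward(ca$fc2, cache$h_avg, da) * (cache$h_avg > 0)
  dh_max <- fc_backward(ca$fc2, cache$h_max, da) * (cache$h_max > 0)
  ds_avg <- fc_backward(ca$fc1, cache$s_avg, dh_avg)
  ds_max <- fc_backward(ca$fc1, cache$s_max, dh_max)
  dF <- dF + ds_avg[rep(seq_len(N), each = hw), , drop = FALSE] / hw
  # scatter max-descriptor gradient to the argmax pixel of each (image, channel)
  flat_arg <- as.integer(cache$arg)  # pixel index within image, (N*C) order
  img <- rep(rep(seq_len(N), ncol(F)))
  ch <- rep(seq_len(ncol(F)), each = N)
  rows <- (img - 1L) * hw + flat_arg
  idx <- cbind(rows, ch)
  dF[idx] <- dF[idx] + as.numeric(ds_max)
  dF
}

# full backbone forward on the engine layout; X is (112*112*N x Cin)
backbone_forward <- function(bb, X, N, train = FALSE, H = 112L, W = 112L) {
  shapes <- list(input = c(H, W, ncol(X)))
  r <- conv_forward(bb$conv1, X, H, W, N, train)
  shapes$conv1 <- c(r$H, r$W, ncol(r$Y))
  mp <- maxpool_forward(r$Y, r$H, r$W, N, 3L, 2L, 1L)
  shapes$maxpool <- c(mp$H, mp$W, ncol(mp$Y))
  cache <- list(conv1 = r$cache, mp = mp)
  Y <- mp$Y; h <- mp$H; w <- mp$W
  for (i in seq_along(bb$stages)) {
    rs <- residual_stage_forward(bb$stages[[i]], Y, h, w, N, train)
    cache[[paste0("stage", i)]] <- rs$cache
    Y <- rs$Y; h <- rs$H; w <- rs$W
    shapes[[paste0("stage", i)]] <- c(h, w, ncol(Y))
  }
  hw <- h * w
  fmap <- Y
  if (bb$use_channel_attention) {
    cac <- ca_forward_batch(bb$ca, Y, hw, N)
    cache$ca <- cac
    cache$ca_in <- Y
    Y <- cac$out
  }
  amap <- NULL
  if (bb$use_spatial_attention) {
    sac <- sa_forward_batch(bb$sa, Y, hw, N)
    cache$sa <- sac
    cache$sa_in <- Y
    amap <- sac$M
    shapes$attention <- c(h, w, 1)
    Y <- sac$out
  }
  feat <- gap_forward(Y, hw, N)
  shapes$feature <- length(feat[1, ])
  list(feat = feat, fmap = fmap, amap = amap, hw = hw, N = N,
       shapes = shapes, cache = cache)
}

backbone_backward <- function(bb, fwd, dfeat) {
  hw <- fwd$hw; N <- fwd$N
  d <- gap_backward(dfeat, hw, N)
  if (bb$use_spatial_attention) {
    d <- sa_backward_batch(bb$sa, fwd$cache$sa_in, fwd$cache$sa, d, hw, N)
  }
  if (bb$use_channel_attention) {
    d <- ca_backward_batch(bb$ca, fwd$cache$ca_in, fwd$cache$ca, d, hw, N)
  }
  for (i in rev(seq_along(bb$stages))) {
    d <- residual_stage_backward(bb$stages[[i]], fwd$cache[[paste0("stage", i)]], d)
  }
  d <- maxpool_backward(fwd$cache$mp, d)
  conv_backward(bb$conv1, fwd$cache$conv1, d, need_dx = FALSE)
  invisible(NULL)
}

#' Forward shape trace of the backbone
#'
#' Runs a single random 112x112x3 image through the backbone and returns
#' the output dimensions of every unit (stem conv, max pooling, the four
#' residual stages, the attention map and the pooled feature).
#'
#' @param bb a `facial_backbone`.
#' @return named list of integer dimension vectors.
#' @export
backbone_shape_trace <- function(bb) {
  X <- matrix(runif(112 * 112 * 3), ncol = 3)
  backbone_forward(bb, X, 1L, train = FALSE)$shapes
}

#' @export
print.facial_backbone <- function(x, ...) {
  cat("<facial_backbone> ResNet-18 (from scratch), 112x112x3 -> 4x4x512 -> 512\n")
  cat("  spatial attention:", x$use_spatial_attention,
      "| channel attention:", x$use_channel_attention, "\n")
  cat("  trainable parameters:", count_parameters(x), "\n")
  invisible(x)
}
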