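# Landmark feature CNN: three Conv-BN-ReLU blocks, 7x7 kernels, stride 2,
# no padding (so spatial size shrinks 112 -> 53 -> 24 -> 9), channel widths
# 64/128/256, then global average pooling to a 256-length feature. The
# landmark image content is simple, so a deliberately small network is used.

#' Build the landmark feature network
#'
#' @param seed optional integer fixing initialization.
#' @return a `landmark_net` object mapping a 112x112x1 landmark image to a
#'   256-length facial landmark feature.
#' @export
build_landmark_net <- function(seed = NULL) {
  builder <- function() {
    net <- list(
      c1 = new_conv(7, 7, 1, 64, 2, 0),
      c2 = new_conv(7, 7, 64, 128, 2, 0),
      c3 = new_conv(7, 7, 128, 256, 2, 0),
      feat_dim = 256L
    )
    class(net) <- "landmark_net"
    net
  }
  if (is.null(seed)) builder() else with_seed(seed, builder())
}

landmark_net_params <- function(net) {
  c(conv_params(net$c1, "lm.c1"), conv_params(net$c2, "lm.c2"),
    conv_params(net$c3, "lm.c3"))
}

# X layout: (112*112*N x 1)
landmark_net_forward <- function(net, X, N, train = FALSE, H = 112L) {
  if (nrow(X) != H * H * N || ncol(X) != 1) {
    stop("shape error: landmark net expects ", H, "x", H, "x1 images")
  }
  shapes <- list(input = c(H, H, 1))
  r1 <- conv_forward(net$c1, X, H, H, N, train)
  shapes$conv1 <- c(r1$H, r1$W, ncol(r1$Y))
  r2 <- conv_forward(net$c2, r1$Y, r1$H, r1$W, N, train)
  shapes$conv2 <- c(r2$H, r2$W, ncol(r2$Y))
  r3 <- conv_forward(net$c3, r2$Y, r2$H, r2$W, N, train)
  shapes$conv3 <- c(r3$H, r3$W, ncol(r3$Y))
  hw <- r3$H * r3$W
  feat <- gap_forward(r3$Y, hw, N)
  shapes$feature <- ncol(feat)
  list(feat = feat, hw = hw, N = N, shapes = shapes,
       cache = list(c1 = r1$cache, c2 = r2$cache, c3 = r3$cache))
}

landmark_net_backward <- function(net, fwd, dfeat) {
  d <- gap_backward(dfeat, fwd$hw, fwd$N)
  d <- conv_backward(net$c3, fwd$cache$c3, d)
  d <- conv_backward(net$c2, fwd$cache$c2, d)
  conv_backward(net$c1, fwd$cache$c1, d, need_dx = FALSE)
  invisible(NULL)
}

#' Extract the facial landmark feature from a landmark image
#'
#' @param net a `landmark_net`.
#' @param img `112 x 112` landmark image matrix (or 112x112x1 array).
#' @return numeric vector of length 256.
#' @export
extract_landmark_feature <- function(net, img) {
  img <- drop(img)
  if (!is.matrix(img) || nrow(img) != 112 || ncol(img) != 112) {
    stop("shape error: expected a 112x112 landmark image")
  }
  as.numeric(landmark_net_forward(net, matrix(as.numeric(img), ncol = 1), 1L)$feat)
}

#' Forward shape trace of the landmark network
#'
#' @param net a `landmark_net`.
#' @return named list of output dimensions per block.
#' @export
landmark_net_shape_trace <- function(net) {
  X <- matrix(runif(112 * 112), ncol = 1)
  landmark_net_forward(net, X, 1L)$shapes
}

#' @export
print.landmark_net <- function(x, ...) {
  cat("<landmark_net> 112x112x1 -> 53x53x64 -> 24x24x128 -> 9x9x256 -> 256\n")
  cat("  trainable parameters:", count_parameters(x), "\n")
  invisible(x)
}
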