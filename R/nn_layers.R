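# Minimal CPU neural-network engine.
#
# Activations are numeric matrices with H*W*N rows (pixel r + c*H within an
# image, images stacked in blocks) and C columns; fully connected
# activations are plain n x d matrices. Parameters live in small
# environments so gradient accumulation and SGD updates mutate in place.

# ---- parameters -----------------------------------------------------------

new_param <- function(val, decay = TRUE) {
  e <- new.env(parent = emptyenv())
  e$v <- val
  e$g <- NULL
  e$m <- NULL
  e$decay <- decay
  class(e) <- "nn_param"
  e
}

acc_grad <- function(p, g) {
  p$g <- if (is.null(p$g)) g else p$g + g
  invisible(p)
}

zero_grads <- function(params) {
  for (p in params) p$g <- NULL
  invisible(params)
}

# He (fan-in scaled) normal initialization for ReLU layers.
init_he <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

init_xavier <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, sd = sqrt(1 / fan_in)), nrow, ncol)
}

# ---- convolution + batch norm blocks -------------------------------------

# weights stored (kh*kw*cin) x cout, in-column order dr + dc*kh + ci*kh*kw
new_conv <- function(kh, kw, cin, cout, stride, pad, bn = TRUE,
                     act = c("relu", "none")) {
  act <- match.arg(act)
  fan_in <- kh * kw * cin
  layer <- list(
    kh = kh, kw = kw, cin = cin, cout = cout, stride = stride, pad = pad,
    W = new_param(init_he(fan_in, cout, fan_in)),
    b = new_param(rep(0, cout), decay = FALSE),
    act = act,
    bn = if (bn) new_bn(cout) else NULL
  )
  class(layer) <- "conv_layer"
  layer
}

new_bn <- function(c, eps = 1e-5, momentum = 0.1) {
  s <- new.env(parent = emptyenv())
  s$rm <- rep(0, c)
  s$rv <- rep(1, c)
  list(
    gamma = new_param(rep(1, c), decay = FALSE),
    beta = new_param(rep(0, c), decay = FALSE),
    stats = s, eps = eps, momentum = momentum
  )
}

conv_forward <- function(cl, X, H, W, N, train) {
  Y <- .conv2d_fw(X, H, W, N, cl$W$v, cl$b$v, cl$kh, cl$kw, cl$stride, cl$pad)
  Ho <- (H + 2 * cl$pad - cl$kh) %/% cl$stride + 1
  Wo <- (W + 2 * cl$pad - cl$kw) %/% cl$stride + 1
  cache <- list(X = X, H = H, W = W, N = N)
  if (!is.null(cl$bn)) {
    bn <- cl$bn
    r <- .bn_fw(Y, bn$gamma$v, bn$beta$v, bn$stats$rm, bn$stats$rv,
                bn$eps, bn$momentum, train, cl$act == "relu")
    if (train) {
      bn$stats$rm <- r$rm
      bn$stats$rv <- r$rv
    }
    cache$bn <- list(X = Y, m = r$m, ivar = r$ivar)
    Y <- r$Y
    cache$out <- Y
  } else if (cl$act == "relu") {
    Y <- relu(Y)
    cache$out <- Y
  }
  list(Y = Y, H = Ho, W = Wo, cache = cache)
}

conv_backward <- function(cl, cache, dY, need_dx = TRUE) {
  if (!is.null(cl$bn)) {
    use_relu <- cl$act == "relu"
    r <- .bn_bw(cache$bn$X, cache$bn$m, cache$bn$ivar, cl$bn$gamma$v, dY,
                if (use_relu) cache$out else matrix(0, 0, 0), use_relu)
    acc_grad(cl$bn$gamma, r$dgamma)
    acc_grad(cl$bn$beta, r$dbeta)
    dY <- r$dX
  } else if (cl$act == "relu") {
    dY <- dY * (cache$out > 0)
  }
  r <- .conv2d_bw(cache$X, cache$H, cache$W, cache$N, cl$W$v, dY,
                  cl$kh, cl$kw, cl$stride, cl$pad, need_dx)
  acc_grad(cl$W, r$dW)
  acc_grad(cl$b, r$db)
  if (need_dx) r$dX else NULL
}

conv_params <- function(cl, prefix) {
  out <- list(W = cl$W, b = cl$b)
  if (!is.null(cl$bn)) {
    out$gamma <- cl$bn$gamma
    out$beta <- cl$bn$beta
  }
  setNames(out, paste0(prefix, ".", names(out)))
}

# ---- pooling --------------------------------------------------------------

maxpool_forward <- function(X, H, W, N, k, stride, pad) {
  r <- .maxpool_fw(X, H, W, N, k, stride, pad)
  Ho <- (H + 2 * pad - k) %/% stride + 1
  list(Y = r$Y, arg = r$arg, H = Ho, W = Ho, nrow_x = nrow(X))
}

maxpool_backward <- function(cache, dY) {
  .maxpool_bw(dY, cache$arg, cache$nrow_x)
}

# global average pooling: (hw*N x C) -> (N x C)
gap_forward <- function(X, hw, N) {
  matrix(.colMeans(matrix(X, nrow = hw), hw, N * ncol(X)), nrow = N)
}

gap_backward <- function(dY, hw, N) {
  dY[rep(seq_len(N), each = hw), , drop = FALSE] / hw
}

# ---- fully connected ------------------------------------------------------

new_fc <- function(d_in, d_out, init = c("he", "xavier", "small")) {
  init <- match.arg(init)
  W <- switch(init,
    he = init_he(d_out, d_in, d_in),
    xavier = init_xavier(d_out, d_in, d_in),
    # near-zero head: keeps sigmoid/softmax heads in their linear regime
    # at the start of training (a saturated attention head stalls every
    # upstream gradient)
    small = matrix(rnorm(d_out * d_in, sd = 1e-3), d_out, d_in))
  list(W = new_param(W), b = new_param(rep(0, d_out), decay = FALSE))
}

fc_forward <- function(fc, X) {
  Y <- tcrossprod(X, fc$W$v)
  Y + rep(fc$b$v, each = nrow(X))
}

fc_backward <- function(fc, X, dY) {
  acc_grad(fc$W, crossprod(dY, X))
  acc_grad(fc$b, .colSums(dY, nrow(dY), ncol(dY)))
  dY %*% fc$W$v
}

fc_params <- function(fc, prefix) {
  setNames(list(fc$W, fc$b), paste0(prefix, c(".W", ".b")))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- optimizer ------------------------------------------------------------

# SGD with momentum and decoupled-from-biases L2 weight decay:
#   v <- mu * v + g + wd * p ; p <- p - lr * v
sgd_step <- function(params, lr, momentum = 0.9, weight_decay = 1e-4) {
  for (p in params) {
    if (is.null(p$g)) next
    g <- p$g
    if (p$decay && weight_decay > 0) g <- g + weight_decay * p$v
    p$m <- if (is.null(p$m)) g else momentum * p$m + g
    p$v <- p$v - lr * p$m
  }
  invisible(params)
}

# deep-copy parameter values (for best-epoch checkpointing)
params_snapshot <- function(params) lapply(params, function(p) p$v)

params_restore <- function(params, snap) {
  for (nm in names(snap)) params[[nm]]$v <- snap[[nm]]
  invisible(params)
}
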