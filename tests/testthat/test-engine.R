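# Correctness of the compiled training-engine kernels against independent
# double-precision oracles, and finite-difference checks of the pure-R
# backward passes.

test_that("the convolution kernel matches a direct double-precision oracle", {
  set.seed(1)
  cases <- list(
    list(H = 9, W = 9, cin = 3, cout = 4, k = 3, s = 1, p = 1),
    list(H = 12, W = 10, cin = 2, cout = 5, k = 7, s = 2, p = 0),
    list(H = 8, W = 8, cin = 4, cout = 3, k = 1, s = 2, p = 0),
    list(H = 11, W = 11, cin = 1, cout = 2, k = 7, s = 2, p = 3)
  )
  for (cs in cases) {
    N <- 2
    X <- matrix(rnorm(cs$H * cs$W * N * cs$cin), ncol = cs$cin)
    Wt <- matrix(rnorm(cs$k^2 * cs$cin * cs$cout, sd = 0.5), ncol = cs$cout)
    b <- rnorm(cs$cout)
    Y <- stressclip:::.conv2d_fw(X, cs$H, cs$W, N, Wt, b, cs$k, cs$k,
                                 cs$s, cs$p)
    hw_out <- nrow(Y) / N
    for (n in 1:N) {
      rows_in <- (n - 1) * cs$H * cs$W + seq_len(cs$H * cs$W)
      rows_out <- (n - 1) * hw_out + seq_len(hw_out)
      want <- oracle_conv2d(X[rows_in, , drop = FALSE], cs$H, cs$W, Wt, b,
                            cs$k, cs$k, cs$s, cs$p)
      expect_equal(Y[rows_out, , drop = FALSE], want, tolerance = 1e-5)
    }
  }
})

test_that("convolution backward agrees with finite differences of the kernel", {
  set.seed(2)
  H <- 7; W <- 7; cin <- 2; cout <- 3; k <- 3; s <- 2; p <- 1; N <- 2
  X <- matrix(rnorm(H * W * N * cin), ncol = cin)
  Wt <- matrix(rnorm(k * k * cin * cout, sd = 0.5), ncol = cout)
  b <- rnorm(cout)
  Y0 <- stressclip:::.conv2d_fw(X, H, W, N, Wt, b, k, k, s, p)
  dY <- matrix(rnorm(length(Y0)), nrow = nrow(Y0))
  loss <- function(Xv, Wv, bv) {
    sum(stressclip:::.conv2d_fw(Xv, H, W, N, Wv, bv, k, k, s, p) * dY)
  }
  bw <- stressclip:::.conv2d_bw(X, H, W, N, Wt, dY, k, k, s, p, TRUE)
  h <- 1e-2  # float32 kernels: balanced step
  for (i in sample(length(Wt), 6)) {
    Wp <- Wt; Wp[i] <- Wp[i] + h
    Wm <- Wt; Wm[i] <- Wm[i] - h
    expect_equal(bw$dW[i], (loss(X, Wp, b) - loss(X, Wm, b)) / (2 * h),
                 tolerance = 5e-3)
  }
  for (i in sample(length(X), 6)) {
    Xp <- X; Xp[i] <- Xp[i] + h
    Xm <- X; Xm[i] <- Xm[i] - h
    expect_equal(bw$dX[i], (loss(Xp, Wt, b) - loss(Xm, Wt, b)) / (2 * h),
                 tolerance = 5e-3)
  }
  expect_equal(bw$db, colSums(dY), tolerance = 1e-4)
})

test_that("max pooling forward/backward route values and gradients correctly", {
  set.seed(3)
  H <- 6; W <- 6; N <- 2; C <- 3
  X <- matrix(rnorm(H * W * N * C), ncol = C)
  r <- stressclip:::.maxpool_fw(X, H, W, N, 3L, 2L, 1L)
  # every pooled value is the max over its (clamped) 3x3 window
  expect_equal(nrow(r$Y), 3 * 3 * N)
  for (c in 1:C) {
    expect_true(all(r$Y[, c] == X[r$arg[, c], c]))
  }
  dY <- matrix(rnorm(length(r$Y)), nrow = nrow(r$Y))
  dX <- stressclip:::.maxpool_bw(dY, r$arg, nrow(X))
  # total gradient mass is conserved per channel
  expect_equal(colSums(dX), colSums(dY), tolerance = 1e-12)
})

test_that("batch-norm forward/backward match a double-precision reference", {
  set.seed(4)
  n <- 40; C <- 5
  X <- matrix(rnorm(n * C, mean = 2, sd = 3), ncol = C)
  gamma <- runif(C, 0.5, 2); beta <- rnorm(C)
  rm0 <- rnorm(C); rv0 <- runif(C, 0.5, 2)
  eps <- 1e-5; mom <- 0.1
  out <- stressclip:::.bn_fw(X, gamma, beta, rm0, rv0, eps, mom, TRUE, FALSE)
  m_ref <- colMeans(X)
  v_ref <- colMeans(sweep(X, 2, m_ref)^2)
  xhat <- sweep(sweep(X, 2, m_ref), 2, sqrt(v_ref + eps), "/")
  Y_ref <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  expect_equal(out$Y, Y_ref, tolerance = 1e-10)
  expect_equal(out$rm, (1 - mom) * rm0 + mom * m_ref, tolerance = 1e-10)
  expect_equal(out$rv, (1 - mom) * rv0 + mom * v_ref * n / (n - 1),
               tolerance = 1e-10)

  dY <- matrix(rnorm(n * C), ncol = C)
  bw <- stressclip:::.bn_bw(X, out$m, out$ivar, gamma, dY, matrix(0, 0, 0),
                            FALSE)
  expect_equal(bw$dgamma, colSums(dY * xhat), tolerance = 1e-10)
  expect_equal(bw$dbeta, colSums(dY), tolerance = 1e-10)
  # finite-difference check of dX through the full normalization
  f <- function(Xv) {
    m <- colMeans(Xv)
    v <- colMeans(sweep(Xv, 2, m)^2)
    xh <- sweep(sweep(Xv, 2, m), 2, sqrt(v + eps), "/")
    sum(sweep(sweep(xh, 2, gamma, "*"), 2, beta, "+") * dY)
  }
  h <- 1e-5
  for (i in sample(length(X), 6)) {
    Xp <- X; Xp[i] <- Xp[i] + h
    Xm <- X; Xm[i] <- Xm[i] - h
    expect_equal(bw$dX[i], (f(Xp) - f(Xm)) / (2 * h), tolerance = 1e-4)
  }
  # eval mode uses the running statistics
  ev <- stressclip:::.bn_fw(X, gamma, beta, rm0, rv0, eps, mom, FALSE, FALSE)
  Y_ev <- sweep(sweep(sweep(sweep(X, 2, rm0), 2, sqrt(rv0 + eps), "/"),
                      2, gamma, "*"), 2, beta, "+")
  expect_equal(ev$Y, Y_ev, tolerance = 1e-10)
})

test_that("temporal module backward matches finite differences", {
  set.seed(5)
  tm <- build_temporal_module(d_concat = 5, seed = 6)
  f <- matrix(rnorm(4 * 5), 4)
  truth <- 2L
  loss_of <- function(fv) {
    out <- stressclip:::temporal_forward(tm, fv, train = FALSE)
    cross_entropy(out$scores, truth) + 0.5 * sum(out$ffinal^2)
  }
  out <- stressclip:::temporal_forward(tm, f, train = TRUE)
  dlogits <- stressclip:::ce_logit_grad(out$scores, truth)
  df <- stressclip:::temporal_backward(tm, out$cache, dlogits, out$ffinal)
  h <- 1e-6
  for (i in sample(length(f), 8)) {
    fp <- f; fp[i] <- fp[i] + h
    fm <- f; fm[i] <- fm[i] - h
    expect_equal(df[i], (loss_of(fp) - loss_of(fm)) / (2 * h),
                 tolerance = 1e-5)
  }
})

test_that("batched spatial-attention backward matches finite differences", {
  set.seed(6)
  C <- 6; N <- 2; hw <- 16
  sa <- list(K = stressclip:::new_param(array(rnorm(98, sd = 0.3), c(7, 7, 2))),
             b = stressclip:::new_param(0.2))
  Fm <- matrix(rnorm(hw * N * C), ncol = C)
  dout <- matrix(rnorm(hw * N * C), ncol = C)
  loss_of <- function(Fv) {
    sum(stressclip:::sa_forward_batch(sa, Fv, hw, N)$out * dout)
  }
  cache <- stressclip:::sa_forward_batch(sa, Fm, hw, N)
  dF <- stressclip:::sa_backward_batch(sa, Fm, cache, dout, hw, N)
  h <- 1e-6
  for (i in sample(length(Fm), 8)) {
    Fp <- Fm; Fp[i] <- Fp[i] + h
    Fm2 <- Fm; Fm2[i] <- Fm2[i] - h
    expect_equal(dF[i], (loss_of(Fp) - loss_of(Fm2)) / (2 * h),
                 tolerance = 1e-4)
  }
  # kernel gradient too
  dK <- sa$K$g
  loss_of_k <- function(Kv) {
    sa2 <- list(K = stressclip:::new_param(Kv), b = sa$b)
    sum(stressclip:::sa_forward_batch(sa2, Fm, hw, N)$out * dout)
  }
  for (i in sample(98, 4)) {
    Kp <- sa$K$v; Kp[i] <- Kp[i] + h
    Km <- sa$K$v; Km[i] <- Km[i] - h
    expect_equal(dK[i], (loss_of_k(Kp) - loss_of_k(Km)) / (2 * h),
                 tolerance = 1e-4)
  }
})

test_that("batched channel-attention backward matches finite differences", {
  set.seed(7)
  C <- 8; N <- 2; hw <- 16
  ca <- list(fc1 = stressclip:::new_fc(C, 2), fc2 = stressclip:::new_fc(2, C))
  Fm <- matrix(rnorm(hw * N * C), ncol = C)
  dout <- matrix(rnorm(hw * N * C), ncol = C)
  loss_of <- function(Fv) {
    sum(stressclip:::ca_forward_batch(ca, Fv, hw, N)$out * dout)
  }
  cache <- stressclip:::ca_forward_batch(ca, Fm, hw, N)
  dF <- stressclip:::ca_backward_batch(ca, Fm, cache, dout, hw, N)
  h <- 1e-6
  for (i in sample(length(Fm), 8)) {
    Fp <- Fm; Fp[i] <- Fp[i] + h
    Fm2 <- Fm; Fm2[i] <- Fm2[i] - h
    fd <- (loss_of(Fp) - loss_of(Fm2)) / (2 * h)
    expect_equal(dF[i], fd, tolerance = 1e-4)
  }
})

test_that("SGD with momentum follows the reference update rule", {
  p <- stressclip:::new_param(c(1, 2), decay = TRUE)
  p$g <- c(0.5, -0.5)
  stressclip:::sgd_step(list(p), lr = 0.1, momentum = 0.9,
                        weight_decay = 0.01)
  g1 <- c(0.5, -0.5) + 0.01 * c(1, 2)
  v1 <- g1
  expect_equal(p$v, c(1, 2) - 0.1 * v1)
  p$g <- c(0.2, 0.2)
  x1 <- p$v
  stressclip:::sgd_step(list(p), lr = 0.1, momentum = 0.9,
                        weight_decay = 0.01)
  g2 <- c(0.2, 0.2) + 0.01 * x1
  v2 <- 0.9 * v1 + g2
  expect_equal(p$v, x1 - 0.1 * v2)
})
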