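test_that("forward shape trace reproduces every printed output size", {
  bb <- build_backbone(seed = 1)
  tr <- backbone_shape_trace(bb)
  expect_equal(tr$input, c(112, 112, 3))
  expect_equal(tr$conv1, c(56, 56, 64))
  expect_equal(tr$maxpool, c(28, 28, 64))
  expect_equal(tr$stage1, c(28, 28, 64))
  expect_equal(tr$stage2, c(14, 14, 128))
  expect_equal(tr$stage3, c(7, 7, 256))
  expect_equal(tr$stage4, c(4, 4, 512))
  expect_equal(tr$attention, c(4, 4, 1))
  expect_equal(tr$feature, 512)
})

test_that("two builds with the same seed have identical initial parameters", {
  a <- stressclip:::backbone_params(build_backbone(seed = 99))
  b <- stressclip:::backbone_params(build_backbone(seed = 99))
  for (nm in names(a)) expect_identical(a[[nm]]$v, b[[nm]]$v)
  c1 <- stressclip:::backbone_params(build_backbone(seed = 100))
  expect_false(identical(a[["bb.conv1.W"]]$v, c1[["bb.conv1.W"]]$v))
})

test_that("parameter count matches a layer-by-layer arithmetic sum", {
  conv_n <- function(k, cin, cout) k * k * cin * cout + cout + 2 * cout
  expected <-
    conv_n(7, 3, 64) +                                      # stem
    2 * conv_n(3, 64, 64) +                                 # stage 1
    conv_n(3, 64, 128) + conv_n(3, 128, 128) + conv_n(1, 64, 128) +
    conv_n(3, 128, 256) + conv_n(3, 256, 256) + conv_n(1, 128, 256) +
    conv_n(3, 256, 512) + conv_n(3, 512, 512) + conv_n(1, 256, 512) +
    7 * 7 * 2 + 1                                           # attention conv
  expect_equal(count_parameters(build_backbone(seed = 1)), expected)
})

test_that("spatial attention is uniformly 0.5 under zero weights", {
  set.seed(1)
  fmap <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  amap <- spatial_attention(fmap, array(0, c(7, 7, 2)), 0)
  expect_equal(amap, matrix(0.5, 4, 4))
})

test_that("channel-constant feature maps give identical mean and max maps", {
  base <- matrix(runif(16), 4, 4)
  fmap <- array(rep(base, 8), c(4, 4, 8))
  avg <- rowMeans(fmap, dims = 2)
  mx <- apply(fmap, c(1, 2), max)
  expect_equal(avg, mx)
  # with a kernel acting only on the difference of channels, the map is 0.5
  k <- array(0, c(7, 7, 2))
  k[4, 4, 1] <- 3
  k[4, 4, 2] <- -3
  expect_equal(spatial_attention(fmap, k, 0), matrix(0.5, 4, 4))
})

test_that("spatial attention matches a pool-pad-convolve-sigmoid oracle", {
  set.seed(2)
  for (i in 1:5) {
    fmap <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
    kernel <- array(rnorm(98, sd = 0.3), c(7, 7, 2))
    bias <- rnorm(1)
    got <- spatial_attention(fmap, kernel, bias)
    expect_equal(got, oracle_spatial_attention(fmap, kernel, bias),
                 tolerance = 1e-12)
    expect_true(all(got > 0 & got < 1))
  }
})

test_that("attend_and_pool implements GAP(F + M o F)", {
  set.seed(3)
  fmap <- array(rnorm(4 * 4 * 16), c(4, 4, 16))
  gap <- apply(fmap, 3, mean)
  expect_equal(attend_and_pool(fmap, matrix(0, 4, 4)), gap)
  expect_equal(attend_and_pool(fmap, matrix(1, 4, 4)), 2 * gap)
  amap <- matrix(runif(16), 4, 4)
  oracle <- vapply(1:16, function(c) mean(fmap[, , c] * (1 + amap)),
                   numeric(1))
  expect_equal(attend_and_pool(fmap, amap), oracle, tolerance = 1e-12)
})

test_that("attend_and_pool is linear in the feature maps for fixed attention", {
  set.seed(4)
  f1 <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  f2 <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  amap <- matrix(runif(16), 4, 4)
  expect_equal(attend_and_pool(f1 + 2 * f2, amap),
               attend_and_pool(f1, amap) + 2 * attend_and_pool(f2, amap),
               tolerance = 1e-12)
})

test_that("the batched engine attention equals the single-image surface op", {
  set.seed(5)
  C <- 12
  sa <- list(K = stressclip:::new_param(array(rnorm(98, sd = 0.2), c(7, 7, 2))),
             b = stressclip:::new_param(0.1))
  N <- 3
  Fm <- matrix(rnorm(16 * N * C), ncol = C)
  out <- stressclip:::sa_forward_batch(sa, Fm, 16L, N)
  for (n in seq_len(N)) {
    rows <- (n - 1) * 16 + 1:16
    fmap <- array(Fm[rows, ], c(4, 4, C))
    expect_equal(matrix(out$M[rows], 4, 4),
                 spatial_attention(fmap, sa$K$v, sa$b$v), tolerance = 1e-12)
  }
})

test_that("channel attention is 0.5 per channel under zero weights and composes", {
  set.seed(6)
  fmap <- array(rnorm(4 * 4 * 32), c(4, 4, 32))
  w1 <- matrix(0, 2, 32); w2 <- matrix(0, 32, 2)
  expect_equal(channel_attention(fmap, w1, rep(0, 2), w2, rep(0, 32)),
               rep(0.5, 32))
  # all four attention combinations of the backbone are constructible
  for (sa_on in c(TRUE, FALSE)) {
    for (ca_on in c(TRUE, FALSE)) {
      bb <- build_backbone(seed = 2, use_spatial_attention = sa_on,
                           use_channel_attention = ca_on)
      tr <- backbone_shape_trace(bb)
      expect_equal(tr$feature, 512)
    }
  }
})

test_that("gradients reach every trainable parameter of the full model", {
  set.seed(8)
  model <- build_stress_model(model_config(frames_per_clip = 2L, seed = 3L))
  clip <- tiny_clip(frames = 2L)
  fwd <- model_forward(model, list(clip), train = TRUE)
  g <- list(list(dlogits = stressclip:::ce_logit_grad(fwd$scores[1, ], 1L),
                 dffinal = NULL))
  stressclip:::model_backward(model, fwd, g)
  params <- stressclip:::model_params(model)
  expect_gt(length(params), 50)
  for (nm in names(params)) {
    expect_false(is.null(params[[nm]]$g), info = nm)
  }
  # every weight matrix (not biases shadowed by batch norm) gets signal
  heavy <- grep("\\.(W|K|gamma)$", names(params), value = TRUE)
  nonzero <- vapply(heavy, function(nm) any(params[[nm]]$g != 0), logical(1))
  expect_true(all(nonzero))
})
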