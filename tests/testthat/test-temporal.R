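test_that("frame-wise concatenation keeps the facial block first", {
  facial <- matrix(1, 48, 512)
  landmark <- matrix(0, 48, 256)
  cc <- concat_features(facial, landmark)
  expect_equal(dim(cc), c(48, 768))
  expect_true(all(cc[, 1:512] == 1))
  expect_true(all(cc[, 513:768] == 0))
  expect_error(concat_features(matrix(0, 48, 512), matrix(0, 47, 256)),
               "length mismatch")
})

test_that("slicing the concatenation recovers both inputs exactly", {
  set.seed(1)
  facial <- matrix(rnorm(8 * 512), 8)
  landmark <- matrix(rnorm(8 * 256), 8)
  cc <- concat_features(facial, landmark)
  expect_equal(cc[, 1:512], facial)
  expect_equal(cc[, 513:768], landmark)
  # without the landmark branch, concatenation is the identity
  expect_equal(concat_features(facial, NULL), facial)
})

test_that("temporal weights are 0.5 under all-zero layers (sigmoid head)", {
  tm <- build_temporal_module(d_concat = 6, seed = 1)
  for (p in stressclip:::temporal_params(tm)) p$v[] <- 0
  w <- temporal_weights(tm, matrix(rnorm(4 * 6), 4))
  expect_equal(w, rep(0.5, 4))
})

test_that("identical frame features give identical weights", {
  tm <- build_temporal_module(d_concat = 10, seed = 2)
  f <- matrix(rep(rnorm(10), each = 48), 48)
  w <- temporal_weights(tm, f)
  expect_length(w, 48)
  expect_equal(w, rep(w[1], 48))
  expect_true(all(w > 0 & w < 1))
})

test_that("the weight layers match a hand-coded dense-algebra oracle", {
  set.seed(3)
  d <- 6L
  tm <- build_temporal_module(d_concat = d, seed = 3)
  W1 <- matrix(rnorm(144, sd = 0.4), 12)
  b1 <- rnorm(12)
  W2 <- matrix(rnorm(144, sd = 0.4), 12)
  b2 <- rnorm(12)
  w3 <- matrix(rnorm(12, sd = 0.4), 1)
  b3 <- rnorm(1)
  tm$fc1$W$v <- W1; tm$fc1$b$v <- b1
  tm$fc2$W$v <- W2; tm$fc2$b$v <- b2
  tm$fc3$W$v <- w3; tm$fc3$b$v <- b3
  f <- matrix(rnorm(4 * d), 4)

  A <- colMeans(f)
  oracle <- vapply(1:4, function(i) {
    g <- c(f[i, ], A)
    h1 <- pmax(W1 %*% g + b1, 0)
    h2 <- pmax(W2 %*% h1 + b2, 0)
    1 / (1 + exp(-(w3 %*% h2 + b3)))
  }, numeric(1))
  expect_equal(temporal_weights(tm, f), oracle, tolerance = 1e-12)
})

test_that("fusion is the weighted frame average", {
  set.seed(4)
  f <- matrix(rnorm(48 * 16), 48)
  expect_equal(fuse_frames(f, rep(1, 48)), colMeans(f))
  w <- rep(0, 48); w[7] <- 1
  expect_equal(fuse_frames(f, w), f[7, ] / 48)
  wr <- runif(48)
  oracle <- colSums(f * wr) / 48
  expect_equal(fuse_frames(f, wr), oracle, tolerance = 1e-12)
  expect_error(fuse_frames(f, runif(10)), "length mismatch")
})

test_that("classification is softmax of a fully connected layer", {
  tm <- build_temporal_module(d_concat = 8, seed = 5)
  tm$cls$W$v[] <- 0
  tm$cls$b$v[] <- 0
  expect_equal(classify_feature(tm, rnorm(8)), rep(1 / 3, 3))
  set.seed(6)
  W <- matrix(rnorm(24), 3)
  b <- rnorm(3)
  tm$cls$W$v <- W; tm$cls$b$v <- b
  f <- rnorm(8)
  s <- classify_feature(tm, f)
  expect_equal(s, softmax_oracle(as.numeric(W %*% f + b)), tolerance = 1e-12)
  expect_equal(sum(s), 1)
  expect_true(all(s > 0))
})

test_that("permuting frames permutes weights and leaves the fusion invariant", {
  set.seed(7)
  tm <- build_temporal_module(d_concat = 12, seed = 7)
  f <- matrix(rnorm(16 * 12), 16)
  w <- temporal_weights(tm, f)
  ff <- fuse_frames(f, w)
  perm <- sample(16)
  wp <- temporal_weights(tm, f[perm, ])
  expect_equal(wp, w[perm], tolerance = 1e-12)
  expect_equal(fuse_frames(f[perm, ], wp), ff, tolerance = 1e-12)
  expect_equal(classify_feature(tm, fuse_frames(f[perm, ], wp)),
               classify_feature(tm, ff), tolerance = 1e-12)
})

test_that("the landmark-free configuration contracts to 512/1024 dimensions", {
  tm <- build_temporal_module(d_concat = 512, seed = 8)
  expect_equal(dim(tm$fc1$W$v), c(1024, 1024))
  expect_equal(dim(tm$fc3$W$v), c(1, 1024))
  expect_equal(dim(tm$cls$W$v), c(3, 512))
  f <- matrix(rnorm(4 * 512), 4)
  w <- temporal_weights(tm, f)
  expect_length(fuse_frames(f, w), 512)
})

test_that("dimension trace matches the printed module table", {
  tm <- build_temporal_module(seed = 9)
  f <- matrix(rnorm(48 * 768), 48)
  wf <- stressclip:::temporal_weights_fwd(tm, f)
  expect_equal(dim(wf$G), c(48, 1536))    # per-frame total concatenation
  expect_equal(dim(wf$H1), c(48, 1536))
  expect_equal(dim(wf$H2), c(48, 1536))
  expect_length(wf$w, 48)
  ff <- fuse_frames(f, wf$w)
  expect_length(ff, 768)
  expect_length(classify_feature(tm, ff), 3)
})

test_that("the batched multi-clip path equals the per-clip computation", {
  set.seed(11)
  tm <- build_temporal_module(d_concat = 10, seed = 11)
  Ts <- c(3L, 5L, 4L)
  feats <- matrix(rnorm(sum(Ts) * 10), sum(Ts))
  tb <- stressclip:::temporal_forward_batch(tm, feats, Ts, train = TRUE)
  offs <- cumsum(c(0L, Ts))
  for (i in seq_along(Ts)) {
    rows <- offs[i] + seq_len(Ts[i])
    single <- stressclip:::temporal_forward(tm, feats[rows, , drop = FALSE],
                                            train = TRUE)
    expect_equal(tb$w[rows], single$w, tolerance = 1e-12)
    expect_equal(tb$ffinal[i, ], single$ffinal, tolerance = 1e-12)
    expect_equal(tb$scores[i, ], single$scores, tolerance = 1e-12)
  }
  # and the backward pass
  dlogits <- matrix(rnorm(9), 3)
  dextra <- matrix(rnorm(30), 3)
  dfeats <- stressclip:::temporal_backward_batch(tm, tb$cache, dlogits, dextra)
  for (i in seq_along(Ts)) {
    rows <- offs[i] + seq_len(Ts[i])
    single <- stressclip:::temporal_forward(tm, feats[rows, , drop = FALSE],
                                            train = TRUE)
    df <- stressclip:::temporal_backward(tm, single$cache, dlogits[i, ],
                                         dextra[i, ])
    expect_equal(dfeats[rows, ], df, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("a linear weight head is available where no activation is printed", {
  tm <- build_temporal_module(d_concat = 6, weight_head = "linear", seed = 10)
  f <- matrix(rnorm(4 * 6, sd = 3), 4)
  w <- temporal_weights(tm, f)
  expect_length(w, 4)  # unbounded weights are permitted in this mode
})
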