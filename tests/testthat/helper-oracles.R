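# Independent brute-force oracles used across the tests. These deliberately
# share no code with the package implementation.

# direct bilinear resampling, center-aligned, edge-clamped
oracle_bilinear <- function(img, out_h, out_w) {
  in_h <- dim(img)[1]; in_w <- dim(img)[2]
  out <- array(0, c(out_h, out_w, dim(img)[3]))
  for (ch in seq_len(dim(img)[3])) {
    for (i in seq_len(out_h)) {
      for (j in seq_len(out_w)) {
        sy <- min(max((i - 0.5) * in_h / out_h - 0.5, 0), in_h - 1)
        sx <- min(max((j - 0.5) * in_w / out_w - 0.5, 0), in_w - 1)
        y0 <- floor(sy); x0 <- floor(sx)
        y1 <- min(y0 + 1, in_h - 1); x1 <- min(x0 + 1, in_w - 1)
        fy <- sy - y0; fx <- sx - x0
        out[i, j, ch] <-
          img[y0 + 1, x0 + 1, ch] * (1 - fy) * (1 - fx) +
          img[y1 + 1, x0 + 1, ch] * fy * (1 - fx) +
          img[y0 + 1, x1 + 1, ch] * (1 - fy) * fx +
          img[y1 + 1, x1 + 1, ch] * fy * fx
      }
    }
  }
  out
}

# direct 2-D Gaussian convolution with symmetric (edge-repeating) reflection,
# then max-rescaling -- the blur contract
oracle_gaussian_blur <- function(img, sigma) {
  r <- ceiling(4 * sigma)
  k1 <- exp(-((-r:r)^2) / (2 * sigma^2))
  k2 <- outer(k1, k1)
  k2 <- k2 / sum(k2)
  n <- nrow(img); m <- ncol(img)
  reflect <- function(i, n) {
    i <- ifelse(i < 1, 1 - i, i)
    ifelse(i > n, 2 * n + 1 - i, i)
  }
  out <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      acc <- 0
      for (di in -r:r) {
        for (dj in -r:r) {
          acc <- acc + k2[di + r + 1, dj + r + 1] *
            img[reflect(i + di, n), reflect(j + dj, m)]
        }
      }
      out[i, j] <- acc
    }
  }
  if (max(out) > 0) out <- out / max(out)
  out
}

# brute-force spatial attention: pool -> zero-pad -> convolve -> sigmoid
oracle_spatial_attention <- function(fmap, kernel, bias) {
  h <- dim(fmap)[1]; w <- dim(fmap)[2]
  avg <- apply(fmap, c(1, 2), mean)
  mx <- apply(fmap, c(1, 2), max)
  kh <- dim(kernel)[1]; kw <- dim(kernel)[2]
  ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2
  pad <- function(m) {
    p <- matrix(0, h + 2 * ph, w + 2 * pw)
    p[ph + seq_len(h), pw + seq_len(w)] <- m
    p
  }
  pa <- pad(avg); pm <- pad(mx)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      acc <- bias
      for (di in seq_len(kh)) {
        for (dj in seq_len(kw)) {
          acc <- acc + pa[i + di - 1, j + dj - 1] * kernel[di, dj, 1] +
                       pm[i + di - 1, j + dj - 1] * kernel[di, dj, 2]
        }
      }
      out[i, j] <- 1 / (1 + exp(-acc))
    }
  }
  out
}

# direct strided valid/zero-padded convolution on the engine layout,
# one image, double precision
oracle_conv2d <- function(X, H, W, Wt, b, kh, kw, stride, pad) {
  Cin <- ncol(X); Cout <- ncol(Wt)
  Ho <- (H + 2 * pad - kh) %/% stride + 1
  Wo <- (W + 2 * pad - kw) %/% stride + 1
  Y <- matrix(0, Ho * Wo, Cout)
  for (co in seq_len(Cout)) {
    for (oc in 0:(Wo - 1)) {
      for (or in 0:(Ho - 1)) {
        acc <- b[co]
        for (ci in 0:(Cin - 1)) {
          for (dc in 0:(kw - 1)) {
            for (dr in 0:(kh - 1)) {
              r <- or * stride - pad + dr
              c <- oc * stride - pad + dc
              if (r >= 0 && r < H && c >= 0 && c < W) {
                acc <- acc + X[r + c * H + 1, ci + 1] *
                  Wt[dr + dc * kh + ci * kh * kw + 1, co]
              }
            }
          }
        }
        Y[or + oc * Ho + 1, co] <- acc
      }
    }
  }
  Y
}

# macro one-vs-rest sensitivity/specificity from a confusion matrix
oracle_macro_sens_spec <- function(conf) {
  k <- nrow(conf)
  sens <- spec <- numeric(k)
  for (c in seq_len(k)) {
    tp <- conf[c, c]
    fn <- sum(conf[c, -c])
    fp <- sum(conf[-c, c])
    tn <- sum(conf[-c, -c])
    sens[c] <- tp / (tp + fn)
    spec[c] <- tn / (tn + fp)
  }
  c(sensitivity = 100 * mean(sens), specificity = 100 * mean(spec))
}

softmax_oracle <- function(z) exp(z) / sum(exp(z))

# random 68-point landmark set inside a canvas
random_landmarks <- function(canvas = 112, margin = 6) {
  cbind(runif(68, margin, canvas - 1 - margin),
        runif(68, margin, canvas - 1 - margin))
}

# tiny clip for structural tests (content irrelevant)
tiny_clip <- function(subject = "S01", video = "v1", label = "neutral",
                      frames = 2L) {
  arr <- array(runif(112 * 112 * 3 * frames), c(112, 112, 3, frames))
  lms <- replicate(frames, random_landmarks(), simplify = FALSE)
  new_clip(arr, lms, subject, video, label)
}
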