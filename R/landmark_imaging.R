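# Facial-landmark image preprocessing: min-max normalization, dot
# rendering, Gaussian blurring. Face detectors jitter frame to frame: the
# face box (hence every landmark) shifts by a common offset, and each
# detected point carries its own noise. Min-max normalization cancels the
# common shift/scale by re-spanning the canvas; blurring spreads each dot
# so residual per-point jitter changes the image only gradually.

N_LANDMARKS <- 68L

validate_landmarks <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) != N_LANDMARKS || ncol(points) != 2) {
    stop("invalid landmarks: expected a ", N_LANDMARKS,
         " x 2 matrix of (x, y) coordinates")
  }
  if (!all(is.finite(points))) stop("invalid landmarks: non-finite coordinates")
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y")
  points
}

#' Min-max normalize a landmark set onto the canvas
#'
#' Per-axis affine map sending the observed coordinate range `[min, max]`
#' to `[margin_px, canvas - 1 - margin_px]`, so every frame's landmarks
#' span the canvas identically regardless of where (and at what scale) the
#' face box landed. A degenerate axis (`max == min`) is mapped to the
#' canvas center. With `joint = TRUE` a single scale (the smaller of the
#' two axis scales) is used for both axes, preserving the aspect ratio,
#' and the result is centered.
#'
#' The operation is idempotent: normalized landmarks already span the
#' target range and map to themselves.
#'
#' @param points 68 x 2 matrix of (x, y) pixel coordinates.
#' @param canvas canvas side length in pixels (default 112).
#' @param margin_px margin kept free on every side (default 4), so blurred
#'   dot mass stays on-canvas.
#' @param joint logical; aspect-preserving joint normalization.
#' @return 68 x 2 matrix of normalized coordinates.
#' @export
minmax_normalize <- function(points, canvas = 112L, margin_px = 4L,
                             joint = FALSE) {
  points <- validate_landmarks(points)
  stopifnot(canvas > 2 * margin_px)
  lo <- margin_px
  hi <- canvas - 1 - margin_px
  mins <- apply(points, 2, min)
  maxs <- apply(points, 2, max)
  rng <- maxs - mins
  if (joint) {
    scale <- if (max(rng) == 0) 0 else (hi - lo) / max(rng)
    out <- sweep(points, 2, mins) * scale
    # center each axis inside [lo, hi]
    out <- sweep(out, 2, (hi - lo - rng * scale) / 2 + lo, `+`)
  } else {
    out <- points
    for (ax in 1:2) {
      if (rng[ax] == 0) {
        out[, ax] <- (canvas - 1) / 2
      } else {
        out[, ax] <- (points[, ax] - mins[ax]) * (hi - lo) / rng[ax] + lo
      }
    }
  }
  out
}

#' Render a landmark set as white dots on a black canvas
#'
#' Each landmark becomes a single pixel of value 1.0 at its rounded
#' coordinate on a zero background; coincident rounded positions collapse
#' to one dot. Coordinates are 0-based with x = column, y = row.
#'
#' @param points 68 x 2 matrix of (x, y) coordinates inside the canvas.
#' @param canvas canvas side length in pixels.
#' @return `canvas x canvas` matrix in \{0, 1\}.
#' @export
render_landmark_image <- function(points, canvas = 112L) {
  points <- validate_landmarks(points)
  px <- floor(points + 0.5)
  px[, 1] <- pmin(pmax(px[, 1], 0), canvas - 1)
  px[, 2] <- pmin(pmax(px[, 2], 0), canvas - 1)
  img <- matrix(0, canvas, canvas)
  img[cbind(px[, 2] + 1, px[, 1] + 1)] <- 1
  img
}

#' Gaussian-blur a landmark image
#'
#' Discrete Gaussian convolution (separable, kernel truncated at 4 sigma,
#' symmetric edge reflection) followed by rescaling so the brightest pixel
#' is exactly 1.0. An all-zero image stays all-zero.
#'
#' @param image numeric matrix (the rendered landmark image).
#' @param sigma_px Gaussian standard deviation in pixels (> 0, default 2).
#' @return blurred matrix with maximum 1 (or all zeros).
#' @export
gaussian_blur <- function(image, sigma_px = 2) {
  if (!is.numeric(sigma_px) || length(sigma_px) != 1 || sigma_px <= 0) {
    stop("invalid parameter: sigma_px must be a positive number")
  }
  image <- as.matrix(image)
  r <- ceiling(4 * sigma_px)
  k <- exp(-((-r:r)^2) / (2 * sigma_px^2))
  k <- k / sum(k)
  out <- blur_1d(blur_1d(image, k, r, rows = TRUE), k, r, rows = FALSE)
  mx <- max(out)
  if (mx > 0) out <- out / mx
  out
}

# separable 1-D pass with symmetric (edge-including) reflection
blur_1d <- function(img, k, r, rows) {
  n <- if (rows) nrow(img) else ncol(img)
  idx <- seq_len(n)
  acc <- 0
  for (d in -r:r) {
    j <- idx + d
    j <- ifelse(j < 1, 1 - j, j)        # reflect below: 0 -> 1, -1 -> 2
    j <- ifelse(j > n, 2 * n + 1 - j, j) # reflect above: n+1 -> n
    acc <- acc + k[d + r + 1] * (if (rows) img[j, , drop = FALSE]
                                 else img[, j, drop = FALSE])
  }
  acc
}

#' Full landmark-image preprocessing pipeline
#'
#' Normalize (optional), render, blur (optional) -- producing the
#' single-channel landmark image consumed by the landmark CNN. With both
#' steps enabled the result is invariant to translating or rescaling the
#' raw landmark coordinates, which is exactly the face-box jitter the
#' preprocessing is designed to cancel.
#'
#' @inheritParams minmax_normalize
#' @inheritParams gaussian_blur
#' @param normalize,blur logical toggles (the preprocessing ablation).
#' @return `canvas x canvas` landmark image in `[0, 1]`.
#' @export
landmark_image_pipeline <- function(points, canvas = 112L, margin_px = 4L,
                                    sigma_px = 2, normalize = TRUE,
                                    blur = TRUE, joint = FALSE) {
  points <- validate_landmarks(points)
  if (normalize) {
    points <- minmax_normalize(points, canvas, margin_px, joint = joint)
  }
  img <- render_landmark_image(points, canvas)
  if (blur) img <- gaussian_blur(img, sigma_px)
  img
}
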