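# Seedable synthetic clip generator. Emulates the statistical structure the
# recognition method assumes: three balanced stress classes, per-subject
# appearance variation, a class-dependent localized intensity patch
# (spatial cue, visible to the spatial attention), cue presence in only a
# class-dependent fraction of frames (temporal cue, visible to the temporal
# attention), class-dependent landmark displacement on cue frames (signal
# for the landmark branch), and detector-style landmark jitter: a common
# per-frame offset (face-box jitter) plus i.i.d. per-point noise.
#
# Faces are procedural blob composites, not rendered humans: the networks
# consume pixel statistics, and procedural cues give controllable ground
# truth for attention localization tests.

#' Specification for a synthetic clip dataset
#'
#' @param n_subjects number of subjects (the reference study uses 50).
#' @param clips_per_subject_per_class clips per subject and class.
#' @param frames_per_clip frames per clip (default 48, i.e. 2 s at 24 fps).
#' @param image_size frame side length in pixels (default 112).
#' @param cue_cells integer 3-vector: the 3x3 grid cell (1-9, row-major)
#'   carrying each class's intensity patch (neutral, low, high).
#' @param cue_amplitude patch amplitude in intensity units (0-1).
#' @param cue_fraction numeric 3-vector: per-class fraction of frames
#'   carrying the cue.
#' @param landmark_cue_px numeric 3-vector: mouth-landmark displacement in
#'   pixels on cue frames, per class.
#' @param landmark_jitter_sd detector-jitter scale in pixels: the sd of the
#'   per-frame common landmark offset and of the per-point noise.
#' @param appearance_sd per-subject base-face variation (intensity units
#'   for the blob field; also scales subject landmark-template deformation).
#' @param seed master seed; all randomness flows from it through named
#'   substreams (appearance, cue, jitter, pixel).
#' @return a `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects = 50L,
                           clips_per_subject_per_class = 4L,
                           frames_per_clip = 48L,
                           image_size = 112L,
                           cue_cells = c(1L, 3L, 7L),
                           cue_amplitude = 0.6,
                           cue_fraction = c(0.3, 0.6, 0.9),
                           landmark_cue_px = c(1, 2.5, 4),
                           landmark_jitter_sd = 1,
                           appearance_sd = 0.05,
                           seed = 1L) {
  stopifnot(n_subjects >= 1, clips_per_subject_per_class >= 1,
            frames_per_clip >= 1, image_size >= 32,
            length(cue_cells) == 3, all(cue_cells %in% 1:9),
            length(unique(cue_cells)) == 3,
            cue_amplitude >= 0, cue_amplitude <= 1,
            length(cue_fraction) == 3, all(cue_fraction >= 0),
            all(cue_fraction <= 1), landmark_jitter_sd >= 0,
            appearance_sd >= 0)
  spec <- list(
    n_subjects = as.integer(n_subjects),
    clips_per_subject_per_class = as.integer(clips_per_subject_per_class),
    frames_per_clip = as.integer(frames_per_clip),
    image_size = as.integer(image_size),
    cue_cells = as.integer(cue_cells),
    cue_amplitude = cue_amplitude,
    cue_fraction = cue_fraction,
    landmark_cue_px = landmark_cue_px,
    landmark_jitter_sd = landmark_jitter_sd,
    appearance_sd = appearance_sd,
    seed = as.integer(seed)
  )
  class(spec) <- "synthetic_spec"
  spec
}

# center (x, y) of a 3x3 grid cell, row-major indexing
grid_cell_center <- function(cell, size) {
  w <- size / 3
  row <- (cell - 1L) %/% 3L
  col <- (cell - 1L) %% 3L
  c(x = (col + 0.5) * w, y = (row + 0.5) * w)
}

# 68-point neutral landmark template on a `size` canvas
landmark_template <- function(size = 112) {
  s <- size / 112
  ell <- function(n, cx, cy, rx, ry, from, to) {
    phi <- seq(from, to, length.out = n) * pi / 180
    cbind(cx + rx * cos(phi), cy - ry * sin(phi))
  }
  jaw <- ell(17, 56, 50, 36, 44, 180, 360)
  brow_l <- cbind(seq(26, 46, length.out = 5), 30 - c(0, 2, 3, 2, 0))
  brow_r <- cbind(seq(66, 86, length.out = 5), 30 - c(0, 2, 3, 2, 0))
  nose_bridge <- cbind(rep(56, 4), seq(38, 54, length.out = 4))
  nostrils <- cbind(seq(48, 64, length.out = 5), 58 + c(0, 1.5, 2, 1.5, 0))
  eye_l <- ell(6, 36, 38, 7, 3, 0, 300)
  eye_r <- ell(6, 76, 38, 7, 3, 0, 300)
  mouth_out <- ell(12, 56, 72, 16, 8, 0, 330)
  mouth_in <- ell(8, 56, 72, 10, 4, 0, 315)
  pts <- rbind(jaw, brow_l, brow_r, nose_bridge, nostrils, eye_l, eye_r,
               mouth_out, mouth_in) * s
  colnames(pts) <- c("x", "y")
  pts
}

MOUTH_IDX <- 49:68

# gaussian bump on a size x size canvas
bump <- function(size, cx, cy, sx, sy, amp) {
  gx <- exp(-((seq_len(size) - 1 - cx)^2) / (2 * sx^2))
  gy <- exp(-((seq_len(size) - 1 - cy)^2) / (2 * sy^2))
  amp * (gy %o% gx)
}

# per-subject base face and deformed landmark template (appearance stream)
subject_appearance <- function(spec, subject) {
  size <- spec$image_size
  with_seed(substream_seed(spec$seed, paste0("appearance/", subject)), {
    s <- size / 112
    face <- matrix(0.15, size, size) +
      bump(size, 56 * s, 54 * s, 30 * s, 38 * s, 0.5) -
      bump(size, 36 * s, 38 * s, 6 * s, 3.5 * s, 0.25) -
      bump(size, 76 * s, 38 * s, 6 * s, 3.5 * s, 0.25) -
      bump(size, 56 * s, 72 * s, 12 * s, 5 * s, 0.2)
    for (k in 1:6) {
      face <- face + bump(size, runif(1, 0.2, 0.8) * size,
                          runif(1, 0.2, 0.8) * size,
                          runif(1, 4, 14) * s, runif(1, 4, 14) * s,
                          rnorm(1, 0, spec$appearance_sd))
    }
    tint <- 1 + rnorm(3, 0, spec$appearance_sd)
    scale <- rnorm(1, 1, spec$appearance_sd)
    offset <- rnorm(2, 0, 20 * spec$appearance_sd)
    tmpl <- landmark_template(size)
    ctr <- colMeans(tmpl)
    pts <- sweep(tmpl, 2, ctr) * scale
    pts <- sweep(pts, 2, ctr + offset, `+`) +
      matrix(rnorm(2 * nrow(tmpl), 0, 10 * spec$appearance_sd), ncol = 2)
    list(face = face, tint = tint, landmarks = pts)
  })
}

#' Generate a synthetic clip dataset
#'
#' Deterministic for a fixed spec (same spec + seed gives bit-identical
#' output). Each clip records which frames carry the class cue in
#' `meta$cue_frames`, so attention-localization tests have ground truth.
#'
#' @param spec a [synthetic_spec()].
#' @return a `synthetic_dataset`: list with `clips` (list of [new_clip()]),
#'   `manifest` (one row per clip: subject_id, video_id, label, clip) and
#'   the `spec`.
#' @export
generate_clips <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  size <- spec$image_size
  classes <- CLASS_LEVELS
  clips <- list()
  rows <- list()
  for (si in seq_len(spec$n_subjects)) {
    subject <- sprintf("S%02d", si)
    app <- subject_appearance(spec, subject)
    for (ci in seq_along(classes)) {
      label <- classes[ci]
      video_id <- paste0(subject, "_", label)
      cell <- grid_cell_center(spec$cue_cells[ci], size)
      for (k in seq_len(spec$clips_per_subject_per_class)) {
        tag <- paste0(subject, "/", label, "/", k)
        Tn <- spec$frames_per_clip
        cue <- with_seed(substream_seed(spec$seed, paste0("cue/", tag)),
                         runif(Tn) < spec$cue_fraction[ci])
        jit <- with_seed(substream_seed(spec$seed, paste0("jitter/", tag)), {
          list(common = matrix(rnorm(2 * Tn, 0, spec$landmark_jitter_sd),
                               ncol = 2),
               point = array(rnorm(2 * N_LANDMARKS * Tn, 0,
                                   spec$landmark_jitter_sd),
                             c(N_LANDMARKS, 2, Tn)))
        })
        pix <- with_seed(substream_seed(spec$seed, paste0("pixel/", tag)),
                         array(rnorm(size * size * Tn, 0, 0.01),
                               c(size, size, Tn)))
        frames <- array(0, c(size, size, 3, Tn))
        landmarks <- vector("list", Tn)
        patch <- bump(size, cell["x"], cell["y"], 6 * size / 112,
                      6 * size / 112, spec$cue_amplitude)
        for (t in seq_len(Tn)) {
          img <- app$face + pix[, , t]
          if (cue[t]) img <- img + patch
          for (ch in 1:3) {
            frames[, , ch, t] <- pmin(pmax(img * app$tint[ch], 0), 1)
          }
          pts <- app$landmarks
          # scripted motion: gentle head sway, identical for every subject
          sway <- c(1.5 * sin(2 * pi * t / Tn), 0.8 * cos(2 * pi * t / Tn))
          pts <- sweep(pts, 2, sway, `+`)
          if (cue[t]) {
            pts[MOUTH_IDX, 2] <- pts[MOUTH_IDX, 2] + spec$landmark_cue_px[ci]
          }
          pts <- sweep(pts, 2, jit$common[t, ], `+`) + jit$point[, , t]
          landmarks[[t]] <- pts
        }
        clips[[length(clips) + 1L]] <- new_clip(
          frames, landmarks, subject, video_id, label,
          meta = list(cue_frames = cue, cue_cell = spec$cue_cells[ci]))
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = subject, video_id = video_id, label = label,
          clip = length(clips), stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(clips = clips, manifest = do.call(rbind, rows), spec = spec),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d clips (%d subjects x 3 classes x %d), %d frames of %dx%d\n",
    length(x$clips), x$spec$n_subjects, x$spec$clips_per_subject_per_class,
    x$spec$frames_per_clip, x$spec$image_size, x$spec$image_size))
  invisible(x)
}

#' The worked example fixture
#'
#' A tiny fixed dataset -- 3 subjects x 3 classes x 2 clips of 8 frames --
#' used throughout the tests and documentation. Deterministic; its landmark
#' tracks are also shipped as CSV fixtures under
#' `inst/extdata/worked_fixture/`.
#'
#' @return a `synthetic_dataset`.
#' @export
make_worked_fixture <- function() {
  generate_clips(synthetic_spec(
    n_subjects = 3L, clips_per_subject_per_class = 2L, frames_per_clip = 8L,
    seed = 424242L))
}

#' Write a synthetic dataset in the manifest + frame-directory layout
#'
#' Produces the on-disk layout the clip reader consumes: `manifest.csv`
#' (one row per video), one PNG frame directory per video, and one landmark
#' CSV per video.
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory.
#' @return the manifest data frame, invisibly.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vids <- unique(ds$manifest$video_id)
  rows <- lapply(vids, function(v) {
    sel <- which(ds$manifest$video_id == v)
    vdir <- file.path(dir, "videos", v)
    dir.create(vdir, recursive = TRUE, showWarnings = FALSE)
    lms <- list()
    n <- 0L
    for (i in sel) {
      cl <- ds$clips[[i]]
      for (t in seq_len(n_frames(cl))) {
        n <- n + 1L
        png::writePNG(cl$frames[, , , t],
                      file.path(vdir, sprintf("frame_%05d.png", n)))
      }
      lms <- c(lms, cl$landmarks)
    }
    lm_path <- file.path(dir, "landmarks", paste0(v, ".csv"))
    dir.create(dirname(lm_path), recursive = TRUE, showWarnings = FALSE)
    write_landmark_csv(lms, lm_path)
    data.frame(subject_id = ds$clips[[sel[1]]]$subject_id, video_id = v,
               label = ds$clips[[sel[1]]]$label, path = vdir,
               landmarks = lm_path, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}
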