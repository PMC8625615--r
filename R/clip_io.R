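# Clip construction: face-box cropping with bilinear resizing, fixed-length
# segmentation of frame sequences, random frame subsampling for long clips,
# and the on-disk manifest / clip-store formats.

#' Face bounding box
#'
#' 0-based, half-open pixel box `[x0, x1) x [y0, y1)`.
#'
#' @param x0,y0,x1,y1 box corners in pixels.
#' @return a `face_box`.
#' @export
face_box <- function(x0, y0, x1, y1) {
  stopifnot(x1 > x0, y1 > y0)
  structure(list(x0 = x0, y0 = y0, x1 = x1, y1 = y1), class = "face_box")
}

#' Crop a face box out of a frame and resize it
#'
#' The box is clamped to the frame bounds and the cropped region is
#' resampled to `out_size x out_size` with center-aligned bilinear
#' interpolation (output pixel centers map to `(i + 0.5) * scale - 0.5` in
#' crop coordinates, edge-clamped). Intensities stay within the range of
#' the input crop.
#'
#' @param frame numeric array `H x W x 3` with intensities in `[0, 1]`.
#' @param box a [face_box()].
#' @param out_size output side length (>= 2, default 112).
#' @return `out_size x out_size x 3` array.
#' @export
crop_and_resize_face <- function(frame, box, out_size = 112L) {
  stopifnot(length(dim(frame)) == 3, out_size >= 2)
  H <- dim(frame)[1]; W <- dim(frame)[2]
  x0 <- max(0, floor(box$x0)); y0 <- max(0, floor(box$y0))
  x1 <- min(W, ceiling(box$x1)); y1 <- min(H, ceiling(box$y1))
  if (x1 <= x0 || y1 <= y0) {
    stop("invalid box: no intersection with the frame")
  }
  crop <- frame[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE]
  bilinear_resize(crop, out_size, out_size)
}

# center-aligned bilinear resampling via row/column interpolation matrices
bilinear_resize <- function(img, out_h, out_w) {
  interp_matrix <- function(n_out, n_in) {
    scale <- n_in / n_out
    src <- (seq_len(n_out) - 0.5) * scale - 0.5
    src <- pmin(pmax(src, 0), n_in - 1)
    lo <- floor(src)
    frac <- src - lo
    hi <- pmin(lo + 1, n_in - 1)
    Mt <- matrix(0, n_out, n_in)
    Mt[cbind(seq_len(n_out), lo + 1)] <- 1 - frac
    Mt[cbind(seq_len(n_out), hi + 1)] <-
      Mt[cbind(seq_len(n_out), hi + 1)] + frac
    Mt
  }
  Ry <- interp_matrix(out_h, dim(img)[1])
  Rx <- interp_matrix(out_w, dim(img)[2])
  out <- array(0, c(out_h, out_w, dim(img)[3]))
  for (ch in seq_len(dim(img)[3])) {
    out[, , ch] <- Ry %*% img[, , ch] %*% t(Rx)
  }
  out
}

#' Construct a clip
#'
#' @param frames `112 x 112 x 3 x T` array of face crops (values in `[0, 1]`).
#' @param landmarks list of `T` landmark matrices (68 x 2), or NULL.
#' @param subject_id,video_id identifiers.
#' @param label one of `"neutral"`, `"low"`, `"high"`.
#' @param frame_idx optional integer source-frame indices.
#' @param meta optional list of extra metadata.
#' @return a `clip` object.
#' @export
new_clip <- function(frames, landmarks, subject_id, video_id, label,
                     frame_idx = NULL, meta = list()) {
  stopifnot(length(dim(frames)) == 4)
  label <- match.arg(label, CLASS_LEVELS)
  Tn <- dim(frames)[4]
  if (!is.null(landmarks) && length(landmarks) != Tn) {
    stop("landmarks and frames differ in length")
  }
  structure(list(
    frames = frames, landmarks = landmarks,
    subject_id = as.character(subject_id), video_id = as.character(video_id),
    label = label,
    frame_idx = if (is.null(frame_idx)) seq_len(Tn) else as.integer(frame_idx),
    meta = meta
  ), class = "clip")
}

#' @export
print.clip <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<clip> subject %s video %s label %s: %d frames of %dx%dx%d\n",
              x$subject_id, x$video_id, x$label, d[4], d[1], d[2], d[3]))
  invisible(x)
}

n_frames <- function(clip) dim(clip$frames)[4]

#' Segment a frame sequence into fixed-length clips
#'
#' Consecutive non-overlapping blocks of `frames_per_clip` frames; the
#' trailing remainder of a video is discarded. Fewer frames than one clip
#' yields an empty list, not an error.
#'
#' @param frames `H x W x 3 x n` array of face crops in time order.
#' @param fps frames per second of the source video (> 0).
#' @param clip_seconds clip length in seconds (default 2).
#' @param frames_per_clip frames per clip; defaults to
#'   `round(fps * clip_seconds)` (48 at 24 fps and 2 s).
#' @param landmarks optional list of per-frame landmark matrices.
#' @param subject_id,video_id,label metadata inherited by every clip.
#' @return list of [new_clip()] objects.
#' @export
segment_video <- function(frames, fps = 24, clip_seconds = 2,
                          frames_per_clip = NULL, landmarks = NULL,
                          subject_id = "s", video_id = "v",
                          label = "neutral") {
  stopifnot(fps > 0, length(dim(frames)) == 4)
  if (is.null(frames_per_clip)) frames_per_clip <- round(fps * clip_seconds)
  n <- dim(frames)[4]
  n_clips <- n %/% frames_per_clip
  if (n_clips == 0) {
    message("segment_video: ", n, " frames < ", frames_per_clip,
            " per clip; no clips produced")
    return(list())
  }
  lapply(seq_len(n_clips), function(k) {
    sel <- (k - 1L) * frames_per_clip + seq_len(frames_per_clip)
    new_clip(frames[, , , sel, drop = FALSE],
             if (!is.null(landmarks)) landmarks[sel],
             subject_id, video_id, label, frame_idx = sel)
  })
}

#' Randomly subsample a frame sequence to a target length
#'
#' A uniformly random duplicate-free subset of frame indices, re-sorted
#' into temporal order; deterministic for a fixed seed. Used to reduce
#' clips longer than the reference length to the standard frame count.
#'
#' @param n_frames number of available frames (or a vector/array whose
#'   length along time defines it -- see `value`).
#' @param target number of frames to keep (<= `n_frames`).
#' @param seed optional integer seed.
#' @return strictly increasing integer vector of `target` frame indices.
#' @export
subsample_frames <- function(n_frames, target, seed = NULL) {
  stopifnot(target >= 1)
  if (n_frames < target) {
    stop("insufficient frames: ", n_frames, " < ", target)
  }
  if (n_frames == target) return(seq_len(n_frames))
  draw <- function() sort(sample.int(n_frames, target))
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# ---- face-box providers ---------------------------------------------------

#' Face-box providers
#'
#' A provider is a function `(frame, frame_index) -> face_box` standing in
#' for a face detector. `full_frame_provider()` returns the whole frame
#' (for pre-cropped data); `fixture_box_provider(boxes)` replays boxes from
#' a data frame with columns `frame`, `x0`, `y0`, `x1`, `y1` (e.g. a
#' detector's cached output).
#'
#' @param boxes data frame of per-frame boxes.
#' @return a provider function.
#' @export
full_frame_provider <- function() {
  function(frame, frame_index) {
    face_box(0, 0, dim(frame)[2], dim(frame)[1])
  }
}

#' @rdname full_frame_provider
#' @export
fixture_box_provider <- function(boxes) {
  stopifnot(all(c("frame", "x0", "y0", "x1", "y1") %in% names(boxes)))
  function(frame, frame_index) {
    row <- boxes[boxes$frame == frame_index, ]
    if (nrow(row) == 0) stop("no box for frame ", frame_index)
    face_box(row$x0[1], row$y0[1], row$x1[1], row$y1[1])
  }
}

# ---- manifests and on-disk layout ----------------------------------------

#' Read or write a dataset manifest
#'
#' The manifest is a CSV with one row per video: `subject_id`, `video_id`,
#' `label`, `path` (frames directory), and optionally `landmarks` (a
#' per-video landmark CSV).
#'
#' @param path CSV file path.
#' @param manifest data frame to write.
#' @return `read_manifest()` returns the manifest data frame.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("subject_id", "video_id", "label", "path") %in% names(m)))
  m
}

#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a directory of frames (PNG, lexicographic order)
#'
#' @param dir directory containing frame images.
#' @return `H x W x 3 x n` array of frames in `[0, 1]`.
#' @export
read_frames_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("no PNG frames in ", dir)
  imgs <- lapply(files, function(f) {
    x <- png::readPNG(f)
    if (length(dim(x)) == 2) x <- array(rep(x, 3), c(dim(x), 3))
    x[, , 1:3, drop = FALSE]
  })
  array(unlist(imgs), c(dim(imgs[[1]]), length(imgs)))
}

#' Read per-video landmark tracks
#'
#' One row per frame, 136 coordinate columns (`x1..x68`, `y1..y68`) plus an
#' optional leading `frame` column.
#'
#' @param path landmark CSV path.
#' @return list of 68 x 2 landmark matrices, one per frame.
#' @export
read_landmark_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  xcols <- paste0("x", seq_len(N_LANDMARKS))
  ycols <- paste0("y", seq_len(N_LANDMARKS))
  stopifnot(all(c(xcols, ycols) %in% names(d)))
  lapply(seq_len(nrow(d)), function(i) {
    validate_landmarks(cbind(as.numeric(d[i, xcols]), as.numeric(d[i, ycols])))
  })
}

#' @rdname read_landmark_csv
#' @param landmarks list of 68 x 2 matrices to write.
#' @param digits coordinate precision written to disk.
#' @export
write_landmark_csv <- function(landmarks, path, digits = 2) {
  rows <- t(vapply(landmarks, function(p) {
    round(c(p[, 1], p[, 2]), digits)
  }, numeric(2 * N_LANDMARKS)))
  colnames(rows) <- c(paste0("x", seq_len(N_LANDMARKS)),
                      paste0("y", seq_len(N_LANDMARKS)))
  write.csv(cbind(frame = seq_len(nrow(rows)), as.data.frame(rows)), path,
            row.names = FALSE)
  invisible(path)
}

#' Write / read a clip store
#'
#' One directory per clip holding the frames as PNG plus a JSON sidecar
#' with subject, video, label and source-frame indices (and a landmark CSV
#' when landmarks are attached).
#'
#' @param clips list of [new_clip()] objects.
#' @param dir store directory.
#' @return `read_clip_store()` returns the list of clips.
#' @export
write_clip_store <- function(clips, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(clips)) {
    cl <- clips[[i]]
    cdir <- file.path(dir, sprintf("clip_%05d", i))
    dir.create(cdir, showWarnings = FALSE)
    for (k in seq_len(n_frames(cl))) {
      png::writePNG(cl$frames[, , , k],
                    file.path(cdir, sprintf("frame_%04d.png", k)))
    }
    if (!is.null(cl$landmarks)) {
      write_landmark_csv(cl$landmarks, file.path(cdir, "landmarks.csv"))
    }
    jsonlite::write_json(
      list(subject_id = cl$subject_id, video_id = cl$video_id,
           label = cl$label, frame_idx = cl$frame_idx),
      file.path(cdir, "clip.json"), auto_unbox = TRUE)
  }
  invisible(dir)
}

#' @rdname write_clip_store
#' @export
read_clip_store <- function(dir) {
  cdirs <- sort(list.dirs(dir, recursive = FALSE))
  lapply(cdirs, function(cdir) {
    meta <- jsonlite::read_json(file.path(cdir, "clip.json"),
                                simplifyVector = TRUE)
    frames <- read_frames_dir(cdir)
    lm_path <- file.path(cdir, "landmarks.csv")
    lms <- if (file.exists(lm_path)) read_landmark_csv(lm_path)
    new_clip(frames, lms, meta$subject_id, meta$video_id, meta$label,
             frame_idx = meta$frame_idx)
  })
}
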