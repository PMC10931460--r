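# Synthetic face-video generator.
#
# Every other module is trainable and testable on these frames without any
# external corpus.  A latent BDI-II severity in [0, 63] controls two facial
# cues by fixed affine maps (so monotonicity is exact and testable):
# mouth curvature (smiling decreases with severity) and eye openness
# (narrowing eyes with severity).  Frames carry exact ground-truth face
# boxes and the five landmarks (eyes, nose tip, mouth corners).

# severity -> signed mouth curvature (positive = smile)
severity_to_curvature <- function(severity) 0.35 - 0.7 * severity / 63

# severity -> eye openness in (0, 1]
severity_to_openness <- function(severity) 1 - 0.75 * severity / 63

#' Specification of one synthetic face
#'
#' @param severity BDI-II severity in `[0, 63]`.
#' @param center_xy face centre `c(x, y)` in 0-based pixel coordinates.
#' @param face_scale face width in pixels.
#' @param noise_sigma standard deviation of additive Gaussian intensity
#'   noise (image is clipped back to `[0, 1]`).
#' @param seed integer seed; the rendered frame is a pure function of the
#'   spec including this seed.
#' @return Object of class `"face_spec"` with derived `mouth_curvature`
#'   (strictly decreasing in severity) and `eye_openness` (strictly
#'   decreasing, in `(0, 1]`).
#' @export
face_spec <- function(severity, center_xy = c(32, 32), face_scale = 36,
                      noise_sigma = 0.02, seed = 1L) {
  if (!is.finite(severity) || severity < 0 || severity > 63)
    stop("severity must lie in [0, 63] (BDI-II range)")
  if (face_scale <= 4) stop("face_scale too small")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(severity = severity,
                 mouth_curvature = severity_to_curvature(severity),
                 eye_openness = severity_to_openness(severity),
                 center_xy = center_xy,
                 face_scale = face_scale,
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "face_spec")
}

#' Render one synthetic face frame with ground truth
#'
#' Draws an elliptical face on a textured background, two eyes whose
#' vertical opening follows `eye_openness`, a nose, and a mouth arc whose
#' curvature follows `mouth_curvature`, then adds Gaussian noise.
#' Deterministic for a fixed spec (including its seed).
#'
#' @param spec a [face_spec()].
#' @param height,width frame dimensions in pixels, both `>= 32`.
#' @return Object of class `"synthetic_frame"`: list with `image`
#'   (`(height, width, 3)` array in `[0, 1]`), `true_box` (quadruple,
#'   0-based half-open), `true_landmarks` (length-10: x,y for left eye,
#'   right eye, nose tip, left mouth corner, right mouth corner) and
#'   `severity`.
#' @export
make_face_frame <- function(spec, height = 64L, width = 64L) {
  if (!inherits(spec, "face_spec")) stop("spec must be a face_spec")
  if (height < 32 || width < 32) stop("frame must be at least 32x32")
  with_seed(spec$seed, render_face(spec, height, width))
}

render_face <- function(spec, H, W) {
  fs <- spec$face_scale
  cx <- spec$center_xy[1]; cy <- spec$center_xy[2]
  a <- fs / 2              # horizontal semi-axis
  b <- fs / 1.6            # vertical semi-axis
  # pixel centres, 0-based
  xs <- matrix(rep(seq_len(W) - 1, each = H), nrow = H)
  ys <- matrix(rep(seq_len(H) - 1, times = W), nrow = H)

  # textured background (low-frequency sinusoids with random phase)
  ph <- runif(4, 0, 2 * pi)
  fr <- runif(2, 0.04, 0.09)
  bg <- 0.45 + 0.06 * sin(fr[1] * xs + ph[1]) * cos(fr[2] * ys + ph[2]) +
        0.04 * sin(0.13 * (xs + ys) + ph[3])
  img <- array(0, dim = c(H, W, 3))
  img[, , 1] <- bg * 0.9; img[, , 2] <- bg; img[, , 3] <- bg * 1.05

  paint <- function(mask, col) {
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[mask] <- col[ch]
      img[, , ch] <<- pl
    }
  }

  # face ellipse with a little boundary irregularity
  er <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2
  paint(er <= 1, c(0.85, 0.72, 0.60))

  # eyes: dark ellipses, vertical opening scaled by eye_openness
  eo <- spec$eye_openness
  exl <- cx - 0.25 * fs; exr <- cx + 0.25 * fs
  ey <- cy - 0.15 * fs
  ea <- 0.09 * fs
  eb <- max(0.5, 0.07 * fs * eo)
  for (ex in c(exl, exr)) {
    em <- ((xs - ex) / ea)^2 + ((ys - ey) / eb)^2 <= 1
    paint(em, c(0.12, 0.10, 0.10))
  }

  # nose: small wedge
  ny <- cy + 0.06 * fs
  nm <- abs(xs - cx) <= 0.035 * fs & ys >= ny - 0.08 * fs & ys <= ny
  paint(nm, c(0.70, 0.55, 0.45))

  # mouth: parabolic arc; corners displaced by curvature
  mc <- spec$mouth_curvature
  my <- cy + 0.28 * fs
  mhw <- 0.20 * fs                       # half-width
  tt <- (xs - cx) / mhw
  curve_y <- my - mc * 0.30 * fs * tt^2
  mm <- abs(tt) <= 1 & abs(ys - curve_y) <= max(0.03 * fs, 0.8)
  paint(mm, c(0.55, 0.20, 0.20))

  if (spec$noise_sigma > 0)
    img <- img + array(rnorm(length(img), sd = spec$noise_sigma), dim = dim(img))
  img[img < 0] <- 0; img[img > 1] <- 1

  box <- c(max(0, cx - a), max(0, cy - b), min(W, cx + a), min(H, cy + b))
  lm <- c(exl, ey, exr, ey, cx, ny, cx - mhw, my - mc * 0.30 * fs,
          cx + mhw, my - mc * 0.30 * fs)
  structure(list(image = img, true_box = box, true_landmarks = lm,
                 severity = spec$severity),
            class = "synthetic_frame")
}

#' Generate a labelled synthetic face video
#'
#' All frames share one severity label; the face centre jitters frame to
#' frame by at most `jitter_px` in each coordinate.
#'
#' @param video_id character identifier.
#' @param severity BDI-II score in `[0, 63]`.
#' @param n_frames number of frames, `>= 1`.
#' @param jitter_px maximum per-frame centre displacement in pixels.
#' @param seed integer seed.
#' @param height,width frame dimensions.
#' @param face_scale face width in pixels.
#' @param noise_sigma Gaussian intensity noise level.
#' @return Object of class `"labeled_video"`: list with `video_id`,
#'   `frames` (list of [make_face_frame()] results) and `bdi_score`.
#' @export
make_video <- function(video_id, severity, n_frames, jitter_px = 2,
                       seed = 1L, height = 64L, width = 64L,
                       face_scale = 36, noise_sigma = 0.02) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  base_center <- c(width / 2, height / 2)
  jit <- with_seed(derive_seed(seed, paste0("jitter:", video_id)), {
    matrix(runif(2 * n_frames, -jitter_px, jitter_px), ncol = 2)
  })
  frames <- lapply(seq_len(n_frames), function(i) {
    sp <- face_spec(severity,
                    center_xy = base_center + jit[i, ],
                    face_scale = face_scale, noise_sigma = noise_sigma,
                    seed = derive_seed(seed, paste0(video_id, ":f", i)))
    make_face_frame(sp, height = height, width = width)
  })
  structure(list(video_id = video_id, frames = frames, bdi_score = severity),
            class = "labeled_video")
}

#' Generate a synthetic regression dataset of labelled videos
#'
#' @param n_videos number of videos, `>= 2`.
#' @param frames_per_video frames per video.
#' @param severity_sampler function of `n` returning `n` severities in
#'   `[0, 63]`; default uniform.
#' @param seed integer seed.
#' @param dir optional directory; when given, frames are written as PNG in
#'   per-video subdirectories with `labels.csv` and a ground-truth sidecar
#'   `ground_truth.csv` (`video_id,frame_idx,x1,y1,x2,y2,lm1x,...,lm5y`).
#' @param ... passed to [make_video()] (frame size, noise, jitter).
#' @return List with `videos` (list of labelled videos) and `labels`
#'   (data.frame `video_id,bdi_score`).
#' @export
make_regression_dataset <- function(n_videos, frames_per_video = 8,
                                    severity_sampler = function(n) runif(n, 0, 63),
                                    seed = 1L, dir = NULL, ...) {
  if (n_videos < 2) stop("n_videos must be >= 2")
  sev <- with_seed(derive_seed(seed, "severity"), severity_sampler(n_videos))
  if (any(sev < 0 | sev > 63)) stop("severity sampler left [0, 63]")
  ids <- sprintf("vid%03d", seq_len(n_videos))
  videos <- lapply(seq_len(n_videos), function(i) {
    make_video(ids[i], sev[i], n_frames = frames_per_video,
               seed = derive_seed(seed, paste0("video:", ids[i])), ...)
  })
  labels <- data.frame(video_id = ids, bdi_score = sev,
                       stringsAsFactors = FALSE)
  if (!is.null(dir)) write_dataset(videos, labels, dir)
  list(videos = videos, labels = labels)
}

write_dataset <- function(videos, labels, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gt <- list()
  for (v in videos) {
    vd <- file.path(dir, v$video_id)
    dir.create(vd, showWarnings = FALSE)
    for (i in seq_along(v$frames)) {
      fr <- v$frames[[i]]
      png::writePNG(fr$image, file.path(vd, sprintf("frame%04d.png", i)))
      gt[[length(gt) + 1]] <- data.frame(
        video_id = v$video_id, frame_idx = i - 1L,
        x1 = fr$true_box[1], y1 = fr$true_box[2],
        x2 = fr$true_box[3], y2 = fr$true_box[4],
        t(stats::setNames(fr$true_landmarks,
            paste0("lm", rep(1:5, each = 2), c("x", "y")))))
    }
  }
  write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
  write.csv(do.call(rbind, gt), file.path(dir, "ground_truth.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Generate annotated patches for cascade training
#'
#' Face patches are near-centred square crops of a synthetic face (IoU with
#' the true box `>= 0.65`) carrying normalised box offsets and landmarks;
#' part-face patches overlap a face with IoU in `[0.3, 0.65)` and carry box
#' offsets only; non-face patches are background crops with IoU `< 0.3`.
#' The per-task sample indicators beta follow the annotation type:
#' classification uses face and non-face patches, box regression uses face
#' and part patches, landmarks use face patches only.
#'
#' Box-offset targets are `(gt - crop) / crop_side` for each of x1,y1,x2,y2;
#' landmark targets are patch-relative coordinates divided by the crop side.
#'
#' @param n_face,n_nonface,n_part patch counts, all `>= 0`.
#' @param patch_size square patch side in pixels, `>= 12`.
#' @param seed integer seed.
#' @return Object of class `"detection_patch_set"`: list with `patches`
#'   (each: `image`, `label`, `offset`, `landmarks`, `iou`) and `beta`
#'   (0/1 matrix `(n, 3)`, columns d, b, m).
#' @export
make_detection_patches <- function(n_face, n_nonface, n_part,
                                   patch_size = 12L, seed = 1L) {
  if (any(c(n_face, n_nonface, n_part) < 0)) stop("counts must be >= 0")
  if (patch_size < 12) stop("patch_size must be >= 12")
  H <- 64L; W <- 64L
  patches <- vector("list", n_face + n_part + n_nonface)
  beta <- matrix(0L, n_face + n_part + n_nonface, 3,
                 dimnames = list(NULL, c("d", "b", "m")))
  k <- 0L
  rng_seed <- derive_seed(seed, "patches")
  with_seed(rng_seed, {
    mk_frame <- function(i) {
      sp <- face_spec(runif(1, 0, 63),
                      center_xy = c(runif(1, 22, W - 22), runif(1, 22, H - 22)),
                      face_scale = runif(1, 24, 36),
                      noise_sigma = 0.02,
                      seed = derive_seed(rng_seed, paste0("pf", i)))
      make_face_frame(sp, H, W)
    }
    crop_patch <- function(img, cb) {
      x1 <- round(cb[1]); y1 <- round(cb[2]); side <- round(cb[3] - cb[1])
      crop <- img[(y1 + 1):(y1 + side), (x1 + 1):(x1 + side), , drop = FALSE]
      resize_nearest(crop, patch_size, patch_size)
    }
    sample_crop <- function(fr, lo, hi, max_tries = 400) {
      gb <- fr$true_box
      gside <- max(gb[3] - gb[1], gb[4] - gb[2])
      for (t in seq_len(max_tries)) {
        side <- round(gside * runif(1, 0.8, 1.25))
        dx <- runif(1, -0.6, 0.6) * gside
        dy <- runif(1, -0.6, 0.6) * gside
        x1 <- round((gb[1] + gb[3]) / 2 + dx - side / 2)
        y1 <- round((gb[2] + gb[4]) / 2 + dy - side / 2)
        if (x1 < 0 || y1 < 0 || x1 + side > W || y1 + side > H) next
        cb <- c(x1, y1, x1 + side, y1 + side)
        ov <- iou(cb, gb)
        if (ov >= lo && ov < hi) return(list(box = cb, iou = ov))
      }
      NULL
    }
    # face patches
    i <- 0L
    while (k < n_face) {
      i <- i + 1L
      fr <- mk_frame(i)
      cr <- sample_crop(fr, 0.65, 1.0001)
      if (is.null(cr)) next
      side <- cr$box[3] - cr$box[1]
      k <- k + 1L
      patches[[k]] <- list(
        image = crop_patch(fr$image, cr$box),
        label = "face",
        offset = (fr$true_box - cr$box) / side,
        landmarks = (fr$true_landmarks - rep(cr$box[1:2], 5)) / side,
        iou = cr$iou, crop_box = cr$box, face_box = fr$true_box)
      beta[k, ] <- c(1L, 1L, 1L)
    }
    # part-face patches
    while (k < n_face + n_part) {
      i <- i + 1L
      fr <- mk_frame(i)
      cr <- sample_crop(fr, 0.3, 0.65)
      if (is.null(cr)) next
      side <- cr$box[3] - cr$box[1]
      k <- k + 1L
      patches[[k]] <- list(
        image = crop_patch(fr$image, cr$box),
        label = "part",
        offset = (fr$true_box - cr$box) / side,
        landmarks = NULL, iou = cr$iou,
        crop_box = cr$box, face_box = fr$true_box)
      beta[k, ] <- c(0L, 1L, 0L)
    }
    # non-face patches (background crops, IoU < 0.3 with any face)
    while (k < n_face + n_part + n_nonface) {
      i <- i + 1L
      fr <- mk_frame(i)
      side <- round(runif(1, 12, 28))
      x1 <- round(runif(1, 0, W - side)); y1 <- round(runif(1, 0, H - side))
      cb <- c(x1, y1, x1 + side, y1 + side)
      ov <- iou(cb, fr$true_box)
      if (ov >= 0.3) next
      k <- k + 1L
      patches[[k]] <- list(image = crop_patch(fr$image, cb),
                           label = "nonface", offset = NULL,
                           landmarks = NULL, iou = ov,
                           crop_box = cb, face_box = fr$true_box)
      beta[k, ] <- c(1L, 0L, 0L)
    }
  })
  structure(list(patches = patches, beta = beta, patch_size = patch_size),
            class = "detection_patch_set")
}
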