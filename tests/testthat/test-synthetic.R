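# Synthetic face-video generator: determinism, severity signal, geometry.

test_that("frame rendering is a pure function of its spec", {
  sp <- face_spec(17.5, seed = 31)
  f1 <- make_face_frame(sp, 64, 64)
  f2 <- make_face_frame(sp, 64, 64)
  expect_identical(f1$image, f2$image)
  expect_identical(f1$true_box, f2$true_box)
  f3 <- make_face_frame(face_spec(17.5, seed = 32), 64, 64)
  expect_false(identical(f1$image, f3$image))
})

test_that("severity controls geometry monotonically", {
  sev <- seq(0, 60, by = 10)
  mc <- vapply(sev, function(s) face_spec(s)$mouth_curvature, numeric(1))
  eo <- vapply(sev, function(s) face_spec(s)$eye_openness, numeric(1))
  expect_true(all(diff(mc) < 0))
  expect_true(all(diff(eo) < 0))
  expect_true(all(eo > 0 & eo <= 1))
  # extremes have opposite curvature sign
  expect_gt(face_spec(0)$mouth_curvature, 0)
  expect_lt(face_spec(63)$mouth_curvature, 0)
  # landmark positions move with severity even at zero noise
  lm0 <- make_face_frame(face_spec(0, noise_sigma = 0, seed = 1))$true_landmarks
  lm63 <- make_face_frame(face_spec(63, noise_sigma = 0, seed = 1))$true_landmarks
  expect_false(isTRUE(all.equal(lm0, lm63)))
})

test_that("severity outside the BDI-II range is rejected", {
  expect_error(face_spec(-1), "0, 63")
  expect_error(face_spec(64), "0, 63")
})

test_that("landmarks lie inside the box, the box inside the image", {
  set.seed(7)
  for (i in 1:20) {
    sp <- face_spec(runif(1, 0, 63),
                    center_xy = c(runif(1, 24, 40), runif(1, 24, 40)),
                    face_scale = runif(1, 24, 36), seed = i)
    fr <- make_face_frame(sp, 64, 64)
    b <- fr$true_box
    lm <- matrix(fr$true_landmarks, nrow = 2)
    expect_true(b[1] >= 0 && b[2] >= 0 && b[3] <= 64 && b[4] <= 64)
    expect_true(all(lm[1, ] >= b[1] & lm[1, ] <= b[3]))
    expect_true(all(lm[2, ] >= b[2] & lm[2, ] <= b[4]))
  }
})

test_that("videos share one label, jitter is bounded, seeds differ", {
  v <- make_video("v1", 23, n_frames = 105, jitter_px = 2, seed = 5)
  expect_length(v$frames, 105)
  expect_true(all(vapply(v$frames, function(f) f$severity, numeric(1)) == 23))
  centers <- t(vapply(v$frames, function(f)
    c((f$true_box[1] + f$true_box[3]) / 2,
      (f$true_box[2] + f$true_box[4]) / 2), numeric(2)))
  expect_true(all(abs(centers[, 1] - 32) <= 2 + 1e-9))
  expect_true(all(abs(centers[, 2] - 32) <= 2 + 1e-9))
  v2 <- make_video("v1", 23, n_frames = 3, jitter_px = 2, seed = 6)
  expect_false(identical(v$frames[[1]]$image, v2$frames[[1]]$image))
  expect_equal(v2$bdi_score, 23)
  expect_error(make_video("v", 10, n_frames = 0), "n_frames")
})

test_that("zero jitter keeps the face geometry fixed across frames", {
  v <- make_video("v1", 40, n_frames = 4, jitter_px = 0, seed = 9,
                  noise_sigma = 0)
  boxes <- t(vapply(v$frames, function(f) f$true_box, numeric(4)))
  expect_true(all(apply(boxes, 2, function(col) max(col) - min(col)) == 0))
  lms <- t(vapply(v$frames, function(f) f$true_landmarks, numeric(10)))
  expect_true(all(apply(lms, 2, function(col) max(col) - min(col)) == 0))
})

test_that("regression datasets are seeded, labelled and binnable", {
  ds <- make_regression_dataset(10, frames_per_video = 2, seed = 3)
  expect_equal(nrow(ds$labels), 10)
  expect_true(all(ds$labels$bdi_score >= 0 & ds$labels$bdi_score <= 63))
  ds2 <- make_regression_dataset(10, frames_per_video = 2, seed = 3)
  expect_identical(ds$labels, ds2$labels)
  dsc <- make_regression_dataset(5, frames_per_video = 1, seed = 3,
                                 severity_sampler = function(n) rep(28, n))
  expect_true(all(dsc$labels$bdi_score == 28))
  expect_true(all(severity_bin(dsc$labels$bdi_score) == "Moderate"))
  expect_error(make_regression_dataset(1), "n_videos")
})

test_that("dataset round-trips through the on-disk PNG/CSV format", {
  dir <- file.path(tempdir(), "ds-roundtrip")
  unlink(dir, recursive = TRUE)
  ds <- make_regression_dataset(3, frames_per_video = 2, seed = 8, dir = dir)
  back <- read_dataset(dir)
  expect_equal(back$labels$video_id, ds$labels$video_id)
  expect_equal(back$labels$bdi_score, ds$labels$bdi_score, tolerance = 1e-6)
  # 8-bit PNG quantisation: intensities within half a level
  expect_lt(max(abs(back$videos[[1]]$frames[[1]]$image -
                    ds$videos[[1]]$frames[[1]]$image)), 1 / 255)
  expect_equal(back$videos[[2]]$frames[[1]]$true_box,
               ds$videos[[2]]$frames[[1]]$true_box, tolerance = 1e-6)
})

test_that("detection patches carry the annotations their indicators enable", {
  ps <- make_detection_patches(20, 15, 10, patch_size = 24, seed = 2)
  labs <- vapply(ps$patches, function(p) p$label, character(1))
  expect_equal(sum(labs == "face"), 20)
  expect_equal(sum(labs == "nonface"), 15)
  expect_equal(sum(labs == "part"), 10)
  # beta switches exactly the annotated tasks on
  expect_true(all(ps$beta[labs == "face", ] == rep(1, 3)))
  expect_true(all(ps$beta[labs == "part", ] == rep(c(0, 1, 0), each = 10)))
  expect_true(all(ps$beta[labs == "nonface", ] == rep(c(1, 0, 0), each = 15)))
  for (p in ps$patches) {
    expect_equal(dim(p$image), c(24, 24, 3))
    if (p$label == "face") {
      expect_length(p$offset, 4)
      expect_length(p$landmarks, 10)
      expect_gte(p$iou, 0.65)
    }
    if (p$label == "part") {
      expect_null(p$landmarks)
      expect_true(p$iou >= 0.3 && p$iou < 0.65)
    }
    if (p$label == "nonface") expect_lt(p$iou, 0.3)
  }
  # no face patches -> landmark task disabled everywhere
  ps0 <- make_detection_patches(0, 5, 5, patch_size = 12, seed = 2)
  expect_true(all(ps0$beta[, "m"] == 0))
})

test_that("part-patch overlap agrees with a direct IoU computation", {
  ps <- make_detection_patches(0, 0, 8, patch_size = 12, seed = 14)
  for (p in ps$patches) {
    ov <- direct_iou(p$crop_box, p$face_box)
    expect_equal(ov, p$iou, tolerance = 1e-12)
    expect_true(ov >= 0.3 && ov < 0.65)
  }
})
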