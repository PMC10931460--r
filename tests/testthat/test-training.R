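# Splits, model assembly, the fit object and its methods, aggregation and
# the ablation harness.

test_that("video-level splits respect the 3:1 ratio and are disjoint", {
  vids <- as.list(1:100)
  sp <- split_dataset(vids, seed = 4)
  expect_length(sp$train, 75)
  expect_length(sp$val, 25)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_setequal(c(sp$train, sp$val), 1:100)
  expect_identical(sp, split_dataset(vids, seed = 4))
  expect_false(identical(sp, split_dataset(vids, seed = 5)))
  expect_error(split_dataset(as.list(1:3)), "at least 4")
})

test_that("the assembled model maps any batch to one score per image", {
  m <- build_model(tiny_backbone(), "cca", input_size = 32, seed = 2)
  for (n in c(1, 3)) {
    x <- array(rnorm(32 * 32 * 3 * n), dim = c(32, 32, 3, n))
    out <- model_predict_frames(m, x)
    expect_length(out, n)
    expect_true(all(is.finite(out)))
  }
  # variant "none" drops the attention unit entirely (plain pyramid model)
  m0 <- build_model(tiny_backbone(), "none", input_size = 32, seed = 2)
  expect_null(m0$attn)
  expect_lt(model_param_count(m0), model_param_count(m))
  expect_error(build_model(tiny_backbone(), "cca", input_size = 40),
               "divisible by 32")
  expect_error(build_model(tiny_backbone(), "simple"), "arg")
})

test_that("the deeper configuration has strictly more parameters", {
  m50 <- build_model(backbone_config(depth = 50, width_mult = 0.03125,
                                     fpn_channels = 8),
                     "cca", input_size = 32, seed = 1)
  m101 <- build_model(backbone_config(depth = 101, width_mult = 0.03125,
                                      fpn_channels = 8),
                      "cca", input_size = 32, seed = 1)
  expect_gt(model_param_count(m101), model_param_count(m50))
})

test_that("training tracks history and restores the best checkpoint", {
  tf <- get_tiny_fit()
  fit <- tf$fit
  expect_s3_class(fit, "ccanet")
  expect_equal(nrow(fit$history), 2)
  expect_equal(fit$best_val_loss, min(fit$history$val_loss))
  expect_true(all(is.finite(fit$history$train_loss)))
  expect_output(print(fit), "attention: cca")
  expect_lte(fit$val_metrics$mae, fit$val_metrics$rmse)
  r <- residuals(fit)
  expect_length(r, length(fit$split$val))
})

test_that("frame scores aggregate to clamped per-video records", {
  agg <- ccanet:::aggregate_video_scores(
    video_id = c("a", "a", "b", "b", "c"),
    frame_scores = c(10, 20, 70, 80, -5),
    frame_labels = c(15, 15, 60, 60, 0))
  expect_equal(agg$video_score[agg$video_id == "a"], 15)   # mean(10, 20)
  expect_equal(agg$video_score[agg$video_id == "b"], 63)   # clamped
  expect_equal(agg$video_score[agg$video_id == "c"], 0)    # clamped
  med <- ccanet:::aggregate_video_scores(
    video_id = c("a", "a", "a"), frame_scores = c(1, 50, 2),
    frame_labels = rep(10, 3), aggregate = "median")
  expect_equal(med$video_score, 2)
})

test_that("predict_video scores frames and inherits the video label", {
  tf <- get_tiny_fit()
  v <- tf$ds$videos[[1]]
  rec <- predict_video(tf$fit, v)
  expect_length(rec$frame_scores, length(v$frames))
  expect_equal(rec$video_score,
               min(max(mean(rec$frame_scores), 0), 63))
  expect_equal(rec$true_score, v$bdi_score)
  rep <- predict(tf$fit, tf$ds$videos[1:4])
  expect_s3_class(rep, "metrics_report")
  expect_equal(rep$n_subjects, 4)
  expect_error(predict_video(tf$fit, list(frames = list())), "no frames")
})

test_that("checkpoints round-trip the model exactly", {
  tf <- get_tiny_fit()
  path <- file.path(tempdir(), "ck.rds")
  save_checkpoint(tf$fit, path)
  back <- load_checkpoint(path)
  v <- tf$ds$videos[[2]]
  expect_equal(predict_video(back, v)$frame_scores,
               predict_video(tf$fit, v)$frame_scores, tolerance = 1e-12)
  expect_error(load_checkpoint(
    { p <- file.path(tempdir(), "junk.rds"); saveRDS(list(a = 1), p); p }),
    "unrecognised")
})

test_that("the ablation harness is deterministic and one row per variant", {
  ds <- make_regression_dataset(8, frames_per_video = 2, seed = 21,
                                height = 48, width = 48, face_scale = 30)
  cfg <- train_config(epochs = 1, batch_size = 8, seed = 21)
  t1 <- run_ablation(ds$videos, variants = c("none", "cca"), config = cfg,
                     backbone_cfg = tiny_backbone(), input_size = 32)
  expect_equal(nrow(t1), 2)
  expect_equal(t1$model, c("FPN", "FPN+CCA"))
  expect_true(all(t1$mae <= t1$rmse + 1e-12))
  t2 <- run_ablation(ds$videos, variants = c("none", "cca"), config = cfg,
                     backbone_cfg = tiny_backbone(), input_size = 32)
  expect_equal(t1$rmse, t2$rmse, tolerance = 1e-12)
  expect_equal(t1$mae, t2$mae, tolerance = 1e-12)
  csv <- file.path(tempdir(), "ablation.csv")
  write_ablation_csv(t1, csv)
  expect_equal(names(read.csv(csv)), c("Models", "RMSE", "MAE"))
})

test_that("diagnostic plots are written and non-empty", {
  recs <- data.frame(video_id = letters[1:6], true_score = seq(5, 55, 10),
                     video_score = seq(5, 55, 10))
  p1 <- error_boxplot(list(model_a = recs,
                           model_b = transform(recs,
                                               video_score = video_score + 5)),
                      file.path(tempdir(), "box.png"))
  p2 <- qq_plot(recs, file.path(tempdir(), "qq.png"))
  expect_true(file.exists(p1) && file.size(p1) > 0)
  expect_true(file.exists(p2) && file.size(p2) > 0)
  expect_error(qq_plot(recs[1, ], file.path(tempdir(), "qq2.png")),
               "at least 2")
})

test_that("training configuration validates its fields", {
  expect_error(train_config(learning_rate = 0), "invalid")
  expect_error(train_config(epochs = 0), "invalid")
  cfg <- train_config()
  expect_equal(cfg$learning_rate, 0.001)
  expect_equal(cfg$weight_decay, 0.0001)
  expect_equal(cfg$batch_size, 128L)
  expect_equal(cfg$epochs, 100L)
  expect_equal(cfg$train_val_ratio, c(3, 1))
})
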