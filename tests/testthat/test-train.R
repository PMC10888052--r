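# Training loop: determinism, loss dispatch, checkpoints, prediction export.

tiny_train_setup <- function(n = 3, seed = 77) {
  cases <- lapply(seq_len(n), function(i)
    zscore_normalize(generate_phantom(phantom_params(seed = seed + i))))
  cfg <- model_config(levels = 2, stem_channels = 4,
                      encoder_channels = c(6, 8), input_channels = 4,
                      block = list(channel_reduction = 2, spatial_kernel = 3),
                      seed = 1)
  list(cases = cases, cfg = cfg)
}

test_that("identical seeds give identical epoch-1 losses", {
  su <- tiny_train_setup(2)
  r1 <- train(build_model(su$cfg), su$cases,
              cfg = train_config(lr = 1e-3, epochs = 1, seed = 3))
  r2 <- train(build_model(su$cfg), su$cases,
              cfg = train_config(lr = 1e-3, epochs = 1, seed = 3))
  expect_identical(r1$history$loss, r2$history$loss)
})

test_that("a short run reduces the training loss", {
  su <- tiny_train_setup(3)
  m <- build_model(su$cfg)
  res <- train(m, su$cases, cfg = train_config(lr = 3e-3, epochs = 5, seed = 1))
  expect_lt(tail(res$history$loss, 1), res$history$loss[1])
})

test_that("the loss option dispatches to the right objective", {
  su <- tiny_train_setup(1)
  p <- model_forward(build_model(su$cfg), su$cases[[1]]$sequences)
  lab <- su$cases[[1]]$labels
  l_dice <- nlinet:::training_loss(p, lab, "dice")
  expect_equal(l_dice$wce_part, 0)
  expect_equal(l_dice$total, dice_loss(p, subregion_masks(lab)$masks),
               tolerance = 1e-12)
  l_combo <- nlinet:::training_loss(p, lab, "dice_wce")
  cl <- combo_loss(p, lab)
  expect_equal(l_combo$total, cl$total, tolerance = 1e-12)
  l_ce <- nlinet:::training_loss(p, lab, "dice_ce")
  expect_gt(l_ce$wce_part, 0)
  expect_false(isTRUE(all.equal(l_ce$wce_part, l_combo$wce_part)))
})

test_that("a non-finite loss aborts with a diagnostic", {
  su <- tiny_train_setup(1)
  m <- build_model(su$cfg)
  m$head$params$weight[1] <- NaN
  expect_error(train(m, su$cases, cfg = train_config(lr = 1e-3, epochs = 1)),
               "non-finite loss")
})

test_that("training honors the best-validation checkpoint and writes logs", {
  su <- tiny_train_setup(3)
  m <- build_model(su$cfg)
  ck <- withr::local_tempfile(fileext = ".rds")
  lg <- withr::local_tempfile(fileext = ".jsonl")
  res <- train(m, su$cases[1:2], val_cases = su$cases[3],
               cfg = train_config(lr = 3e-3, epochs = 3, seed = 2,
                                  checkpoint = ck, log = lg))
  expect_true(file.exists(ck))
  expect_equal(nrow(res$history), 3)
  expect_equal(length(readLines(lg)), 3)
  expect_gte(res$best_epoch, 1)
  # the in-memory model carries the best-epoch weights
  m2 <- load_checkpoint(ck)
  x <- su$cases[[3]]$sequences
  expect_identical(model_forward(m2, x), model_forward(m, x))
})

test_that("prediction export round-trips and the fused map rebuilds the masks", {
  su <- tiny_train_setup(1)
  m <- build_model(su$cfg)
  td <- withr::local_tempdir()
  cs <- su$cases[[1]]
  paths <- predict_case(m, cs, td, enforce_nesting = TRUE)
  pr <- model_predict(m, cs$sequences, enforce_nesting = TRUE)
  expect_true(all(file.exists(file.path(td, sprintf("%s_%s.nii.gz",
                                                    cs$case_id,
                                                    c("ET", "TC", "WT"))))))
  fused <- RNifti::readNifti(file.path(td, sprintf("%s_pred_seg.nii.gz",
                                                   cs$case_id)))
  rebuilt <- subregion_masks(array(as.integer(fused), dim = dim(cs$labels)))
  expect_equal(unname(rebuilt$masks), unname(pr$masks), ignore_attr = TRUE)
  # rerun is idempotent at the voxel level
  predict_case(m, cs, td, enforce_nesting = TRUE)
  fused2 <- RNifti::readNifti(file.path(td, sprintf("%s_pred_seg.nii.gz",
                                                    cs$case_id)))
  expect_equal(array(as.numeric(fused2), dim = dim(fused2)),
               array(as.numeric(fused), dim = dim(fused)))
})

test_that("run configuration files build model and train configs", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("model:",
               "  levels: 2",
               "  stem_channels: 4",
               "  encoder_channels: [6, 8]",
               "  input_channels: 4",
               "  block:",
               "    channel_reduction: 2",
               "    spatial_kernel: 3",
               "train:",
               "  lr: 0.003",
               "  epochs: 2"), path)
  rc <- read_run_config(path)
  expect_s3_class(rc$model, "nlinet_config")
  expect_equal(rc$model$encoder_channels, c(6L, 8L))
  expect_equal(rc$train$lr, 0.003)
  expect_equal(rc$train$epochs, 2L)
  # the training hyperparameter defaults are the full-scale protocol
  dflt <- train_config()
  expect_equal(dflt$lr, 1e-4)
  expect_equal(dflt$weight_decay, 1e-5)
  expect_equal(dflt$batch_size, 1)
  expect_equal(dflt$epochs, 200L)
})
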