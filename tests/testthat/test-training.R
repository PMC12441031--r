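test_that("a zero learning rate leaves stage-2 losses exactly constant", {
  tbl <- tiny_table(n = 16, seed = 1)
  fit <- finetune(standardize_features(tbl), NULL,
                  train = short_train(epochs = 6, learning_rate = 0))
  expect_identical(length(unique(fit$history$loss)), 1L)
})

test_that("zero-rate stage-1 losses vary only through view resampling", {
  std <- standardize_features(tiny_table(n = 16, seed = 2))
  pre <- pretrain(std, train = short_train(epochs = 8, learning_rate = 0))
  # parameters never move, so the loss fluctuates only with the fresh
  # disturbance draws each epoch
  expect_lt(diff(range(pre$history$loss)), 0.5)
})

test_that("identical seeds reproduce loss histories and predictions", {
  tbl <- tiny_table(n = 16, seed = 3)
  f1 <- ssdfrn_fit(tbl, train = short_train(epochs = 4, seed = 9))
  f2 <- ssdfrn_fit(tbl, train = short_train(epochs = 4, seed = 9))
  expect_identical(tidy(f1), tidy(f2))
  expect_identical(predict(f1, tbl), predict(f2, tbl))
})

test_that("the frozen encoder keeps its stage-1 kernels bit-identical", {
  std <- standardize_features(tiny_table(n = 16, seed = 4))
  pre <- pretrain(std, train = short_train(epochs = 3))
  fit <- finetune(std, pre, train = short_train(epochs = 3))
  expect_identical(fit$encoder_params$modules, pre$encoder_params$modules)
})

test_that("an unfrozen encoder updates its kernels during fine-tuning", {
  std <- standardize_features(tiny_table(n = 16, seed = 5))
  pre <- pretrain(std, train = short_train(epochs = 2))
  fit <- finetune(std, pre,
                  train = short_train(epochs = 3,
                                      freeze_encoder_in_stage2 = FALSE))
  expect_false(identical(fit$encoder_params$modules,
                         pre$encoder_params$modules))
})

test_that("constant targets pull the estimator toward the constant", {
  tbl <- tiny_table(n = 16, seed = 6)
  tbl$biomass <- rep(15, 16)
  fit <- finetune(standardize_features(tbl), NULL,
                  train = short_train(epochs = 40))
  expect_lte(fit$history$loss[40], fit$history$loss[1])
  expect_lt(mean(abs(predict(fit, tbl)$.pred - 15)), 0.5)
})

test_that("prediction is order-preserving and schema-checked", {
  tbl <- tiny_table(n = 12, seed = 7)
  fit <- ssdfrn_fit(tbl, pretrain = FALSE, train = short_train(epochs = 2))
  p <- predict(fit, tbl)
  expect_identical(nrow(p), 12L)
  expect_identical(p$sample_id, tbl$sample_id)
  # reversing the rows reverses the predictions
  expect_equal(predict(fit, tbl[12:1, ])$.pred, rev(p$.pred),
               tolerance = 1e-12)
  bad <- tbl
  bad$NDVI <- NULL
  expect_error(predict(fit, bad), "NDVI")
})

test_that("a zero-weight estimator head predicts its bias for any input", {
  tbl <- tiny_table(n = 10, seed = 8)
  fit <- ssdfrn_fit(tbl, pretrain = FALSE, train = short_train(epochs = 2))
  fit$estimator <- ssdfrn:::zero_weights(fit$estimator)
  fit$estimator$fc2$b <- 3.25
  expect_identical(unique(predict(fit, tbl)$.pred), 3.25)
})

test_that("fine-tuning refuses tables without a target", {
  tbl <- tiny_table(n = 10, seed = 9)
  tbl$biomass <- NULL
  expect_error(finetune(standardize_features(tbl), NULL,
                        train = short_train(epochs = 2)),
               "biomass")
})

test_that("pretraining validates the window/projection geometry", {
  std <- standardize_features(tiny_table(n = 10, seed = 10))
  expect_error(pretrain(std, encoder = encoder_config(projection_width = 10),
                        train = short_train(epochs = 1)),
               "projection_width")
  expect_error(pretrain(std, decoder = decoder_config(output_width = 10),
                        train = short_train(epochs = 1)),
               "output_width")
})

test_that("model checkpoints round-trip and refuse mismatched schemas", {
  tbl <- tiny_table(n = 12, seed = 11)
  fit <- ssdfrn_fit(tbl, train = short_train(epochs = 2))
  path <- withr::local_tempfile(fileext = ".json")
  save_ssdfrn(fit, path)
  back <- load_ssdfrn(path)
  expect_equal(predict(back, tbl)$.pred, predict(fit, tbl)$.pred,
               tolerance = 1e-12)
  other <- feature_schema(paste0("f", 1:22))
  expect_error(load_ssdfrn(path, schema = other), "refusing to load")
})
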