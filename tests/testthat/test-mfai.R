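test_that("clinical encoding is a length-4 monotone, invertible mapping", {
  v <- encode_clinical(list(age = 65, psa = 10, gleason = 7, tnm = "T2N0M0"))
  expect_length(v, 4)
  expect_equal(unname(v[1]), 65)
  expect_equal(unname(v[2]), log10(11))
  v_m1 <- encode_clinical(list(age = 65, psa = 10, gleason = 7, tnm = "T2N0M1"))
  expect_gt(v_m1[4], v[4])                      # M1 strictly larger
  # invertible over the documented code list
  codes <- as.vector(outer(outer(paste0("T", 1:4), paste0("N", 0:1), paste0),
                           paste0("M", 0:1), paste0))
  ords <- vapply(codes, tnm_ordinal, numeric(1))
  expect_equal(anyDuplicated(ords), 0)
  expect_equal(unname(vapply(ords, tnm_from_ordinal, character(1))), codes)
  expect_error(encode_clinical(list(age = 65, psa = 10, gleason = 7)),
               "missing clinical field")
  expect_error(encode_clinical(list(age = 65, psa = -1, gleason = 7,
                                    tnm = "T2N0M0")), "non-negative")
  expect_error(encode_clinical(list(age = 65, psa = 1, gleason = 7,
                                    tnm = "X9")), "unparseable")
  # raw-PSA mode
  vr <- encode_clinical(list(age = 65, psa = 10, gleason = 7, tnm = "T2N0M0"),
                        log_psa = FALSE)
  expect_equal(unname(vr[2]), 10)
})

test_that("feature fusion concatenates image-first and rejects non-finite input", {
  f <- fuse_features(c(0.2, 0.8), c(65, 1, 7, 2))
  expect_length(f, 6)
  expect_equal(f[1:2], c(0.2, 0.8))
  expect_equal(fuse_features(c(1, 2), c(0, 0, 0, 0))[1:2], c(1, 2))
  expect_error(fuse_features(c(NaN, 1), c(1, 2, 3, 4)), "finite")
  expect_identical(fuse_features(1:2, 3:6), fuse_features(1:2, 3:6))
})

fusion_fixture <- function(seed, img_signal = 0.5, clin_effect = 2,
                           n_patients = 20) {
  set.seed(seed)
  samples <- list(); k <- 0
  clin <- list()
  for (i in seq_len(n_patients)) {
    lab <- as.integer(i %% 2 == 0)
    px <- array(runif(32 * 32 * 3, 0, 0.5), c(32, 32, 3))
    if (lab == 1 && img_signal > 0) px[8:24, 8:24, ] <- px[8:24, 8:24, ] + img_signal
    k <- k + 1
    samples[[k]] <- structure(
      list(pixels = pmin(px, 1), channel_names = c("a", "b", "c"),
           patient_id = sprintf("F%02d", i), slice_index = 1L, label = lab),
      class = "multichannel_sample")
    clin[[i]] <- data.frame(
      patient_id = sprintf("F%02d", i),
      age = round(rnorm(1, 65, 5)),
      psa = exp(rnorm(1, log(15) + clin_effect * 0.3 * lab, 0.3)),
      gleason = sample(6:10, 1, prob = if (lab && clin_effect > 0)
        c(1, 1, 2, 3, 3) else c(3, 3, 2, 1, 1)),
      tnm = if (lab && clin_effect > 0) "T3N1M0" else "T2N0M0",
      label = lab)
  }
  list(samples = samples, clinical = do.call(rbind, clin))
}

train_tiny_net <- function(samples, sp, seed = 3, epochs = 6) {
  set.seed(seed)
  m <- build_model(net_config(growth_rate = 4, block_layers = 2,
                              stem_channels = 8, bottleneck = FALSE,
                              se_reduction = 4, input_size = 32))
  train(m, samples, train_config("densenet", epochs = epochs,
                                 learning_rate = 0.02, batch_size = 8,
                                 seed = seed),
        sp, round = 1, augment = FALSE, balance = FALSE)
}

test_that("stage-2 fusion demands the identical stage-1 split", {
  fx <- fusion_fixture(51)
  sp <- make_splits(fx$clinical$patient_id, seed = 5)
  m <- train_tiny_net(fx$samples, sp)
  expect_error(train_fusion(m, fx$samples, fx$clinical, sp, round = 2),
               "does not match")
  fus <- train_fusion(m, fx$samples, fx$clinical, sp, round = 1, seed = 4)
  expect_s3_class(fus, "fusion_model")
  expect_error(train_fusion(build_model(net_config(
    growth_rate = 4, block_layers = 2, stem_channels = 8,
    bottleneck = FALSE, se_reduction = 4)), fx$samples, fx$clinical, sp),
    "untrained")
})

test_that("fusion predictions are probabilities and aggregate by patient mean", {
  fx <- fusion_fixture(52)
  sp <- make_splits(fx$clinical$patient_id, seed = 5)
  m <- train_tiny_net(fx$samples, sp)
  fus <- train_fusion(m, fx$samples, fx$clinical, sp, round = 1, seed = 4)
  pr <- predict_fusion(fus, fx$samples, fx$clinical)
  expect_true(all(pr$prob >= 0 & pr$prob <= 1))
  expect_equal(pr$label, as.integer(pr$prob > 0.5))
  agg <- aggregate_patient(c(0.7, 0.7, 0.2), c("A", "A", "B"))
  expect_equal(agg$prob[agg$patient_id == "A"], 0.7)   # mean of identical slices
  expect_equal(agg$label, c(1L, 0L))
})

test_that("fusion training is deterministic under fixed seeds", {
  fx <- fusion_fixture(53)
  sp <- make_splits(fx$clinical$patient_id, seed = 5)
  run <- function() {
    m <- train_tiny_net(fx$samples, sp, seed = 7, epochs = 4)
    fus <- train_fusion(m, fx$samples, fx$clinical, sp, round = 1, seed = 4)
    predict_fusion(fus, fx$samples, fx$clinical)$prob
  }
  expect_identical(run(), run())
})

test_that("fusion falls back on the informative modality", {
  # clinical-only signal: image channels are pure noise
  fx <- fusion_fixture(54, img_signal = 0, clin_effect = 3, n_patients = 50)
  sp <- make_splits(fx$clinical$patient_id, seed = 6)
  m <- train_tiny_net(fx$samples, sp, epochs = 4)
  fus <- train_fusion(m, fx$samples, fx$clinical, sp, round = 1, seed = 4)
  hold <- c(sp$rounds[[1]]$validation, sp$rounds[[1]]$test)
  idx <- vapply(fx$samples, function(s) s$patient_id, "") %in% hold
  pr <- predict_fusion(fus, fx$samples[idx], fx$clinical)
  lab <- vapply(fx$samples[idx], function(s) s$label, 1L)
  clin_x <- encode_clinical(fx$clinical)
  tr <- fx$clinical$patient_id %in% sp$rounds[[1]]$train
  bst <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = 3, eta = 0.1,
                  nthread = 1, seed = 1),
    data = xgboost::xgb.DMatrix(clin_x[tr, ], label = fx$clinical$label[tr]),
    nrounds = 50, verbose = 0)
  p_clin <- stats::predict(bst, xgboost::xgb.DMatrix(clin_x[idx, ]))
  auc_fused <- roc_auc(lab, pr$prob)$auc
  auc_clin <- roc_auc(lab, p_clin)$auc
  expect_gte(auc_fused, auc_clin - 0.15)    # within Monte-Carlo noise
  # image-only signal: clinical covariates are exchangeable
  fy <- fusion_fixture(55, img_signal = 0.6, clin_effect = 0, n_patients = 50)
  spy <- make_splits(fy$clinical$patient_id, seed = 6)
  my <- train_tiny_net(fy$samples, spy, epochs = 6)
  fusy <- train_fusion(my, fy$samples, fy$clinical, spy, round = 1, seed = 4)
  holdy <- c(spy$rounds[[1]]$validation, spy$rounds[[1]]$test)
  iy <- vapply(fy$samples, function(s) s$patient_id, "") %in% holdy
  pry <- predict_fusion(fusy, fy$samples[iy], fy$clinical)
  laby <- vapply(fy$samples[iy], function(s) s$label, 1L)
  p_img <- predict_net(my, fy$samples[iy])
  expect_gte(roc_auc(laby, pry$prob)$auc, roc_auc(laby, p_img)$auc - 0.15)
})
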