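# 32px input: stem/2 -> pool/2 -> one transition/2 leaves a 4x4 map at the
# SPP tap, the smallest extent the default 1/2/4 pyramid accepts
tiny_cfg <- function(...) {
  net_config(growth_rate = 4, block_layers = 2, stem_channels = 8,
             bottleneck = FALSE, se_reduction = 4, input_size = 32, ...)
}

# directly constructed separable samples: class 1 has a bright center blob
toy_samples <- function(n_patients, size = 32, seed = 1, signal = 0.5) {
  set.seed(seed)
  out <- list(); k <- 0
  for (i in seq_len(n_patients)) {
    lab <- as.integer(i %% 2 == 0)
    for (sl in 1:2) {
      px <- array(runif(size * size * 3, 0, 0.5), c(size, size, 3))
      if (lab == 1) {
        ctr <- (size / 4):(3 * size / 4)
        px[ctr, ctr, ] <- px[ctr, ctr, ] + signal
      }
      px <- pmin(px, 1)
      k <- k + 1
      out[[k]] <- structure(list(pixels = px, channel_names = c("a", "b", "c"),
                                 patient_id = sprintf("T%02d", i),
                                 slice_index = sl, label = lab),
                            class = "multichannel_sample")
    }
  }
  out
}

test_that("SE block gates channels in (0,1) and preserves shape", {
  set.seed(2)
  x <- array(rnorm(6 * 6 * 8), c(6, 6, 8))
  y <- se_block(x, reduction = 4)
  expect_equal(dim(y), dim(x))
  g <- attr(y, "gates")
  expect_true(all(g > 0 & g < 1))
  # all-ones gates give the identity map
  y1 <- se_block(x, gates = rep(1, 8))
  expect_equal(y1, x, ignore_attr = TRUE)
  expect_error(se_block(x, reduction = 16), "exceeds channel count")
})

test_that("SPP pooling yields a fixed-length vector equal to the bin-wise max", {
  set.seed(3)
  x1 <- array(rnorm(5 * 9), c(5, 9, 1))
  expect_equal(spp_pool(x1, levels = 1), max(x1))
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  for (levels in list(c(1, 2, 4), c(1, 3), 2)) {
    v <- spp_pool(x, levels)
    expect_length(v, 4 * sum(levels^2))
    expect_equal(v, oracle_spp(x, levels), tolerance = 1e-12)
  }
  # length independent of spatial extent
  x2 <- array(rnorm(13 * 7 * 4), c(13, 7, 4))
  expect_length(spp_pool(x2, c(1, 2, 4)), 4 * 21)
  expect_error(spp_pool(array(rnorm(3 * 3 * 2), c(3, 3, 2)), c(1, 4)),
               "smaller than pyramid level")
})

test_that("model builder wires the head and both backbones", {
  set.seed(4)
  m <- build_model(tiny_cfg())
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  fw <- mpfusion:::forward_net(m, x)
  expect_equal(dim(fw$scores), c(2, 2))
  expect_equal(nrow(fw$spp), m$spp_len)
  r <- build_model(net_config("resnet18", resnet_channels = c(8, 16),
                              resnet_blocks = c(1, 1), resnet_strides = c(1, 2),
                              se_reduction = 4))
  fwr <- mpfusion:::forward_net(r, x)
  expect_equal(dim(fwr$scores), c(2, 2))
  expect_error(net_config(spp_levels = numeric(0)), "non-empty")
})

test_that("augmentation bank is seeded, label-preserving and range-safe", {
  set.seed(5)
  img <- array(runif(24 * 24 * 3), c(24, 24, 3))
  expect_identical(augment_bank(img, mode = "off"), img)
  a1 <- augment_bank(img, seed = 42)
  a2 <- augment_bank(img, seed = 42)
  expect_identical(a1, a2)
  expect_true(all(a1 >= 0 & a1 <= 1))
  s <- toy_samples(2)[[1]]
  as_ <- augment_bank(s, seed = 9)
  expect_s3_class(as_, "multichannel_sample")
  expect_identical(as_$label, s$label)
})

test_that("split plan partitions patients with cross-round test disjointness", {
  ids <- sprintf("P%03d", 1:96)
  sp <- make_splits(ids, seed = 7)
  sizes <- sort(lengths(sp$subsets), decreasing = TRUE)
  expect_equal(unname(sizes), c(20, 19, 19, 19, 19))
  all_test <- character(); all_val <- character()
  for (rd in sp$rounds) {
    expect_length(intersect(rd$train, rd$validation), 0)
    expect_length(intersect(rd$train, rd$test), 0)
    expect_length(intersect(rd$validation, rd$test), 0)
    expect_setequal(c(rd$train, rd$validation, rd$test), ids)
    expect_length(intersect(all_test, rd$test), 0)
    all_test <- c(all_test, rd$test); all_val <- c(all_val, rd$validation)
  }
  # held-out coverage: every patient is tested-or-validated exactly once,
  # with 50 test and 46 validation patients over the five rounds
  expect_equal(sort(c(all_test, all_val)), sort(ids))
  expect_length(all_test, 50)
  expect_length(all_val, 46)
  expect_identical(sp, make_splits(ids, seed = 7))
  expect_false(identical(sp$subsets, make_splits(ids, seed = 8)$subsets))
  expect_error(make_splits(sprintf("P%d", 1:9)), "at least 10")
})

test_that("training overfits a tiny separable set and records its schedule", {
  samples <- toy_samples(10, seed = 31)
  sp <- make_splits(sprintf("T%02d", 1:10), seed = 2)
  set.seed(13)
  m <- build_model(tiny_cfg())
  tc <- train_config("densenet", epochs = 15, learning_rate = 0.02,
                     batch_size = 8, seed = 3)
  m <- train(m, samples, tc, sp, round = 1, augment = FALSE, balance = FALSE)
  expect_true(m$trained)
  tr_idx <- vapply(samples, function(s) s$patient_id, "") %in%
    sp$rounds[[1]]$train
  p <- predict_net(m, samples[tr_idx])
  lab <- vapply(samples[tr_idx], function(s) s$label, 1L)
  expect_equal(mean((p > 0.5) == (lab == 1)), 1.0)
  expect_true(all(c("epoch", "train_loss", "val_loss", "lr") %in%
                    colnames(m$history)))
})

test_that("plateau halves the learning rate and stagnation stops training early", {
  samples <- toy_samples(10, seed = 41)
  sp <- make_splits(sprintf("T%02d", 1:10), seed = 2)
  set.seed(17)
  m <- build_model(tiny_cfg())
  # vanishing learning rate: updates are far below the improvement
  # threshold, so the validation loss can never improve after epoch 1
  tc <- train_config("densenet", epochs = 30, learning_rate = 1e-20,
                     batch_size = 8, plateau_patience = 2,
                     early_stop_patience = 6, seed = 3)
  m <- train(m, samples, tc, sp, round = 1, augment = FALSE, balance = FALSE)
  h <- m$history
  expect_lt(nrow(h), 30)                          # early stop fired
  drops <- h$lr[-1] / h$lr[-nrow(h)]
  expect_true(any(abs(drops - 0.5) < 1e-12))      # exact 0.5x step recorded
})

test_that("feature extraction returns the head scores or the SPP vector", {
  set.seed(19)
  m <- build_model(tiny_cfg())
  s <- toy_samples(2)[[1]]
  expect_warning(f <- extract_image_features(m, s), "untrained")
  expect_length(f, 2)
  suppressWarnings({
    fs <- extract_image_features(m, s, mode = "spp")
    expect_length(fs, m$spp_len)
    expect_identical(extract_image_features(m, s), f)   # deterministic
  })
})
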