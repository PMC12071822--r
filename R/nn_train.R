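#' Training configuration
#'
#' Optimization settings for the image classifiers. Defaults follow the
#' study protocol: 50 epochs of stochastic gradient descent with momentum
#' 0.9, weight decay 1e-4, batch size 48, initial learning rate 1e-4 for
#' the DenseNet backbone and 1e-3 for ResNet18, binary cross-entropy
#' loss, learning rate halved (`lr_factor = 0.5`) when the validation
#' loss has not decreased for `plateau_patience = 10` epochs, and early
#' stopping after `early_stop_patience = 20` stagnant epochs.
#'
#' @param backbone `"densenet"` or `"resnet18"` (sets the default
#'   learning rate).
#' @param epochs,learning_rate,batch_size,momentum,weight_decay SGD
#'   settings.
#' @param plateau_patience,lr_factor,early_stop_patience schedule.
#' @param seed integer seed for shuffling, augmentation and
#'   initialization during training.
#' @return An object of class `train_config`.
#' @export
train_config <- function(backbone = c("densenet", "resnet18"), epochs = 50,
                         learning_rate = NULL, batch_size = 48,
                         momentum = 0.9, weight_decay = 1e-4,
                         plateau_patience = 10, lr_factor = 0.5,
                         early_stop_patience = 20, seed = 1) {
  backbone <- match.arg(backbone)
  learning_rate <- learning_rate %||%
    switch(backbone, densenet = 1e-4, resnet18 = 1e-3)
  structure(list(backbone = backbone, epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), momentum = momentum,
                 weight_decay = weight_decay,
                 plateau_patience = as.integer(plateau_patience),
                 lr_factor = lr_factor,
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed)),
            class = "train_config")
}

# binary cross-entropy via the two-score softmax parameterization:
# loss = -mean(log p[label]); returns the score gradient as well
bce_loss <- function(scores, labels) {
  n <- ncol(scores)
  m <- apply(scores, 2, max)
  e <- exp(sweep(scores, 2, m))
  p <- sweep(e, 2, colSums(e), "/")
  pick <- cbind(labels + 1L, seq_len(n))
  idx <- pick[, 1] + nrow(scores) * (pick[, 2] - 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  onehot <- matrix(0, nrow(scores), n)
  onehot[idx] <- 1
  list(loss = loss, grad = (p - onehot) / n, prob = p[2, ])
}

#' Train an SE-SPP classifier on one split round
#'
#' Trains the network by mini-batch stochastic gradient descent with
#' momentum on the training patients of one round of the split plan,
#' monitoring the validation loss each epoch. The training set is
#' class-balanced by oversampling the minority class through the
#' augmentation bank, augmentation is applied to training images only,
#' and all images are standardized by the training set's per-channel mean
#' and standard deviation (stored on the model and re-applied at
#' prediction time). The learning rate is multiplied by `lr_factor` after
#' `plateau_patience` epochs without validation improvement; training
#' stops early after `early_stop_patience` stagnant epochs; the weights
#' with the best validation loss are retained. A non-finite loss aborts
#' with a diagnostic.
#'
#' @param model an untrained [build_model()] network.
#' @param samples list of [assemble_sample()] samples (with labels).
#' @param config a [train_config()].
#' @param split_plan a [make_splits()] plan.
#' @param round split round to train on (1-based).
#' @param augment apply the augmentation bank to training images.
#' @param balance oversample the minority class to parity.
#' @param normalize standardize by training-set channel statistics.
#' @param verbose print per-epoch progress.
#' @return The trained model (with `$history`, `$norm`, `$split_info`).
#' @export
train <- function(model, samples, config = train_config(), split_plan,
                  round = 1, augment = TRUE, balance = TRUE,
                  normalize = TRUE, verbose = FALSE) {
  stopifnot(inherits(model, "sspp_net"), inherits(split_plan, "split_plan"))
  rd <- split_plan$rounds[[round]]
  pid <- vapply(samples, function(s) s$patient_id, character(1))
  lab <- vapply(samples, function(s) as.integer(s$label), integer(1))
  tr_idx <- which(pid %in% rd$train)
  va_idx <- which(pid %in% rd$validation)
  if (!length(tr_idx) || !length(va_idx))
    stop("empty training or validation set for this round")
  with_seed(config$seed, {
    tr_samples <- samples[tr_idx]
    tr_lab <- lab[tr_idx]
    if (balance) {
      n0 <- sum(tr_lab == 0L); n1 <- sum(tr_lab == 1L)
      if (n0 != n1 && min(n0, n1) > 0) {
        minority <- if (n0 < n1) 0L else 1L
        pool <- which(tr_lab == minority)
        extra <- sample(pool, abs(n0 - n1), replace = TRUE)
        aug_extra <- lapply(tr_samples[extra], augment_bank, mode = "train")
        tr_samples <- c(tr_samples, aug_extra)
        tr_lab <- c(tr_lab, rep(minority, length(extra)))
      }
    }
    if (normalize) {
      xs <- sample_batch(tr_samples)
      cm <- as_channel_mat(xs)
      model$norm <- list(mean = colMeans(cm),
                         sd = pmax(apply(cm, 2, sd), 1e-6))
    }
    va_x <- sample_batch(samples[va_idx], model)
    va_lab <- lab[va_idx]
    lr <- config$learning_rate
    best_loss <- Inf; best <- NULL; stagnant <- 0L
    hist <- list()
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(length(tr_samples))
      ep_loss <- 0; nb <- 0L
      for (b0 in seq(1, length(ord), by = config$batch_size)) {
        bi <- ord[b0:min(b0 + config$batch_size - 1L, length(ord))]
        bs <- tr_samples[bi]
        if (augment) bs <- lapply(bs, augment_bank, mode = "train")
        x <- sample_batch(bs, model)
        fw <- forward_net(model, x, training = TRUE, keep_caches = TRUE)
        ls <- bce_loss(fw$scores, tr_lab[bi])
        if (!is.finite(ls$loss))
          stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch))
        backward_net(model, fw, ls$grad)
        sgd_step(c(model$layers, list(model$head)), lr, config$momentum,
                 config$weight_decay)
        ep_loss <- ep_loss + ls$loss; nb <- nb + 1L
      }
      vfw <- forward_net(model, va_x, training = FALSE)
      vls <- bce_loss(vfw$scores, va_lab)
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                  val_loss = vls$loss, lr = lr)
      if (verbose)
        message(sprintf("epoch %02d  train %.4f  val %.4f  lr %.2e",
                        epoch, ep_loss / nb, vls$loss, lr))
      if (vls$loss < best_loss - 1e-9) {
        best_loss <- vls$loss
        best <- snapshot_params(c(model$layers, list(model$head)))
        stagnant <- 0L
      } else {
        stagnant <- stagnant + 1L
        if (stagnant %% config$plateau_patience == 0L) lr <- lr * config$lr_factor
        if (stagnant >= config$early_stop_patience) break
      }
    }
    if (!is.null(best))
      restore_params(c(model$layers, list(model$head)), best)
    model$history <- do.call(rbind, hist)
    model$trained <- TRUE
    model$split_info <- list(round = round, train = sort(rd$train),
                             validation = sort(rd$validation),
                             test = sort(rd$test), seed = split_plan$seed)
    model
  })
}

#' Predict class probabilities for samples
#'
#' Evaluation-mode forward pass (no augmentation, stored normalization
#' applied), returning the progression-class probability per sample.
#'
#' @param model a trained [train()] network.
#' @param samples list of samples.
#' @return Numeric vector of class-1 probabilities.
#' @export
predict_net <- function(model, samples) {
  x <- sample_batch(samples, model)
  fw <- forward_net(model, x, training = FALSE)
  e <- exp(sweep(fw$scores, 2, apply(fw$scores, 2, max)))
  p <- sweep(e, 2, colSums(e), "/")
  p[2, ]
}
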