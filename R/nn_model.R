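#' Network configuration for the SE-SPP classifiers
#'
#' Architecture settings for the squeeze-and-excitation / spatial pyramid
#' pooling image classifiers. The default `"densenet"` backbone is a
#' DenseNet-121-style network (growth rate 32, bottleneck dense units,
#' blocks of 6/12/24 layers each followed by an SE gate and a halving
#' transition); the spatial pyramid pooling layer replaces the final
#' pooling at the 512-channel stage reached after the third transition,
#' with pyramid levels 1x1, 2x2 and 4x4, so a 224 x 224 input yields a
#' 512 * (1 + 4 + 16) = 10752-long feature vector ahead of the fully
#' connected head. `"resnet18"` is the standard 4-stage residual network
#' with an SE gate after each stage and the same SPP head. Narrower
#' variants for small studies are obtained by lowering `growth_rate`,
#' `block_layers`, `stem_channels` and `input_size`.
#'
#' @param backbone `"densenet"` or `"resnet18"`.
#' @param se_reduction squeeze-and-excitation bottleneck ratio (default
#'   16, the original SE-Net setting).
#' @param spp_levels pyramid grid sizes (default `c(1, 2, 4)`).
#' @param n_classes number of output scores (default 2).
#' @param input_size expected square input side (default 224).
#' @param growth_rate,block_layers,stem_channels,bottleneck DenseNet
#'   settings.
#' @param resnet_channels,resnet_blocks,resnet_strides ResNet settings.
#' @return An object of class `net_config`.
#' @export
net_config <- function(backbone = c("densenet", "resnet18"),
                       se_reduction = 16, spp_levels = c(1, 2, 4),
                       n_classes = 2, input_size = 224,
                       growth_rate = 32, block_layers = c(6, 12, 24),
                       stem_channels = 64, bottleneck = TRUE,
                       resnet_channels = c(64, 128, 256, 512),
                       resnet_blocks = c(2, 2, 2, 2),
                       resnet_strides = c(1, 2, 2, 2)) {
  backbone <- match.arg(backbone)
  if (length(spp_levels) == 0 || any(spp_levels < 1))
    stop("spp_levels must be non-empty and positive")
  if (se_reduction < 1) stop("se_reduction must be >= 1")
  structure(list(backbone = backbone, se_reduction = se_reduction,
                 spp_levels = as.integer(spp_levels),
                 n_classes = as.integer(n_classes),
                 input_size = as.integer(input_size),
                 growth_rate = as.integer(growth_rate),
                 block_layers = as.integer(block_layers),
                 stem_channels = as.integer(stem_channels),
                 bottleneck = bottleneck,
                 resnet_channels = as.integer(resnet_channels),
                 resnet_blocks = as.integer(resnet_blocks),
                 resnet_strides = as.integer(resnet_strides)),
            class = "net_config")
}

#' Build an SE-SPP image classifier
#'
#' Instantiates the configured backbone with a squeeze-and-excitation
#' block appended to each dense/residual stage output, the spatial
#' pyramid pooling layer in place of the final pooling, and a fully
#' connected head mapping the SPP vector to the class scores. Weights are
#' He-initialized from the current RNG stream (no pretrained downloads).
#'
#' @param config a [net_config()].
#' @param n_channels input channel count (default 3).
#' @return An object of class `sspp_net`.
#' @export
build_model <- function(config = net_config(), n_channels = 3) {
  stopifnot(inherits(config, "net_config"))
  layers <- list()
  if (config$backbone == "densenet") {
    c <- config$stem_channels
    layers <- c(layers, list(ly_conv(n_channels, c, 7L, 2L, 3L), ly_bn(c),
                             ly_relu(), ly_maxpool(3L, 2L, 1L)))
    for (nb in config$block_layers) {
      db <- ly_dense_block(c, nb, config$growth_rate, config$bottleneck)
      c <- db$cout
      tr <- ly_transition(c)
      layers <- c(layers, list(db, ly_se(c, min(config$se_reduction, c)), tr))
      c <- tr$cout
    }
  } else {
    ch <- config$resnet_channels
    c <- ch[1]
    layers <- c(layers, list(ly_conv(n_channels, c, 7L, 2L, 3L), ly_bn(c),
                             ly_relu(), ly_maxpool(3L, 2L, 1L)))
    for (s in seq_along(ch)) {
      for (b in seq_len(config$resnet_blocks[s])) {
        stride <- if (b == 1L) config$resnet_strides[s] else 1L
        layers <- c(layers, list(ly_resblock(c, ch[s], stride)))
        c <- ch[s]
      }
      layers <- c(layers, list(ly_se(c, min(config$se_reduction, c))))
    }
  }
  spp_len <- c * sum(config$spp_levels^2)
  layers <- c(layers, list(ly_spp(config$spp_levels)))
  head <- ly_fc(spp_len, config$n_classes)
  structure(list(layers = layers, head = head, config = config,
                 n_channels = n_channels, spp_len = spp_len,
                 trained = FALSE, norm = NULL, history = NULL,
                 split_info = NULL),
            class = "sspp_net")
}

#' @export
print.sspp_net <- function(x, ...) {
  cat(sprintf("<sspp_net %s> SPP %s -> %d features -> %d classes%s\n",
              x$config$backbone,
              paste(x$config$spp_levels, collapse = "/"),
              x$spp_len, x$config$n_classes,
              if (x$trained) " [trained]" else ""))
  invisible(x)
}

# full forward pass; x is (H, W, C, N). Returns scores (n_classes x N),
# spp features (F x N) and, when keep_caches, the caches for backprop.
forward_net <- function(model, x, training = FALSE, keep_caches = FALSE) {
  caches <- if (keep_caches) vector("list", length(model$layers)) else NULL
  for (k in seq_along(model$layers)) {
    r <- ly_fw(model$layers[[k]], x, training)
    x <- r$out
    if (keep_caches) caches[[k]] <- r$cache
  }
  spp <- x                               # F x N after the SPP layer
  rh <- ly_fw(model$head, spp, training)
  list(scores = rh$out, spp = spp, caches = caches, head_cache = rh$cache)
}

backward_net <- function(model, fw, gscores) {
  g <- ly_bw(model$head, fw$head_cache, gscores)
  for (k in rev(seq_along(model$layers)))
    g <- ly_bw(model$layers[[k]], fw$caches[[k]], g)
  invisible(g)
}

#' Squeeze-and-excitation channel gate
#'
#' Applies an SE gate to a feature map: global average pooling squeezes
#' each channel to a scalar, a two-layer bottleneck (ReLU then sigmoid)
#' produces per-channel gates in (0, 1), and the input is rescaled
#' channel-wise. With no `weights` supplied the excitation weights are
#' He-initialized from the current RNG stream; pass `gates` to bypass the
#' excitation entirely (e.g. all-ones gates give the identity map).
#'
#' @param feature_map `(H, W, C)` or `(H, W, C, N)` numeric array.
#' @param reduction bottleneck ratio; must not exceed the channel count.
#' @param weights optional list `(w1, b1, w2, b2)` of excitation weights.
#' @param gates optional explicit gate values (length C or C x N matrix).
#' @return Array of the input shape with attribute `"gates"` (C x N).
#' @export
se_block <- function(feature_map, reduction = 16, weights = NULL,
                     gates = NULL) {
  x <- feature_map
  d3 <- length(dim(x)) == 3L
  if (d3) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (is.null(gates)) {
    if (reduction > d[3]) stop("SE reduction exceeds channel count")
    l <- ly_se(d[3], reduction)
    if (!is.null(weights)) l$par <- weights
    r <- ly_fw(l, x, training = FALSE)
    out <- r$out; g <- r$cache$g
  } else {
    g <- matrix(gates, d[3], d[4])
    out <- x * bc_cn(g, d)
    dim(out) <- d
  }
  if (d3) dim(out) <- d[1:3]
  attr(out, "gates") <- g
  out
}

#' Spatial pyramid pooling of a feature map
#'
#' Adaptive max pooling of a feature map at each pyramid level, flattened
#' and concatenated into a fixed-length vector of length
#' `C * sum(levels^2)` — independent of the spatial extent of the input,
#' which must be at least `max(levels)` in each direction.
#'
#' @param feature_map `(H, W, C)` numeric array (or `(H, W, C, N)`, giving
#'   a matrix with one column per sample).
#' @param levels pyramid grid sizes.
#' @return Numeric vector of length `C * sum(levels^2)` (or a matrix for
#'   batched input).
#' @export
spp_pool <- function(feature_map, levels = c(1, 2, 4)) {
  x <- feature_map
  d3 <- length(dim(x)) == 3L
  if (d3) dim(x) <- c(dim(x), 1L)
  out <- spp_fw_cpp(x, as.integer(levels))$out
  if (d3) as.vector(out) else out
}

#' Extract the image feature vector of a sample
#'
#' Runs one sample through a (trained) network in evaluation mode and
#' returns the one-dimensional image feature vector handed to the fusion
#' stage: by default the fully connected head's class-score vector
#' (`mode = "scores"`), or the pre-head SPP feature vector
#' (`mode = "spp"`).
#'
#' @param model an [build_model()] network.
#' @param sample a [assemble_sample()] result or `(H, W, C)` array.
#' @param mode `"scores"` or `"spp"`.
#' @return Numeric vector (length `n_classes` or the SPP length).
#' @export
extract_image_features <- function(model, sample, mode = c("scores", "spp")) {
  mode <- match.arg(mode)
  if (!isTRUE(model$trained))
    warning("model is untrained; features come from initial weights")
  x <- sample_batch(list(sample), model)
  fw <- forward_net(model, x, training = FALSE)
  if (mode == "scores") as.vector(fw$scores) else as.vector(fw$spp)
}

# stack samples into an (H, W, C, N) batch, applying the model's stored
# training-set normalization when present
sample_batch <- function(samples, model = NULL) {
  px <- lapply(samples, function(s)
    if (inherits(s, "multichannel_sample")) s$pixels else s)
  d <- dim(px[[1]])
  x <- array(0, dim = c(d, length(px)))
  for (i in seq_along(px)) x[, , , i] <- px[[i]]
  if (!is.null(model$norm)) {
    x <- (x - bc_channel(model$norm$mean, dim(x))) /
      bc_channel(model$norm$sd, dim(x))
    dim(x) <- c(d, length(px))
  }
  x
}
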